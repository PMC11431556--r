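#' Mediated (indirect) effect by the product of coefficients
#'
#' Two-step MR mediation: `beta1` is the exposure -> mediator causal effect
#' and `beta2` the mediator -> outcome effect, each from its own
#' instrumented analysis in non-overlapping samples, so the mediated effect
#' is their product. The standard error is the first-order delta method
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`; the interval is the symmetric
#' normal `point +/- z se` and the p-value two-sided normal.
#'
#' @param beta1,se1 exposure -> mediator effect and standard error.
#' @param beta2,se2 mediator -> outcome effect and standard error.
#' @param level confidence level (default 0.95).
#' @return List with `mediated`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
mediated_effect <- function(beta1, se1, beta2, se2, level = 0.95) {
  stopifnot(se1 > 0, se2 > 0)
  point <- beta1 * beta2
  se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  z <- stats::qnorm((1 + level) / 2)
  pval <- if (se == 0) 1 else pval_from_estimate(point, se)
  list(mediated = point, se = se,
       ci_low = point - z * se, ci_high = point + z * se, pval = pval)
}

#' Direct effect
#'
#' The exposure -> outcome effect not transmitted through the mediator:
#' the difference between the total effect and the mediated effect.
#'
#' @param total total causal effect of the exposure on the outcome.
#' @param mediated mediated effect (product of coefficients).
#' @return `total - mediated`.
#' @export
direct_effect <- function(total, mediated) total - mediated

#' Mediation proportion
#'
#' `100 * mediated / total`, in percent. When the mediated and total effects
#' have opposite signs the proportion is negative and a suppression warning
#' is issued (the mediator masks rather than transmits part of the effect).
#'
#' @param mediated mediated effect.
#' @param total total effect; must be nonzero.
#' @return Proportion in percent.
#' @export
mediation_proportion <- function(mediated, total) {
  if (total == 0) stop("mediation proportion undefined for total effect 0")
  if (mediated != 0 && sign(mediated) != sign(total)) {
    warning("mediated and total effects have opposite signs (suppression); proportion is negative")
  }
  100 * mediated / total
}

#' Confidence interval for the mediation proportion
#'
#' First-order delta method on the ratio `mediated/total`, treating the two
#' as independent (the exposure -> mediator and mediator -> outcome legs use
#' different instrument sets from the exposure -> outcome leg, so their
#' correlation is negligible at first order):
#' `var(m/t) ~ (m/t)^2 (var_m/m^2 + var_t/t^2)`. A seeded parametric
#' bootstrap (`method = "bootstrap"`) is available as a check on the normal
#' approximation when the total effect is imprecise. Endpoints are returned
#' sorted (low, high).
#'
#' @param mediated,mediated_se mediated effect and its standard error.
#' @param total,total_se total effect and its standard error.
#' @param level confidence level (default 0.95).
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot,seed bootstrap replicates and seed (bootstrap method only).
#' @return Numeric vector `c(low, high)` in percent.
#' @export
proportion_ci <- function(mediated, mediated_se, total, total_se,
                          level = 0.95, method = c("delta", "bootstrap"),
                          n_boot = 10000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(total != 0, mediated_se >= 0, total_se >= 0)
  z <- stats::qnorm((1 + level) / 2)
  if (method == "delta") {
    prop <- 100 * mediated / total
    rel_var <- (if (mediated != 0) mediated_se^2 / mediated^2 else 0) +
      total_se^2 / total^2
    se <- abs(prop) * sqrt(rel_var)
    if (mediated == 0) se <- 100 * mediated_se / abs(total)
    sort(c(prop - z * se, prop + z * se))
  } else {
    props <- withr::with_seed(seed, {
      m <- stats::rnorm(n_boot, mediated, mediated_se)
      t_ <- stats::rnorm(n_boot, total, total_se)
      100 * m / t_
    })
    unname(stats::quantile(props, c((1 - level) / 2, (1 + level) / 2)))
  }
}

#' Two-step MR mediation for one exposure-mediator-outcome triple
#'
#' Runs the full decomposition: `beta1` from IVW of exposure -> mediator
#' (instruments selected on the exposure), `beta2` from IVW of mediator ->
#' outcome (instruments selected on the mediator), `total` from IVW of
#' exposure -> outcome (same instrument rules as the main screen). Each leg
#' passes through selection, clumping, harmonization, the configured
#' outcome-association and weak-instrument filters, and the a priori
#' exclusion list. The sensitivity battery's Egger-intercept test is run on
#' every leg and failures (p < 0.05) are flagged.
#'
#' By default the mediator -> outcome leg additionally excludes SNPs that
#' are exposure-associated at the exposure threshold: such variants reach
#' the mediator through the exposure and would transmit the exposure's
#' direct (non-mediated) path into `beta2`, biasing the decomposition.
#'
#' @param exposure,mediator,outcome [gwas_sumstats()] objects.
#' @param cfg an [instrument_config()].
#' @param exclude_exposure_associated drop exposure-associated SNPs from the
#'   mediator -> outcome leg (default `TRUE`).
#' @param n_boot,seed passed to bootstrap-based components where needed.
#' @param quiet suppress messages.
#' @return A list of class `mediation_result` with ids, per-leg estimates
#'   (`beta1`, `se1`, `beta2`, `se2`, `total`, `se_total`), the mediated
#'   effect with delta-method interval and p-value, `direct`,
#'   `proportion_pct` and `proportion_ci`, per-leg Egger-intercept p-values
#'   (`egger_flags`), and `status` (`"ok"` or a withhold reason).
#' @export
run_mediation <- function(exposure, mediator, outcome, cfg = instrument_config(),
                          exclude_exposure_associated = TRUE,
                          n_boot = 1000, seed = 1L, quiet = TRUE) {
  ids <- c(exposure = attr(exposure, "trait_id"),
           mediator = attr(mediator, "trait_id"),
           outcome = attr(outcome, "trait_id"))

  leg_total <- mr_leg(exposure, outcome, cfg, quiet = quiet)
  leg1 <- mr_leg(exposure, mediator, cfg, quiet = quiet)
  extra <- character()
  if (exclude_exposure_associated) {
    extra <- exposure$SNP[exposure$P < cfg$exposure_p_threshold]
  }
  leg2 <- mr_leg(mediator, outcome, cfg, extra_excluded = extra, quiet = quiet)

  failed <- c(total = is.null(leg_total$estimate), beta1 = is.null(leg1$estimate),
              beta2 = is.null(leg2$estimate))
  if (any(failed)) {
    return(structure(list(exposure_id = ids[["exposure"]],
                          mediator_id = ids[["mediator"]],
                          outcome_id = ids[["outcome"]],
                          status = paste0("withheld: no instruments for leg(s) ",
                                          paste(names(failed)[failed], collapse = ", "))),
                     class = "mediation_result"))
  }

  med <- mediated_effect(leg1$estimate$beta, leg1$estimate$se,
                         leg2$estimate$beta, leg2$estimate$se)
  total <- leg_total$estimate$beta
  prop <- if (total != 0) {
    suppressWarnings(mediation_proportion(med$mediated, total))
  } else NA_real_
  prop_ci <- if (total != 0) {
    proportion_ci(med$mediated, med$se, total, leg_total$estimate$se)
  } else c(NA_real_, NA_real_)

  egger_flags <- c(total = leg_total$egger_intercept_pval,
                   beta1 = leg1$egger_intercept_pval,
                   beta2 = leg2$egger_intercept_pval)

  structure(list(
    exposure_id = ids[["exposure"]], mediator_id = ids[["mediator"]],
    outcome_id = ids[["outcome"]],
    beta1 = leg1$estimate$beta, se1 = leg1$estimate$se,
    n_snp1 = leg1$estimate$n_snp,
    beta2 = leg2$estimate$beta, se2 = leg2$estimate$se,
    n_snp2 = leg2$estimate$n_snp,
    total = total, se_total = leg_total$estimate$se,
    n_snp_total = leg_total$estimate$n_snp,
    mediated = med$mediated, mediated_se = med$se,
    mediated_ci_low = med$ci_low, mediated_ci_high = med$ci_high,
    mediated_pval = med$pval,
    direct = direct_effect(total, med$mediated),
    proportion_pct = prop, proportion_ci = prop_ci,
    egger_flags = egger_flags,
    egger_flagged = any(egger_flags < 0.05, na.rm = TRUE),
    status = "ok"
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", x$exposure_id, x$mediator_id,
              x$outcome_id))
  if (!identical(x$status, "ok")) {
    cat(" ", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("  mediated = %.4f (95%% CI %.4f, %.4f), p = %.4g\n",
              x$mediated, x$mediated_ci_low, x$mediated_ci_high, x$mediated_pval))
  cat(sprintf("  total = %.4f, direct = %.4f, proportion = %.3g%% (%.3g%%, %.3g%%)\n",
              x$total, x$direct, x$proportion_pct,
              x$proportion_ci[1], x$proportion_ci[2]))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    return(data.frame(exposure = x$exposure_id, mediator = x$mediator_id,
                      outcome = x$outcome_id, status = x$status,
                      stringsAsFactors = FALSE))
  }
  data.frame(exposure = x$exposure_id, mediator = x$mediator_id,
             outcome = x$outcome_id,
             beta1 = x$beta1, se1 = x$se1, beta2 = x$beta2, se2 = x$se2,
             total = x$total, se_total = x$se_total,
             mediated = x$mediated, mediated_se = x$mediated_se,
             mediated_ci_low = x$mediated_ci_low,
             mediated_ci_high = x$mediated_ci_high,
             mediated_pval = x$mediated_pval,
             direct = x$direct, proportion_pct = x$proportion_pct,
             proportion_ci_low = x$proportion_ci[1],
             proportion_ci_high = x$proportion_ci[2],
             egger_flagged = x$egger_flagged, status = x$status,
             stringsAsFactors = FALSE)
}
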