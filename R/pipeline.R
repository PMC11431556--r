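#' One instrumented exposure -> outcome analysis leg
#'
#' The shared selection-to-estimation path used by the screen, the reverse
#' MR filter and every mediation leg: exposure-association selection,
#' distance clumping, harmonization, outcome-association filter (skipped
#' when the configured threshold is 0), weak-instrument filter, a priori
#' SNP exclusion, then IVW (Wald ratio when a single instrument remains).
#'
#' @param exposure,outcome [gwas_sumstats()] objects.
#' @param cfg an [instrument_config()].
#' @param extra_excluded additional SNP ids to exclude for this leg only.
#' @param ld optional LD provider passed to [clump()].
#' @param quiet suppress messages.
#' @return List with `h` (the final `harmonized_set`), `estimate` (an
#'   `mr_estimate`, or `NULL` with `reason` when no instruments survive),
#'   `egger_intercept_pval` (NA below k = 3), and `reason`.
#' @export
mr_leg <- function(exposure, outcome, cfg = instrument_config(),
                   extra_excluded = character(), ld = NULL, quiet = TRUE) {
  sel <- select_exposure_snps(exposure, cfg$exposure_p_threshold)
  if (nrow(sel) == 0L) {
    return(list(h = NULL, estimate = NULL, egger_intercept_pval = NA_real_,
                reason = "no_exposure_significant_snps"))
  }
  sel <- clump(sel, r2_max = cfg$clump_r2, window_kb = cfg$clump_window_kb, ld = ld)
  h <- suppressWarnings(harmonize(sel, outcome, quiet = quiet))
  if (cfg$outcome_p_threshold > 0) {
    h <- filter_outcome_associated(h, cfg$outcome_p_threshold)
  }
  h <- filter_weak_instruments(h, cfg$f_min)
  h <- exclude_snps(h, c(cfg$excluded_snps, extra_excluded), quiet = quiet)
  k <- nrow(h)
  if (k == 0L) {
    return(list(h = h, estimate = NULL, egger_intercept_pval = NA_real_,
                reason = "no_instruments_after_filters"))
  }
  est <- if (k == 1L) {
    wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y)
  } else {
    ivw(h)
  }
  eip <- if (k >= 3L) egger_intercept_test(h)$pval else NA_real_
  list(h = h, estimate = est, egger_intercept_pval = eip, reason = NA_character_)
}

#' Forward MR screen of an exposure panel against one outcome
#'
#' For each exposure: instrument selection, harmonization and filtering via
#' [mr_leg()]; MR-PRESSO outlier removal (k >= 4) before final estimation;
#' the five estimators; heterogeneity and pleiotropy diagnostics.
#' IVW p-values are then FDR-adjusted across the screen (Benjamini-
#' Hochberg) and tiered; exposures with IVW p < 0.05 are marked candidates.
#' Exposures yielding no instruments are logged in the `exclusions`
#' attribute and skipped.
#'
#' @param exposures list of [gwas_sumstats()] objects (or a single one).
#' @param outcome a [gwas_sumstats()].
#' @param cfg an [instrument_config()].
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param presso_n_sim MR-PRESSO simulations (0 disables outlier removal).
#' @param seed integer seed governing every stochastic component.
#' @param quiet suppress messages.
#' @return data.frame with one row per analysed exposure: ids, `nsnp`,
#'   per-method beta/se/p columns, OR and CI for IVW, heterogeneity and
#'   Egger-intercept p-values, MR-PRESSO global p and outlier count,
#'   `pval_ivw`, `fdr_q`, `tier`, `candidate`. Attribute `exclusions` is a
#'   data.frame of skipped exposures with machine-readable reasons.
#' @export
run_screen <- function(exposures, outcome, cfg = instrument_config(),
                       n_boot = 1000, presso_n_sim = 1000, seed = 1L,
                       quiet = TRUE) {
  if (inherits(exposures, "gwas_sumstats")) exposures <- list(exposures)
  if (length(exposures) == 0L) stop("empty exposure list")
  rows <- list()
  excl <- list()
  for (i in seq_along(exposures)) {
    ex <- exposures[[i]]
    id <- attr(ex, "trait_id")
    leg <- mr_leg(ex, outcome, cfg, quiet = quiet)
    if (is.null(leg$estimate)) {
      excl[[length(excl) + 1L]] <- data.frame(trait = id, reason = leg$reason,
                                              stringsAsFactors = FALSE)
      next
    }
    h <- leg$h
    presso_global <- NA_real_
    n_outliers <- 0L
    if (presso_n_sim > 0 && nrow(h) >= 4L) {
      pr <- mr_presso(h, n_sim = presso_n_sim, seed = seed + i, sig = 0.05)
      presso_global <- pr$global_pval
      n_outliers <- length(pr$outliers)
      if (n_outliers > 0L) h <- .subset_harmonized(h, !(h$SNP %in% pr$outliers))
    }
    ests <- mr_all_methods(h, n_boot = n_boot, seed = seed + 1000L + i)
    wide <- list(exposure = id, outcome = attr(outcome, "trait_id"),
                 nsnp = nrow(h))
    for (j in seq_len(nrow(ests))) {
      m <- ests$method[j]
      wide[[paste0("beta_", m)]] <- ests$beta[j]
      wide[[paste0("se_", m)]] <- ests$se[j]
      wide[[paste0("pval_", m)]] <- ests$pval[j]
    }
    iv <- ests[ests$method %in% c("ivw", "wald_ratio"), ][1, ]
    wide$or_ivw <- iv$or
    wide$or_low_ivw <- iv$or_low
    wide$or_high_ivw <- iv$or_high
    wide$pval_ivw <- iv$pval
    k <- nrow(h)
    wide$q_ivw_pval <- if (k >= 2L) cochran_q(h, "ivw")$pval else NA_real_
    wide$q_egger_pval <- if (k >= 3L) cochran_q(h, "egger")$pval else NA_real_
    wide$egger_intercept_pval <- if (k >= 3L) egger_intercept_test(h)$pval else NA_real_
    wide$presso_global_pval <- presso_global
    wide$presso_n_outliers <- n_outliers
    rows[[length(rows) + 1L]] <- as.data.frame(wide, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, lapply(rows, function(r) {
      all_cols <- unique(unlist(lapply(rows, names)))
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    }))
    out$fdr_q <- bh_fdr(out$pval_ivw)
    out$tier <- assign_tier(out$fdr_q)
    out$candidate <- out$pval_ivw < 0.05
  }
  attr(out, "exclusions") <- if (length(excl) > 0L) do.call(rbind, excl) else
    data.frame(trait = character(), reason = character(), stringsAsFactors = FALSE)
  out
}

#' Reverse-MR filter on screen candidates
#'
#' For each candidate exposure, runs MR in the reverse direction (the
#' outcome as the instrumented trait, the candidate as the outcome) and
#' removes candidates with reverse IVW p < 0.05 -- traits whose association
#' may reflect causation by the outcome rather than of it.
#'
#' @param candidates character vector of candidate exposure trait ids, or
#'   the data.frame from [run_screen()] (its `candidate` rows are used).
#' @param exposures named list of [gwas_sumstats()] containing at least the
#'   candidates.
#' @param outcome a [gwas_sumstats()].
#' @param cfg an [instrument_config()]; its exposure threshold is applied
#'   to the outcome-side instruments.
#' @param quiet suppress messages.
#' @return Character vector of retained candidate ids; attribute `removed`
#'   is a data.frame of removed traits with the reverse p-value and reason.
#' @export
reverse_mr_filter <- function(candidates, exposures, outcome,
                              cfg = instrument_config(), quiet = TRUE) {
  if (is.data.frame(candidates)) {
    candidates <- candidates$exposure[candidates$candidate]
  }
  if (length(candidates) == 0L) {
    out <- character()
    attr(out, "removed") <- data.frame(trait = character(), reverse_pval = numeric(),
                                       reason = character(), stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, attr, character(1), "trait_id")
  }
  retained <- character()
  removed <- list()
  for (id in candidates) {
    leg <- mr_leg(outcome, exposures[[id]], cfg, quiet = quiet)
    rev_p <- if (is.null(leg$estimate)) NA_real_ else leg$estimate$pval
    if (!is.na(rev_p) && rev_p < 0.05) {
      removed[[length(removed) + 1L]] <-
        data.frame(trait = id, reverse_pval = rev_p,
                   reason = "reverse_causal", stringsAsFactors = FALSE)
    } else {
      retained <- c(retained, id)
    }
  }
  attr(retained, "removed") <- if (length(removed) > 0L) do.call(rbind, removed) else
    data.frame(trait = character(), reverse_pval = numeric(), reason = character(),
               stringsAsFactors = FALSE)
  retained
}

#' Mediation screen: exposures -> mediators -> outcome
#'
#' Screens every retained exposure against every mediator (IVW p < 0.05
#' required on the exposure -> mediator leg) and every mediator against the
#' outcome (IVW p < 0.05 required); qualifying triples are assembled with
#' [run_mediation()]. Triples with an Egger-intercept p < 0.05 on any leg
#' are excluded with reason `"egger_intercept"` (horizontal pleiotropy).
#' The final table is FDR-tiered on the mediated-effect p-values.
#'
#' @param exposures named list of retained exposure [gwas_sumstats()].
#' @param mediators named list of mediator [gwas_sumstats()].
#' @param outcome a [gwas_sumstats()].
#' @param cfg an [instrument_config()].
#' @param seed integer seed.
#' @param quiet suppress messages.
#' @return data.frame of mediation results (one row per retained triple,
#'   columns as `as.data.frame.mediation_result` plus `fdr_q` and `tier`);
#'   attribute `exclusions` logs every excluded pair/triple with a
#'   machine-readable reason.
#' @export
run_mediation_screen <- function(exposures, mediators, outcome,
                                 cfg = instrument_config(), seed = 1L,
                                 quiet = TRUE) {
  if (inherits(exposures, "gwas_sumstats")) exposures <- list(exposures)
  if (inherits(mediators, "gwas_sumstats")) mediators <- list(mediators)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, attr, character(1), "trait_id")
  }
  if (is.null(names(mediators))) {
    names(mediators) <- vapply(mediators, attr, character(1), "trait_id")
  }
  excl <- list()
  note <- function(exposure, mediator, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(exposure = exposure,
                                             mediator = mediator,
                                             reason = reason,
                                             stringsAsFactors = FALSE)
  }

  # mediator -> outcome screen, computed once per mediator
  med_ok <- logical(length(mediators))
  names(med_ok) <- names(mediators)
  for (m in names(mediators)) {
    leg <- mr_leg(mediators[[m]], outcome, cfg, quiet = quiet)
    med_ok[m] <- !is.null(leg$estimate) && leg$estimate$pval < 0.05
  }

  rows <- list()
  for (e in names(exposures)) {
    for (m in names(mediators)) {
      leg1 <- mr_leg(exposures[[e]], mediators[[m]], cfg, quiet = quiet)
      if (is.null(leg1$estimate) || leg1$estimate$pval >= 0.05) {
        note(e, m, "exposure_mediator_screen_failed")
        next
      }
      if (!med_ok[m]) {
        note(e, m, "mediator_outcome_screen_failed")
        next
      }
      res <- run_mediation(exposures[[e]], mediators[[m]], outcome, cfg,
                           seed = seed, quiet = quiet)
      if (!identical(res$status, "ok")) {
        note(e, m, res$status)
        next
      }
      if (res$egger_flagged) {
        note(e, m, "egger_intercept")
        next
      }
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame()
  if (nrow(out) > 0L) {
    out$fdr_q <- bh_fdr(out$mediated_pval)
    out$tier <- assign_tier(out$fdr_q)
  }
  attr(out, "exclusions") <- if (length(excl) > 0L) do.call(rbind, excl) else
    data.frame(exposure = character(), mediator = character(),
               reason = character(), stringsAsFactors = FALSE)
  out
}
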