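#' Cochran's Q heterogeneity test
#'
#' Weighted residual sum of squares of the instrument-level outcome effects
#' about the fitted model, `Q = sum(w_j r_j^2)` with `w_j = 1/se_y_j^2`,
#' referred to a chi-square null with `k-1` (IVW, fixed-effect fit) or `k-2`
#' (Egger) degrees of freedom. Large Q indicates the per-SNP causal ratios
#' disagree more than sampling error allows -- heterogeneity, often a
#' footprint of pleiotropy.
#'
#' @param h a `harmonized_set`.
#' @param method `"ivw"` (k >= 2) or `"egger"` (k >= 3).
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, method = c("ivw", "egger")) {
  method <- match.arg(method)
  stopifnot(inherits(h, "harmonized_set"))
  k <- nrow(h)
  w <- 1 / h$se_y^2
  if (method == "ivw") {
    if (k < 2L) stop("cochran_q(ivw) requires k >= 2")
    beta <- sum(w * h$beta_x * h$beta_y) / sum(w * h$beta_x^2)
    q <- sum(w * (h$beta_y - beta * h$beta_x)^2)
    df <- k - 1L
  } else {
    if (k < 3L) stop("cochran_q(egger) requires k >= 3")
    q <- egger(h)$q
    df <- k - 2L
  }
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; its two-sided
#' normal-theory p-value tests the no-directional-pleiotropy hypothesis
#' (p > 0.05 read as absence of evidence for horizontal pleiotropy).
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return List with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  e <- egger(h)
  list(intercept = e$intercept, se = e$intercept_se, pval = e$intercept_pval)
}

#' Leave-one-out IVW analysis
#'
#' Refits IVW k times, omitting one instrument at a time, to detect single
#' SNPs that drive the estimate. An omission is flagged when it changes the
#' sign of the estimate or moves it outside the full-set confidence
#' interval.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param model IVW variance model.
#' @return data.frame with columns `left_out_snp`, `beta`, `se`, `pval`,
#'   `flagged`; attribute `full` holds the full-set `mr_estimate`.
#' @export
leave_one_out <- function(h, model = "multiplicative_random") {
  stopifnot(inherits(h, "harmonized_set"))
  k <- nrow(h)
  if (k < 3L) stop("leave_one_out requires k >= 3")
  full <- ivw(h, model = model)
  rows <- lapply(seq_len(k), function(j) {
    fit <- ivw(.subset_harmonized(h, -j), model = model)
    data.frame(left_out_snp = h$SNP[j], beta = fit$beta, se = fit$se,
               pval = fit$pval,
               flagged = sign(fit$beta) != sign(full$beta) |
                 fit$beta < full$ci_low | fit$beta > full$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' MR-PRESSO global test and outlier detection
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. For each
#' instrument j the outcome effect is predicted from the IVW fit that leaves
#' j out; the observed RSS of these leave-one-out predictions is compared
#' against its parametric null distribution, obtained by redrawing each
#' `beta_y_j` from `N(predicted_j, se_y_j)` `n_sim` times and recomputing
#' the RSS (leave-one-out slopes re-estimated within each simulation). The
#' global p-value is the rank-based tail probability
#' `(1 + #{RSS_sim >= RSS_obs}) / (n_sim + 1)`.
#'
#' Per-SNP outliers are variants whose observed squared residual exceeds its
#' own simulated null at Bonferroni-adjusted level `sig` (per-SNP rank p
#' times k below `sig`). `corrected` is the IVW estimate after removing
#' them. The distortion test of the original algorithm is not implemented.
#'
#' @param h a `harmonized_set` with at least 4 SNPs (below that the global
#'   test is reported unavailable with a warning).
#' @param n_sim parametric simulations (default 1000; below 100 a warning is
#'   issued).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param sig significance level for outlier calling (default 0.05).
#' @param model IVW variance model for the corrected estimate.
#' @return List with `global_pval`, `outliers` (character vector of SNP
#'   ids), `outlier_pvals` (Bonferroni-adjusted, named), `corrected` (an
#'   `mr_estimate`, or `NULL` when fewer than 2 SNPs remain).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1L, sig = 0.05,
                      model = "multiplicative_random") {
  stopifnot(inherits(h, "harmonized_set"))
  k <- nrow(h)
  if (k < 4L) {
    warning("mr_presso requires k >= 4; global test unavailable")
    return(list(global_pval = NA_real_, outliers = character(),
                outlier_pvals = numeric(), corrected = NULL))
  }
  if (n_sim < 100) warning("n_sim < 100 gives a coarse null; increase n_sim")
  w <- 1 / h$se_y^2
  sxx <- sum(w * h$beta_x^2)
  sxy <- sum(w * h$beta_x * h$beta_y)
  # leave-one-out IVW slopes in closed form
  b_loo <- (sxy - w * h$beta_x * h$beta_y) / (sxx - w * h$beta_x^2)
  pred <- b_loo * h$beta_x
  d_obs <- (h$beta_y - pred)^2
  rss_obs <- sum(d_obs)

  sims <- withr::with_seed(seed, {
    by_sim <- matrix(stats::rnorm(k * n_sim, mean = pred, sd = h$se_y),
                     nrow = k, ncol = n_sim)
    sxy_sim <- colSums(w * h$beta_x * by_sim)                    # 1 x n_sim
    num <- sweep(-(w * h$beta_x) * by_sim, 2, sxy_sim, "+")      # k x n_sim
    b_loo_sim <- num / (sxx - w * h$beta_x^2)
    d_sim <- (by_sim - b_loo_sim * h$beta_x)^2
    list(rss = colSums(d_sim), d = d_sim)
  })
  global_pval <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)

  p_snp <- (1 + rowSums(sims$d >= d_obs)) / (n_sim + 1)
  p_adj <- pmin(p_snp * k, 1)
  names(p_adj) <- h$SNP
  outliers <- h$SNP[p_adj < sig]
  if (length(outliers) > ceiling(k / 2)) {
    warning("mr_presso removed more than half the instruments; set is degenerate")
  }
  keep <- !(h$SNP %in% outliers)
  corrected <- if (sum(keep) >= 2L) ivw(.subset_harmonized(h, keep), model = model) else NULL
  list(global_pval = global_pval, outliers = outliers,
       outlier_pvals = p_adj, corrected = corrected)
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Convenience wrapper assembling Cochran's Q (IVW and Egger fits), the
#' Egger intercept test, the leave-one-out table, and MR-PRESSO into one
#' report.
#'
#' @param h a `harmonized_set` with at least 4 SNPs for the full battery
#'   (components degrade gracefully below their own minimum k).
#' @param n_sim MR-PRESSO simulations.
#' @param seed integer seed.
#' @return List of class `sensitivity_report` with components `q_ivw`,
#'   `q_egger`, `egger_intercept`, `loo`, `presso`.
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = 1L) {
  k <- nrow(h)
  rep <- list(
    q_ivw = if (k >= 2L) cochran_q(h, "ivw") else NULL,
    q_egger = if (k >= 3L) cochran_q(h, "egger") else NULL,
    egger_intercept = if (k >= 3L) egger_intercept_test(h) else NULL,
    loo = if (k >= 3L) leave_one_out(h) else NULL,
    presso = if (k >= 4L) mr_presso(h, n_sim = n_sim, seed = seed) else NULL
  )
  class(rep) <- "sensitivity_report"
  rep
}
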