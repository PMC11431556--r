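#' Instrument-selection configuration
#'
#' Bundles the thresholds of the five-step instrument selection procedure:
#' (1) exposure-association threshold, (2) removal of outcome-associated
#' variants, (3) LD clumping by r-squared and distance, (4) MR-PRESSO outlier
#' exclusion (see [mr_presso()]; applied by the pipeline between selection
#' and estimation), and (5) weak-instrument removal by F-statistic.
#'
#' All thresholds are strict ("less than"). Setting `outcome_p_threshold = 0`
#' disables the outcome-association filter (useful for estimator calibration
#' studies, where truncating on the outcome distorts sampling distributions).
#'
#' @param exposure_p_threshold retain SNPs with exposure p below this
#'   (default 5e-5).
#' @param outcome_p_threshold remove SNPs with outcome p below this
#'   (default 0.05).
#' @param clump_r2 maximum pairwise r-squared between retained instruments
#'   (default 0.001; only enforced when an LD provider is available).
#' @param clump_window_kb clumping distance window in kilobases (default
#'   10000 kb = 10 Mb).
#' @param f_min minimum per-SNP F-statistic (default 10).
#' @param excluded_snps character vector of SNP ids to exclude a priori
#'   (e.g. variants associated with known confounders such as alcohol or
#'   tobacco use).
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(exposure_p_threshold = 5e-5,
                              outcome_p_threshold = 0.05,
                              clump_r2 = 0.001,
                              clump_window_kb = 10000,
                              f_min = 10,
                              excluded_snps = character()) {
  stopifnot(exposure_p_threshold > 0, exposure_p_threshold < 1,
            outcome_p_threshold >= 0, clump_r2 > 0, clump_window_kb >= 0,
            f_min > 0)
  structure(list(exposure_p_threshold = exposure_p_threshold,
                 outcome_p_threshold = outcome_p_threshold,
                 clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 f_min = f_min,
                 excluded_snps = as.character(excluded_snps)),
            class = "instrument_config")
}

#' Select exposure-associated SNPs
#'
#' Criterion (1): retain SNPs whose exposure p-value is strictly below the
#' threshold. Order is preserved. An empty result is allowed (the pipeline
#' logs and skips the pair).
#'
#' @param exposure a [gwas_sumstats()] object.
#' @param threshold p-value threshold (default 5e-5).
#' @return Subset [gwas_sumstats()].
#' @export
select_exposure_snps <- function(exposure, threshold = 5e-5) {
  stopifnot(inherits(exposure, "gwas_sumstats"))
  .subset_sumstats(exposure, exposure$P < threshold)
}

.subset_sumstats <- function(x, keep) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = attr(x, "trait_id"),
            trait_type = attr(x, "trait_type"), n_dropped = 0L,
            class = c("gwas_sumstats", "data.frame"))
}

#' Remove outcome-associated instruments
#'
#' Criterion (2): remove harmonized rows whose outcome p-value is strictly
#' below the threshold, so retained instruments have no detectable direct
#' outcome association. A threshold of 0 disables the filter.
#'
#' @param h a [harmonize()]d set with `pval_y` populated.
#' @param threshold p-value threshold (default 0.05).
#' @return Filtered `harmonized_set`.
#' @export
filter_outcome_associated <- function(h, threshold = 0.05) {
  stopifnot(inherits(h, "harmonized_set"))
  .subset_harmonized(h, !(h$pval_y < threshold))
}

#' Distance-based greedy clumping
#'
#' Criterion (3): greedy selection by ascending exposure p-value. A SNP is
#' accepted iff no previously accepted SNP on the same chromosome lies
#' within `window_kb` kilobases AND (when an LD provider is supplied) has
#' pairwise r-squared above `r2_max` with it. Without an LD provider,
#' distance alone governs -- exact for independent SNPs such as those of the
#' synthetic generator, whose variants are spaced beyond the window.
#'
#' The globally smallest-p SNP always survives; with `window_kb = 0` and no
#' LD provider, clumping is the identity.
#'
#' @param records a [gwas_sumstats()] object with CHR/BP populated.
#' @param r2_max r-squared threshold (default 0.001).
#' @param window_kb distance window in kilobases (default 10000).
#' @param ld optional function `(snp_a, snp_b) -> r2` providing pairwise LD
#'   from an external reference panel.
#' @return Subset [gwas_sumstats()] of retained index SNPs.
#' @export
clump <- function(records, r2_max = 0.001, window_kb = 10000, ld = NULL) {
  stopifnot(inherits(records, "gwas_sumstats"))
  n <- nrow(records)
  if (n <= 1L) return(records)
  ord <- order(records$P)
  accepted <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in accepted) {
      if (records$CHR[i] == records$CHR[j] &&
          abs(records$BP[i] - records$BP[j]) <= window_kb * 1000) {
        if (is.null(ld) || ld(records$SNP[i], records$SNP[j]) > r2_max) {
          conflict <- TRUE
          break
        }
      }
    }
    if (!conflict) accepted <- c(accepted, i)
  }
  .subset_sumstats(records, sort(accepted))
}

#' Single-SNP instrument-strength F-statistic
#'
#' Criterion (5): the summary-statistic approximation F = (beta/se)^2. By
#' rule of thumb, instruments with F below 10 are considered weak.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return F-statistic(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Remove weak instruments
#'
#' Criterion (5): remove harmonized rows whose exposure F-statistic
#' `(beta_x/se_x)^2` is strictly below `f_min`.
#'
#' @param h a `harmonized_set`.
#' @param f_min minimum F (default 10).
#' @return Filtered `harmonized_set`.
#' @export
filter_weak_instruments <- function(h, f_min = 10) {
  stopifnot(inherits(h, "harmonized_set"))
  if (nrow(h) == 0L) return(h)
  .subset_harmonized(h, !(f_statistic(h$beta_x, h$se_x) < f_min))
}

#' Exclude listed SNPs
#'
#' Removes instruments on a user-supplied exclusion list -- typically
#' variants known to associate with confounders of the exposure-outcome
#' relationship (e.g. alcohol and tobacco use for liver cancer).
#'
#' @param h a `harmonized_set`.
#' @param excluded character vector of SNP ids.
#' @param quiet suppress the removal message.
#' @return Filtered `harmonized_set`.
#' @export
exclude_snps <- function(h, excluded, quiet = FALSE) {
  stopifnot(inherits(h, "harmonized_set"))
  drop <- h$SNP %in% excluded
  if (any(drop) && !quiet) {
    message(sprintf("excluded %d listed SNP(s)", sum(drop)))
  }
  .subset_harmonized(h, !drop)
}

#' Read a SNP exclusion list
#'
#' One SNP id per line; blank lines and `#` comments ignored.
#'
#' @param path text file path.
#' @return Character vector of SNP ids.
#' @export
read_snp_exclusion_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
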