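#' Reported hepatocellular-carcinoma MR worked examples
#'
#' Two small tables of causal estimates reported by a published two-sample
#' MR and mediation study of immune cell traits, plasma metabolites and
#' hepatocellular carcinoma (HCC) in East Asians, shipped as worked
#' examples for the package's scale-conversion and mediation calculus.
#'
#' `hcc_reported_or()` returns metabolite -> HCC odds ratios with 95%
#' confidence intervals and the reported p-values. `hcc_reported_mediation()`
#' returns the mediation table: per exposure-mediator-outcome triple the
#' mediated effect with its 95% CI, the mediation proportion in percent,
#' and the reported p-value. The reported CD19 on PB/PC -> HCC total effect
#' is OR 1.224 (`hcc_cd19_total_or()`), the denominator of the 19.3%
#' proportion example.
#'
#' Values are transcribed at their published precision; CI endpoints
#' carrying very few significant digits limit how exactly normal-theory
#' p-values can be reconstructed from them (see
#' `vignette("mr-mediation")`).
#'
#' @return data.frame (see above).
#' @export
hcc_reported_or <- function() {
  utils::read.delim(system.file("extdata", "hcc_reported_or.tsv",
                                package = "mrmediate"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname hcc_reported_or
#' @export
hcc_reported_mediation <- function() {
  utils::read.delim(system.file("extdata", "hcc_reported_mediation.tsv",
                                package = "mrmediate"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname hcc_reported_or
#' @export
hcc_cd19_total_or <- function() 1.224

#' Reconstruct normal-theory p-values from reported estimate/CI pairs
#'
#' For a table of reported estimates with symmetric normal confidence
#' intervals, recovers the implied standard error via [se_from_ci()] and
#' the two-sided normal p-value via [pval_from_estimate()] -- an
#' internal-consistency check on published result tables.
#'
#' @param estimate point estimates (odds ratios when `log_scale = TRUE`,
#'   otherwise additive effects).
#' @param lo,hi 95% CI endpoints.
#' @param log_scale `TRUE` when estimate and CI are on the ratio scale.
#' @return data.frame with columns `se` and `pval`.
#' @export
reconstruct_pvalues <- function(estimate, lo, hi, log_scale = FALSE) {
  se <- se_from_ci(lo, hi, log_scale = log_scale)
  eff <- if (log_scale) log(estimate) else estimate
  data.frame(se = se, pval = pval_from_estimate(eff, se))
}
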