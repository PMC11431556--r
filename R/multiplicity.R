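#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and returned in
#' the input order (delegates to `stats::p.adjust(method = "BH")` after
#' validating the input range).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Evidence tier from an FDR q-value
#'
#' Classifies each association: `"strong"` for q < 0.05, `"suggestive"` for
#' 0.05 <= q < 0.20, `"none"` otherwise.
#'
#' @param q numeric vector of q-values in \[0, 1\].
#' @return Character vector of tier labels.
#' @export
assign_tier <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) stop("q must lie in [0, 1]")
  ifelse(q < 0.05, "strong", ifelse(q < 0.20, "suggestive", "none"))
}
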