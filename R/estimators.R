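#' @title Two-sample MR causal estimators
#' @description
#' The five estimators applied to a harmonized instrument set: inverse
#' variance weighted (IVW, the primary method), MR-Egger, weighted median,
#' and the weighted and simple mode-based estimators, plus the single-SNP
#' Wald ratio fallback. Each returns an `mr_estimate` carrying the causal
#' effect on the log scale (log-odds per unit exposure for a binary
#' outcome), its standard error, a two-sided normal-theory p-value, and the
#' odds-ratio scale with its confidence interval.
#' @name mr-estimators
NULL

.mr_estimate <- function(method, beta, se, n_snp, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  structure(list(method = method, beta = beta, se = se,
                 pval = pval_from_estimate(beta, se),
                 ci_low = ci_low, ci_high = ci_high,
                 or_point = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
                 n_snp = as.integer(n_snp)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$or_point, x$or_low, x$or_high,
              x$pval, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, or = x$or_point,
             or_low = x$or_low, or_high = x$or_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

#' Two-sided normal-theory p-value
#'
#' @param beta effect estimate.
#' @param se standard error, strictly positive.
#' @return `2 * pnorm(-|beta/se|)`, floored at the smallest positive double.
#' @export
pval_from_estimate <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

#' Convert a log-scale estimate to the odds-ratio scale
#'
#' @param beta log odds ratio.
#' @param se its standard error.
#' @param level confidence level (default 0.95).
#' @return List with `or_point`, `or_low`, `or_high`.
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  stopifnot(se > 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  list(or_point = exp(beta), or_low = exp(beta - z * se), or_high = exp(beta + z * se))
}

#' Recover the standard error implied by a reported confidence interval
#'
#' Inverts the symmetric normal interval: on the ratio scale (odds or
#' hazard ratios), `se = (log(hi) - log(lo)) / (2 z)`; on an additive scale,
#' `se = (hi - lo) / (2 z)`. Together with [pval_from_estimate()] this
#' reconstructs the p-value implied by a published estimate/CI pair, a
#' useful internal-consistency check on reported results.
#'
#' @param lo,hi interval endpoints.
#' @param level confidence level of the interval (default 0.95).
#' @param log_scale `TRUE` when the interval is on a ratio scale.
#' @return Implied standard error.
#' @export
se_from_ci <- function(lo, hi, level = 0.95, log_scale = FALSE) {
  z <- stats::qnorm((1 + level) / 2)
  if (log_scale) (log(hi) - log(lo)) / (2 * z) else (hi - lo) / (2 * z)
}

#' Wald ratio for a single instrument
#'
#' `beta_y / beta_x` with the first-order standard error `|se_y / beta_x|`
#' (exposure uncertainty ignored, the usual leading-order approximation).
#'
#' @param beta_x,se_x exposure association and its standard error.
#' @param beta_y,se_y outcome association and its standard error.
#' @return An `mr_estimate` with `n_snp = 1`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("wald_ratio undefined for beta_x = 0")
  .mr_estimate("wald_ratio", beta_y / beta_x, abs(se_y / beta_x), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Weighted average of per-SNP Wald ratios with outcome-variance weights,
#' equivalently the slope of a zero-intercept regression of `beta_y` on
#' `beta_x` with weights `1/se_y^2`:
#' `beta = sum(w beta_x beta_y) / sum(w beta_x^2)`.
#' The fixed-effect standard error is `1/sqrt(sum(w beta_x^2))`; the default
#' multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q/(k-1)))`, with Q Cochran's heterogeneity statistic at the
#' IVW estimate, making the test robust to balanced heterogeneity.
#'
#' @param h a `harmonized_set` with at least 2 SNPs (use [wald_ratio()] for
#'   a single instrument).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate`.
#' @export
ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(h, "harmonized_set"))
  k <- nrow(h)
  if (k < 2L) stop("ivw requires k >= 2 instruments; use wald_ratio() for k = 1")
  w <- 1 / h$se_y^2
  sxx <- sum(w * h$beta_x^2)
  beta <- sum(w * h$beta_x * h$beta_y) / sxx
  se <- sqrt(1 / sxx)
  if (model == "multiplicative_random") {
    q <- sum(w * (h$beta_y - beta * h$beta_x)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  .mr_estimate("ivw", beta, se, k)
}

# orient rows so beta_x >= 0 (the standard Egger convention)
.orient_positive <- function(h) {
  s <- ifelse(h$beta_x < 0, -1, 1)
  list(bx = abs(h$beta_x), by = s * h$beta_y)
}

#' MR-Egger regression
#'
#' Weighted regression of `beta_y` on `beta_x` with a free intercept and
#' weights `1/se_y^2`, after orienting every instrument to a non-negative
#' exposure effect. The slope is the pleiotropy-adjusted causal estimate;
#' the intercept estimates the average directional pleiotropic effect and a
#' nonzero intercept signals violation of the exclusion restriction.
#' Standard errors use multiplicative over-dispersion inflation
#' `max(1, sqrt(Q'/(k-2)))`; p-values are two-sided normal.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return List with `slope` (an `mr_estimate`), `intercept`,
#'   `intercept_se`, `intercept_pval`, and the residual heterogeneity
#'   statistic `q`.
#' @export
egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  k <- nrow(h)
  if (k < 3L) stop("egger requires k >= 3 instruments")
  o <- .orient_positive(h)
  w <- 1 / h$se_y^2
  sw <- sum(w); sx <- sum(w * o$bx); sy <- sum(w * o$by)
  sxx <- sum(w * o$bx^2); sxy <- sum(w * o$bx * o$by)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  resid <- o$by - intercept - slope * o$bx
  q <- sum(w * resid^2)
  infl <- max(1, sqrt(q / (k - 2)))
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(sxx / det) * infl
  list(slope = .mr_estimate("egger", slope, se_slope, k),
       intercept = intercept, intercept_se = se_int,
       intercept_pval = pval_from_estimate(intercept, se_int),
       q = q)
}

# weighted median of values x with weights w by cumulative-weight
# interpolation at 0.5
.weighted_median_scan <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] < 0.5) return(x[length(x)])
  below <- max(which(s < 0.5))
  x[below] + (x[below + 1] - x[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

.ratio_inputs <- function(h, quiet = FALSE) {
  keep <- h$beta_x != 0
  if (any(!keep)) {
    if (!quiet) warning(sprintf("dropped %d SNP(s) with beta_x = 0", sum(!keep)))
    h <- .subset_harmonized(h, keep)
  }
  h
}

#' Weighted median estimator
#'
#' The weighted median of per-SNP Wald ratios, with weights proportional to
#' the inverse variance of each ratio (`beta_x^2/se_y^2`). Consistent when
#' instruments carrying at least half the weight are valid, so a minority of
#' pleiotropic variants cannot drag the estimate. The standard error comes
#' from a seeded parametric bootstrap: `beta_x` and `beta_y` are redrawn
#' from normals centred at their estimates with their reported standard
#' errors, and the estimator recomputed.
#'
#' @param h a `harmonized_set` with at least 3 SNPs; SNPs with `beta_x = 0`
#'   are dropped with a warning.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonized_set"))
  h <- .ratio_inputs(h)
  k <- nrow(h)
  if (k < 3L) stop("weighted_median requires k >= 3 instruments")
  r <- h$beta_y / h$beta_x
  w <- h$beta_x^2 / h$se_y^2
  est <- .weighted_median_scan(r, w)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, h$beta_x, h$se_x)
      by <- stats::rnorm(k, h$beta_y, h$se_y)
      ok <- bx != 0
      .weighted_median_scan(by[ok] / bx[ok], bx[ok]^2 / h$se_y[ok]^2)
    }, numeric(1))
  })
  .mr_estimate("weighted_median", est, stats::sd(boots), k)
}

# kernel-density ratio mode on a fixed grid; returns the argmax
.mode_scan <- function(r, w, phi) {
  k <- length(r)
  spread <- min(stats::sd(r), stats::IQR(r) / 1.349)
  if (!is.finite(spread) || spread == 0) {
    alt <- c(stats::sd(r), stats::IQR(r) / 1.349)
    alt <- alt[is.finite(alt) & alt > 0]
    if (length(alt) == 0) return(list(mode = r[1], degenerate = TRUE))
    spread <- min(alt)
  }
  bw <- phi * 0.9 * spread * k^(-1 / 5)
  grid <- seq(mean(r) - 5 * stats::sd(r), mean(r) + 5 * stats::sd(r),
              length.out = 10000L)
  dens <- colSums(w * stats::dnorm(outer(r, grid, "-") / bw))
  list(mode = grid[which.max(dens)], degenerate = FALSE)
}

#' Mode-based estimators (simple and weighted)
#'
#' The mode of the per-SNP Wald ratio distribution, estimated as the argmax
#' of a normal-kernel density over a fixed grid of 10,000 points spanning
#' the ratio mean +/- 5 SD. Bandwidth is
#' `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`. The simple mode weights all
#' ratios equally; the weighted mode uses inverse-variance weights
#' `beta_x^2/se_y^2`. Consistent when the largest group of instruments
#' sharing the same ratio is valid (the "plurality valid" assumption).
#' Standard error by seeded parametric bootstrap.
#'
#' If all ratios are identical the bandwidth degenerates to zero; the common
#' ratio is returned with `se = 0` and a warning.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param weighted `TRUE` for the weighted mode (default), `FALSE` for the
#'   simple mode.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mode_estimate <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonized_set"))
  h <- .ratio_inputs(h)
  k <- nrow(h)
  if (k < 3L) stop("mode_estimate requires k >= 3 instruments")
  method <- if (weighted) "weighted_mode" else "simple_mode"
  r <- h$beta_y / h$beta_x
  w <- if (weighted) h$beta_x^2 / h$se_y^2 else rep(1, k)
  if (max(r) == min(r)) {
    warning("all ratios identical; mode is the common ratio with se 0")
    est <- .mr_estimate(method, r[1], .Machine$double.xmin, k)
    est$se <- 0
    est$ci_low <- est$ci_high <- r[1]
    est$or_low <- est$or_high <- exp(r[1])
    est$pval <- if (r[1] == 0) 1 else .Machine$double.xmin
    return(est)
  }
  est <- .mode_scan(r, w, phi)$mode
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, h$beta_x, h$se_x)
      by <- stats::rnorm(k, h$beta_y, h$se_y)
      ok <- bx != 0
      rb <- by[ok] / bx[ok]
      wb <- if (weighted) bx[ok]^2 / h$se_y[ok]^2 else rep(1, sum(ok))
      if (max(rb) == min(rb)) rb[1] else .mode_scan(rb, wb, phi)$mode
    }, numeric(1))
  })
  .mr_estimate(method, est, stats::sd(boots), k)
}

#' Run all five estimators on one harmonized set
#'
#' Applies IVW, MR-Egger, weighted median, weighted mode and simple mode
#' (falling back to the Wald ratio when only one instrument is available,
#' and reporting only the feasible methods for k = 2).
#'
#' @param h a `harmonized_set`.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed integer seed for bootstrap resampling.
#' @param ivw_model IVW variance model, see [ivw()].
#' @return data.frame with one row per method (columns as
#'   `as.data.frame.mr_estimate`).
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 1L,
                           ivw_model = "multiplicative_random") {
  k <- nrow(h)
  if (k == 0L) stop("empty harmonized set")
  if (k == 1L) {
    return(as.data.frame(wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y)))
  }
  out <- list(as.data.frame(ivw(h, model = ivw_model)))
  if (k >= 3L) {
    out <- c(out, list(
      as.data.frame(egger(h)$slope),
      as.data.frame(weighted_median(h, n_boot = n_boot, seed = seed)),
      as.data.frame(mode_estimate(h, weighted = TRUE, n_boot = n_boot, seed = seed + 1L)),
      as.data.frame(mode_estimate(h, weighted = FALSE, n_boot = n_boot, seed = seed + 2L))
    ))
  }
  do.call(rbind, out)
}
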