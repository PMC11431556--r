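# Fixture builders and independent oracle implementations used across the
# suite. Oracles are deliberately written with a different computational
# route (lm fits, explicit loops) than the package's estimators.

make_h <- function(beta_x, se_x, beta_y, se_y,
                   snp = sprintf("rs%03d", seq_along(beta_x))) {
  structure(data.frame(
    SNP = snp, CHR = "1", BP = seq_along(beta_x) * 2e7,
    EA = "A", OA = "G", eaf_x = 0.3,
    beta_x = beta_x, se_x = se_x,
    pval_x = 2 * pnorm(-abs(beta_x / se_x)),
    beta_y = beta_y, se_y = se_y,
    pval_y = 2 * pnorm(-abs(beta_y / se_y)),
    stringsAsFactors = FALSE
  ), exposure_id = "X", outcome_id = "Y",
  class = c("harmonized_set", "data.frame"))
}

# harmonized set with a single true ratio and gaussian noise
rand_h <- function(k, seed, ratio = 0.3, noise = 1) {
  withr::with_seed(seed, {
    bx <- rnorm(k, 0, 0.3)
    bx[abs(bx) < 0.05] <- 0.05
    sex <- runif(k, 0.01, 0.05)
    sey <- runif(k, 0.02, 0.1)
    by <- ratio * bx + noise * rnorm(k, 0, sey)
    make_h(bx, sex, by, sey)
  })
}

make_ss <- function(df, trait = "T1", type = "continuous") {
  defaults <- data.frame(SNP = sprintf("rs%03d", seq_len(nrow(df))),
                         CHR = "1", BP = seq_len(nrow(df)) * 2e7,
                         EA = "A", OA = "G", EAF = 0.3, BETA = 0.1,
                         SE = 0.02, P = 0.5, N = 1000,
                         stringsAsFactors = FALSE)
  for (cc in names(df)) defaults[[cc]] <- df[[cc]]
  suppressMessages(gwas_sumstats(defaults, trait_id = trait, trait_type = type))
}

# weighted least squares through the origin, via lm
oracle_ivw <- function(h, model = "fixed") {
  w <- 1 / h$se_y^2
  fit <- lm(beta_y ~ 0 + beta_x, data = as.data.frame(h), weights = w)
  sm <- summary(fit)
  beta <- unname(coef(fit)[1])
  sigma <- sm$sigma
  se_fixed <- unname(sm$coefficients[1, 2]) / sigma
  se <- if (model == "fixed") se_fixed else se_fixed * max(1, sigma)
  list(beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)))
}

# weighted regression with intercept after orienting beta_x >= 0, via lm
oracle_egger <- function(h) {
  s <- ifelse(h$beta_x < 0, -1, 1)
  d <- data.frame(bx = abs(h$beta_x), by = s * h$beta_y)
  w <- 1 / h$se_y^2
  fit <- lm(by ~ bx, data = d, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- max(1, sigma)
  list(slope = unname(coef(fit)[2]),
       slope_se = unname(sm$coefficients[2, 2]) / sigma * infl,
       intercept = unname(coef(fit)[1]),
       intercept_se = unname(sm$coefficients[1, 2]) / sigma * infl)
}

# brute-force cumulative-weight scan for the weighted median
oracle_weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  total <- sum(w)
  s <- numeric(length(r))
  acc <- 0
  for (j in seq_along(r)) {
    s[j] <- (acc + w[j] / 2) / total
    acc <- acc + w[j]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] < 0.5) return(r[length(r)])
  j <- 1
  while (s[j + 1] < 0.5) j <- j + 1
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# exhaustive double-loop kernel density argmax on the estimator's grid
oracle_mode <- function(r, w, phi = 1) {
  k <- length(r)
  bw <- phi * 0.9 * min(sd(r), IQR(r) / 1.349) * k^(-1 / 5)
  grid <- seq(mean(r) - 5 * sd(r), mean(r) + 5 * sd(r), length.out = 10000L)
  best_x <- grid[1]
  best_d <- -Inf
  for (g in grid) {
    d <- 0
    for (j in seq_len(k)) {
      d <- d + w[j] * exp(-((g - r[j]) / bw)^2 / 2) / sqrt(2 * pi)
    }
    if (d > best_d) {
      best_d <- d
      best_x <- g
    }
  }
  best_x
}

# step-up FDR by the definitional min-over-tails loop
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, ps[j] * m / j)
    q[i] <- min(c(vals, 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# row-subset a harmonized set preserving class and ids
.subset_harmonized_test <- function(h, idx) {
  out <- as.data.frame(h)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, exposure_id = attr(h, "exposure_id"),
            outcome_id = attr(h, "outcome_id"),
            class = c("harmonized_set", "data.frame"))
}

# explicit residual-sum loop for Cochran's Q
oracle_q <- function(h, method = "ivw") {
  w <- 1 / h$se_y^2
  if (method == "ivw") {
    beta <- sum(w * h$beta_x * h$beta_y) / sum(w * h$beta_x^2)
    fitted <- beta * h$beta_x
  } else {
    e <- oracle_egger(h)
    s <- ifelse(h$beta_x < 0, -1, 1)
    fitted <- s * (e$intercept + e$slope * abs(h$beta_x))
  }
  q <- 0
  for (j in seq_len(nrow(h))) q <- q + w[j] * (h$beta_y[j] - fitted[j])^2
  q
}
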