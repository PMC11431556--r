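test_that("the Wald ratio is definitional arithmetic with first-order se", {
  est <- wald_ratio(0.5, 0.02, 0.1, 0.05)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$n_snp, 1L)
  expect_equal(wald_ratio(0.5, 0.02, 0, 0.05)$beta, 0)
  expect_equal(wald_ratio(-0.5, 0.02, 0.1, 0.05)$beta, -0.2)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.05), "beta_x")
})

test_that("IVW with equal weights is the mean of ratios and needs k >= 2", {
  h <- make_h(c(1, 1), c(0.01, 0.01), c(0.1, 0.3), c(1, 1))
  expect_equal(ivw(h)$beta, 0.2)
  expect_error(ivw(make_h(1, 0.01, 0.1, 1)), "k >= 2")
})

test_that("IVW equals an independent weighted-least-squares fit", {
  for (s in 1:20) {
    h <- rand_h(k = 5 + s %% 10, seed = s)
    for (model in c("fixed", "multiplicative_random")) {
      mine <- ivw(h, model = model)
      ref <- oracle_ivw(h, model = model)
      expect_equal(mine$beta, ref$beta, tolerance = 1e-10)
      expect_equal(mine$se, ref$se, tolerance = 1e-10)
      expect_equal(mine$pval, ref$pval, tolerance = 1e-10)
    }
  }
})

test_that("Egger slope and intercept equal an independent weighted regression", {
  for (s in 1:10) {
    h <- rand_h(k = 6 + s, seed = 100 + s)
    mine <- egger(h)
    ref <- oracle_egger(h)
    expect_equal(mine$slope$beta, ref$slope, tolerance = 1e-10)
    expect_equal(mine$slope$se, ref$slope_se, tolerance = 1e-10)
    expect_equal(mine$intercept, ref$intercept, tolerance = 1e-10)
    expect_equal(mine$intercept_se, ref$intercept_se, tolerance = 1e-10)
  }
  expect_error(egger(make_h(c(1, 1), c(0.1, 0.1), c(0.1, 0.2), c(1, 1))),
               "k >= 3")
})

test_that("Egger separates a uniform directional pleiotropic shift from the slope", {
  cfg <- simulation_config(seed = 418, n_snp = 80, prop_causal = 1,
                           prop_causal_mediator = 0, theta_xm = 0,
                           theta_my = 0, theta_xy_direct = 0,
                           pleiotropy_frac = 1, pleiotropy_mean = 0.02,
                           pleiotropy_sd = 0, n_exposure = 10000,
                           n_mediator = 10000, n_outcome = 10000)
  sim <- simulate_triple(cfg)
  leg <- mr_leg(sim$exposure, sim$outcome,
                instrument_config(outcome_p_threshold = 0))
  e <- egger(leg$h)
  expect_lt(abs(e$intercept - 0.02), 3 * e$intercept_se)
  expect_lt(abs(e$slope$beta), 3 * e$slope$se)
})

test_that("the weighted median is the cumulative-weight interpolation at 0.5", {
  h <- make_h(c(1, 1, 1), c(0.01, 0.01, 0.01), c(0.1, 0.2, 0.9), c(1, 1, 1))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 0.2)
  for (s in 1:20) {
    h <- rand_h(k = 4 + s %% 8, seed = 200 + s)
    r <- h$beta_y / h$beta_x
    w <- h$beta_x^2 / h$se_y^2
    expect_equal(weighted_median(h, n_boot = 10, seed = 1)$beta,
                 oracle_weighted_median(r, w), tolerance = 1e-10)
  }
})

test_that("the weighted median resists up to half the weight being pleiotropic", {
  withr::with_seed(77, {
    k <- 51
    bx <- rep(0.2, k)  # equal instrument strength: pleiotropic weight 25/51
    sey <- rep(0.002, k)
    by <- 0.3 * bx + rnorm(k, 0, sey)
    shifted <- seq_len(25)  # 49% of instruments (and of the weight)
    by[shifted] <- by[shifted] + 1.0 * bx[shifted]
    h <- make_h(bx, rep(0.001, k), by, sey)
  })
  est <- weighted_median(h, n_boot = 200, seed = 5)
  naive <- ivw(h)
  # just under half the weight is shifted by +1.0: the median stays near the
  # truth while IVW is dragged roughly halfway to the contaminated ratio
  expect_lt(abs(est$beta - 0.3), 0.05)
  expect_gt(abs(naive$beta - 0.3), 0.3)
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- make_h(rep(1, 3), rep(0.01, 3), rep(0.25, 3), rep(0.05, 3))
  expect_warning(est <- mode_estimate(h, n_boot = 10, seed = 1),
                 "identical")
  expect_equal(est$beta, 0.25)
  expect_equal(est$se, 0)

  h2 <- make_h(rep(1, 4), rep(0.01, 4), c(0.2, 0.21, 0.19, 5), rep(0.05, 4))
  est2 <- mode_estimate(h2, weighted = FALSE, n_boot = 50, seed = 1)
  expect_lt(abs(est2$beta - 0.2), 0.1)
})

test_that("mode argmax equals an exhaustive fine-grid density evaluation", {
  for (s in 1:20) {
    h <- rand_h(k = 5 + s %% 6, seed = 300 + s)
    r <- h$beta_y / h$beta_x
    for (weighted in c(TRUE, FALSE)) {
      w <- if (weighted) h$beta_x^2 / h$se_y^2 else rep(1, nrow(h))
      mine <- mode_estimate(h, weighted = weighted, n_boot = 2, seed = 1)
      expect_equal(mine$beta, oracle_mode(r, w), tolerance = 1e-10)
    }
  }
})

test_that("odds-ratio conversion matches reported interval arithmetic", {
  null <- to_odds_ratio(0, 0.1)
  expect_equal(null$or_point, 1)
  expect_equal(null$or_low * null$or_high, 1, tolerance = 1e-12)
  ci <- to_odds_ratio(log(1.901), 0.2281907)
  expect_equal(ci$or_low, 1.215, tolerance = 1e-3)
  expect_equal(ci$or_high, 2.973, tolerance = 1e-3)
  expect_true(ci$or_low < ci$or_point && ci$or_point < ci$or_high)
})

test_that("normal-theory p-values follow the z-score identities", {
  expect_equal(pval_from_estimate(0, 1), 1)
  expect_equal(pval_from_estimate(1.959964, 1), 0.05, tolerance = 1e-6)
  se <- se_from_ci(1.215, 2.972, log_scale = TRUE)
  expect_lt(abs(pval_from_estimate(log(1.901), se) - 0.005), 2e-4)
})

test_that("all estimators are scale- and sign-equivariant", {
  h <- rand_h(k = 12, seed = 55)
  ests <- function(h, seed = 7) {
    c(ivw = ivw(h)$beta,
      egger = egger(h)$slope$beta,
      wm = weighted_median(h, n_boot = 2, seed = seed)$beta,
      wmode = mode_estimate(h, TRUE, n_boot = 2, seed = seed)$beta,
      smode = mode_estimate(h, FALSE, n_boot = 2, seed = seed)$beta)
  }
  base <- ests(h)
  hc <- h
  hc$beta_x <- 2.5 * h$beta_x
  hc$se_x <- 2.5 * h$se_x
  expect_equal(ests(hc), base / 2.5, tolerance = 1e-8)
  hn <- h
  hn$beta_y <- -h$beta_y
  expect_equal(ests(hn), -base, tolerance = 1e-8)
})

test_that("with a single noise-free ratio every estimator returns it exactly", {
  # power-of-two exposure effects keep the ratios bitwise identical
  bx <- c(0.25, -0.5, 1, 0.125, -2)
  h <- make_h(bx, rep(0.01, 5), 0.37 * bx, rep(0.02, 5))
  expect_equal(ivw(h)$beta, 0.37, tolerance = 1e-12)
  expect_equal(egger(h)$slope$beta, 0.37, tolerance = 1e-12)
  expect_equal(weighted_median(h, n_boot = 2, seed = 1)$beta, 0.37,
               tolerance = 1e-12)
  expect_warning(m <- mode_estimate(h, n_boot = 2, seed = 1), "identical")
  expect_equal(m$beta, 0.37, tolerance = 1e-12)
  expect_equal(wald_ratio(h$beta_x[1], h$se_x[1], h$beta_y[1], h$se_y[1])$beta,
               0.37, tolerance = 1e-12)
})

test_that("mr_all_methods degrades gracefully with instrument count", {
  h1 <- make_h(0.2, 0.01, 0.05, 0.02)
  expect_equal(mr_all_methods(h1)$method, "wald_ratio")
  h2 <- make_h(c(0.2, 0.3), c(0.01, 0.01), c(0.05, 0.08), c(0.02, 0.02))
  expect_equal(mr_all_methods(h2)$method, "ivw")
  h5 <- rand_h(6, seed = 4)
  expect_setequal(mr_all_methods(h5, n_boot = 5, seed = 2)$method,
                  c("ivw", "egger", "weighted_median", "weighted_mode",
                    "simple_mode"))
})
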