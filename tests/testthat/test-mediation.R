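test_that("the product-of-coefficients effect follows the delta method", {
  null <- mediated_effect(0, 0.01, 0.5, 0.1)
  expect_equal(null$mediated, 0)
  expect_equal(null$pval, 2 * pnorm(-abs(0 / null$se)))
  m <- mediated_effect(0.4, 0.05, 0.3, 0.08)
  expect_equal(m$mediated, 0.12)
  expect_equal(m$se, sqrt(0.4^2 * 0.08^2 + 0.3^2 * 0.05^2))
  expect_equal(m$ci_high - m$ci_low, 2 * qnorm(0.975) * m$se)
})

test_that("the delta-method se matches a Monte-Carlo product distribution", {
  b1 <- 0.4; s1 <- 0.05; b2 <- 0.3; s2 <- 0.08
  m <- mediated_effect(b1, s1, b2, s2)
  emp <- withr::with_seed(12, sd(rnorm(1e5, b1, s1) * rnorm(1e5, b2, s2)))
  expect_lt(abs(m$se - emp) / emp, 0.02)
})

test_that("a reported mediated effect and CI imply its p-value", {
  # effect -0.0188 with 95% CI (-0.0335, -0.0040)
  se <- se_from_ci(-0.0335, -0.0040)
  expect_equal(se, 0.0295 / (2 * qnorm(0.975)), tolerance = 1e-10)
  p <- pval_from_estimate(-0.0188, se)
  expect_equal(p, 0.012485, tolerance = 1e-4)
})

test_that("effect decomposition identities hold exactly", {
  expect_equal(direct_effect(0.2, 0.2), 0)
  expect_equal(direct_effect(0.2, 0), 0.2)
  expect_equal(direct_effect(0.2021, 0.0389), 0.1632)
  expect_equal(mediation_proportion(0.0389, log(1.224)), 19.24559,
               tolerance = 1e-5)
  expect_equal(mediation_proportion(0.2, 0.2), 100)
  expect_equal(mediation_proportion(0, 0.2), 0)
  expect_error(mediation_proportion(0.1, 0), "total")
  expect_warning(mediation_proportion(-0.1, 0.2), "suppression")
  # mediated + direct = total; proportion * total / 100 = mediated
  m <- mediated_effect(0.4, 0.05, 0.3, 0.08)
  total <- 0.22
  expect_equal(m$mediated + direct_effect(total, m$mediated), total)
  expect_equal(mediation_proportion(m$mediated, total) * total / 100,
               m$mediated)
})

test_that("the mediated effect is symmetric in its two legs", {
  a <- mediated_effect(0.4, 0.05, -0.3, 0.08)
  b <- mediated_effect(-0.3, 0.08, 0.4, 0.05)
  expect_equal(a$mediated, b$mediated)
  expect_equal(a$se, b$se)
  expect_equal(a$pval, b$pval)
})

test_that("proportion intervals are returned sorted and cover the point", {
  ci <- proportion_ci(0.12, 0.03, 0.22, 0.04)
  expect_lt(ci[1], ci[2])
  prop <- 100 * 0.12 / 0.22
  expect_true(ci[1] < prop && prop < ci[2])
  cib <- proportion_ci(0.12, 0.03, 0.22, 0.04, method = "bootstrap",
                       n_boot = 5000, seed = 3)
  expect_lt(cib[1], cib[2])
})

test_that("run_mediation recovers a known decomposition and is deterministic", {
  cfg <- instrument_config(outcome_p_threshold = 0)
  sims <- lapply(1:10, function(s) {
    simulate_triple(simulation_config(seed = s, n_exposure = 10000,
                                      n_mediator = 10000, n_outcome = 10000))
  })
  res <- lapply(seq_along(sims), function(i) {
    run_mediation(sims[[i]]$exposure, sims[[i]]$mediator, sims[[i]]$outcome,
                  cfg, seed = i)
  })
  props <- vapply(res, `[[`, numeric(1), "proportion_pct")
  mcse <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - sims[[1]]$truth$proportion_pct), 4 * mcse)
  # identities on assembled results
  r <- res[[1]]
  expect_equal(r$mediated, r$beta1 * r$beta2)
  expect_equal(r$mediated + r$direct, r$total)
  # determinism: identical inputs, config and seed give identical results
  again <- run_mediation(sims[[1]]$exposure, sims[[1]]$mediator,
                         sims[[1]]$outcome, cfg, seed = 1)
  expect_identical(as.data.frame(again), as.data.frame(res[[1]]))
})

test_that("a null exposure->mediator path gives calibrated mediated p-values", {
  cfg <- instrument_config(outcome_p_threshold = 0)
  ps <- vapply(1:150, function(s) {
    sim <- simulate_triple(simulation_config(
      seed = 5000 + s, theta_xm = 0, n_exposure = 10000,
      n_mediator = 10000, n_outcome = 10000))
    run_mediation(sim$exposure, sim$mediator, sim$outcome, cfg,
                  seed = s)$mediated_pval
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
})

test_that("legs without instruments withhold the result with a reason", {
  sim <- simulate_triple(simulation_config(seed = 8, prop_causal = 0,
                                           prop_causal_mediator = 0.25))
  res <- run_mediation(sim$exposure, sim$mediator, sim$outcome,
                       instrument_config())
  expect_match(res$status, "withheld")
  expect_match(res$status, "beta1")
})
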