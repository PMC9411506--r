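# Monte Carlo sampling and propagation.

test_that("sample_ef is deterministic, degenerate at sd 0, and honours bounds", {
  spec <- ef_spec("x", 0.010, 0.009, 0.001, 0.018, "normal")
  a <- sample_ef(spec, 1000, seed = 42)
  b <- sample_ef(spec, 1000, seed = 42)
  expect_identical(a, b)
  expect_true(all(a >= 0.001 & a <= 0.018))

  flat <- ef_spec("flat", 0.5, 0)
  expect_equal(sample_ef(flat, 10, seed = 1), rep(0.5, 10))

  expect_error(
    sample_ef(ef_spec("neg", -0.01, 0.01, pdf = "lognormal"), 10, seed = 1),
    class = "fertghg_config_error")
})

test_that("truncated-normal draws match the closed-form truncated mean", {
  spec <- ef_spec("tier1", 0.010, 0.009, 0.001, 0.018, "normal")
  n <- 5000
  x <- sample_ef(spec, n, seed = 7)
  # independent oracle: closed-form mean of a normal truncated to [a, b]
  a <- (spec$min - spec$mean) / spec$sd
  b <- (spec$max - spec$mean) / spec$sd
  trunc_mean <- spec$mean +
    spec$sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  trunc_var <- spec$sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) /
                              (pnorm(b) - pnorm(a)) -
                              ((dnorm(a) - dnorm(b)) /
                                 (pnorm(b) - pnorm(a)))^2)
  se <- sqrt(trunc_var / n)
  expect_lt(abs(mean(x) - trunc_mean), 3 * se)
})

test_that("lognormal sampling is moment-matched on the natural scale", {
  spec <- ef_spec("ln", 2, 0.5, pdf = "lognormal")
  x <- sample_ef(spec, 2e5, seed = 3)
  expect_lt(abs(mean(x) - 2), 3 * 0.5 / sqrt(2e5))
  expect_lt(abs(sd(x) - 0.5), 0.02)
  expect_true(all(x > 0))
})

test_that("coefficient of variation is 100 sd/mean, missing at mean 0", {
  expect_equal(coefficient_of_variation(200, 50), 25)
  expect_equal(coefficient_of_variation(10, 0), 0)
  expect_true(is.na(coefficient_of_variation(0, 5)))
})

test_that("zero-uncertainty propagation collapses onto the deterministic engine", {
  act <- toy_activity(n = 2, n_consumption = c(100, 400))
  reg <- toy_registry(zero_sd = TRUE)
  det <- account_emissions(act, reg, "ipcc_tier1")
  mc <- propagate_uncertainty(act, reg, "ipcc_tier1", n = 200, seed = 9)
  glob <- mc[mc$scope == "global", ]
  expect_equal(glob$mean[glob$component == "total"],
               aggregate_emissions(det, "global")$total, tolerance = 1e-12)
  expect_equal(glob$sd, rep(0, nrow(glob)), tolerance = 1e-20)
  for (cmp in c("ghg_m", "ghg_d", "ghg_u")) {
    expect_equal(mc$mean[mc$scope == "C1" & mc$component == cmp],
                 det[[cmp]][det$country == "C1"], tolerance = 1e-12)
  }
})

test_that("identical seeds give identical MC results", {
  act <- toy_activity(n = 2)
  reg <- toy_registry()
  a <- propagate_uncertainty(act, reg, "ipcc_wetdry", n = 300, seed = 21)
  b <- propagate_uncertainty(act, reg, "ipcc_wetdry", n = 300, seed = 21)
  expect_identical(a$mean, b$mean)
  expect_identical(a$sd, b$sd)
  c_ <- propagate_uncertainty(act, reg, "ipcc_wetdry", n = 300, seed = 22)
  expect_false(identical(a$sd, c_$sd))
})

test_that("a single-EF component inherits that EF's CV; totals conserve per draw", {
  # one country, one product (AN), manufacturing EF the only uncertain input
  act <- toy_activity(n = 1, regions = "Europe", climates = "wet",
                      share_urea = 0, share_an = 1)
  tabs <- toy_ef_tables(regions = "Europe", sd_frac_m = 0, sd_frac_t = 0)
  an_row <- tabs$manufacturing$product == "AN"
  tabs$manufacturing$sd[an_row] <- 0.25 * tabs$manufacturing$mean[an_row]
  cfg <- list(
    direct_ef_schemes = list(ipcc_tier1 = list(mean = 0.01, sd = 0,
                                               min = 0.01, max = 0.01)),
    indirect_factors = list(
      wet = list(frac_gasf = list(sd = 0), ef4 = list(sd = 0),
                 frac_leach = list(sd = 0), ef5 = list(sd = 0)),
      dry = list(frac_gasf = list(sd = 0), ef4 = list(sd = 0),
                 frac_leach = list(sd = 0), ef5 = list(sd = 0))),
    urea_ef = list(sd = 0))
  reg <- load_registry(cfg, manufacturing_ef = tabs$manufacturing,
                       transport_ef = tabs$transport)
  mc <- propagate_uncertainty(act, reg, "ipcc_tier1", n = 5000, seed = 13,
                              keep_draws = TRUE)
  cv_m <- mc$cv[mc$scope == "global" & mc$component == "ghg_m"]
  se_cv <- 25 / sqrt(2 * 5000) * sqrt(1 + 2 * 0.25^2)
  expect_lt(abs(cv_m - 25), 3 * se_cv)
  draws <- attr(mc, "draws")
  expect_equal(draws[, "total"],
               rowSums(draws[, c("ghg_m", "ghg_t", "ghg_d", "ghg_v",
                                 "ghg_l", "ghg_u")]),
               tolerance = 1e-12)
})

test_that("MC means converge to the deterministic value for linear components", {
  act <- toy_activity(n = 2, n_consumption = c(100, 50))
  tabs <- toy_ef_tables()
  reg <- load_registry(manufacturing_ef = tabs$manufacturing,
                       transport_ef = tabs$transport)
  det <- aggregate_emissions(account_emissions(act, reg, "ipcc_tier1"),
                             "global")
  mc <- propagate_uncertainty(act, reg, "ipcc_tier1", n = 5000, seed = 31)
  glob <- mc[mc$scope == "global", ]
  m <- glob[glob$component == "ghg_m", ]
  # manufacturing EFs are untruncated lognormals here, so the MC mean is an
  # unbiased estimate of the deterministic value
  expect_lt(abs(m$mean - det$ghg_m), 3 * m$sd / sqrt(5000))
})
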