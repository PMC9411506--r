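# Empirical direct-EF estimation from paired plots.

make_raw <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(record_id = r[["id"]], country = r[["country"]],
               region = r[["region"]], crop = r[["crop"]],
               n_applied_kg_ha = r[["n"]], n2o_treated_kg_ha = r[["t"]],
               n2o_control_kg_ha = r[["c"]], climate = "wet",
               fertiliser_type = r[["type"]], stringsAsFactors = FALSE)
  }))
}

test_that("plot-level EF is the flux difference per unit N, sign preserved", {
  expect_equal(plot_level_ef(1.0, 1.0, 120), 0)
  expect_equal(plot_level_ef(1.5, 0.5, 100), 0.01)
  expect_equal(plot_level_ef(0.3, 0.5, 100), -0.002)
  expect_error(plot_level_ef(1, 0.5, 0), class = "fertghg_schema_error")
  expect_error(plot_level_ef(1, 0.5, -10), class = "fertghg_schema_error")
})

test_that("filtering keeps only usable synthetic pairs and logs reasons", {
  raw <- make_raw(
    list(id = "a", country = "FR", region = "Europe", crop = "wheat",
         n = 100, t = 1.2, c = 0.4, type = "synthetic"),
    list(id = "b", country = "FR", region = "Europe", crop = "maize",
         n = 150, t = 0.9, c = 0.3, type = "synthetic"),
    list(id = "c", country = "FR", region = "Europe", crop = "wheat",
         n = 100, t = 1.0, c = 0.4, type = "organic"),
    list(id = "d", country = "FR", region = "Europe", crop = "wheat",
         n = 100, t = 1.1, c = 0.4, type = "mixed"),
    list(id = "e", country = "FR", region = "Europe", crop = "wheat",
         n = 100, t = 1.2, c = 0.4, type = "synthetic")  # duplicate of a
  )
  kept <- filter_synthetic_plots(raw)
  expect_equal(nrow(kept), 2)
  log <- attr(kept, "filter_log")
  expect_equal(unname(log["non_synthetic"]), 2L)
  expect_equal(unname(log["duplicate"]), 1L)

  raw$n2o_control_kg_ha[1] <- NA
  kept2 <- filter_synthetic_plots(raw)
  expect_equal(unname(attr(kept2, "filter_log")["missing_control"]), 1L)

  expect_error(filter_synthetic_plots(raw[0, ]),
               class = "fertghg_schema_error")
  all_organic <- raw
  all_organic$fertiliser_type <- "organic"
  expect_error(filter_synthetic_plots(all_organic),
               class = "fertghg_schema_error")
})

test_that("country estimates are means/sample-sds of plot EFs", {
  raw <- make_raw(
    list(id = 1, country = "A", region = "Europe", crop = "w", n = 100,
         t = 1.0, c = 0.0, type = "synthetic"),
    list(id = 2, country = "A", region = "Europe", crop = "m", n = 100,
         t = 2.0, c = 0.0, type = "synthetic"),
    list(id = 3, country = "A", region = "Europe", crop = "r", n = 100,
         t = 3.0, c = 0.0, type = "synthetic"),
    list(id = 4, country = "B", region = "Europe", crop = "w", n = 100,
         t = 0.5, c = 0.0, type = "synthetic")
  )
  est <- estimate_country_efs(filter_synthetic_plots(raw))
  expect_equal(nrow(est), 2)
  a <- est[est$scope == "A", ]
  expect_equal(a$mean, 0.02)
  expect_equal(a$sd, sd(c(0.01, 0.02, 0.03)))
  expect_equal(a$n_points, 3)
  b <- est[est$scope == "B", ]
  expect_equal(b$mean, 0.005)
  expect_equal(b$sd, 0)   # single plot: sd 0 with a logged warning
  expect_equal(b$n_points, 1)
})

test_that("regional mean is the points-weighted mean of country means", {
  country_efs <- data.frame(
    level = "country", scope = c("A", "B"), region = "Europe",
    mean = c(0.01, 0.02), sd = c(0.001, 0), n_points = c(3L, 1L),
    pdf = "lognormal", stringsAsFactors = FALSE
  )
  reg <- estimate_regional_efs(country_efs)
  expect_equal(reg$mean, (0.01 * 3 + 0.02 * 1) / 4)
  expect_equal(reg$n_points, 4)
  expect_equal(reg$n_countries, 2)

  # single-country region: regional estimate equals the country estimate
  solo <- country_efs[1, ]
  reg1 <- estimate_regional_efs(solo)
  expect_equal(reg1$mean, solo$mean)
  expect_equal(reg1$n_points, solo$n_points)

  # weighted-mean property: regional mean within member-country range
  expect_gte(reg$mean, min(country_efs$mean))
  expect_lte(reg$mean, max(country_efs$mean))
})

test_that("global EF weights regions by their number of data countries", {
  regional <- data.frame(
    level = "region", scope = c("Europe", "Africa"), mean = c(0.01, 0.03),
    sd = c(0.002, 0.004), n_points = c(10L, 4L), n_countries = c(5L, 5L),
    pdf = "lognormal", stringsAsFactors = FALSE
  )
  glob <- estimate_global_ef(regional)
  expect_equal(glob$mean, 0.02)
  expect_equal(glob$n_points, 14)
  expect_equal(estimate_global_ef(regional[1, ])$mean, 0.01)
  expect_error(estimate_global_ef(regional[0, ]),
               class = "fertghg_schema_error")
})

test_that("estimates are order-invariant and linear in flux differences", {
  spec <- world_spec(seed = 11, countries_per_region = 2,
                     plots_per_country = 8)
  plots <- gen_paired_plots(world_true_efs(spec), spec)
  est1 <- estimate_direct_efs(plots)
  est2 <- estimate_direct_efs(plots[rev(seq_len(nrow(plots))), ])
  reord <- function(df) df[order(df$scope), ]
  expect_equal(reord(est1$country)[, c("scope", "mean", "sd", "n_points")],
               reord(est2$country)[, c("scope", "mean", "sd", "n_points")],
               ignore_attr = TRUE)
  expect_equal(est1$global$mean, est2$global$mean)

  doubled <- plots
  doubled$n2o_treated_kg_ha <- plots$n2o_control_kg_ha +
    2 * (plots$n2o_treated_kg_ha - plots$n2o_control_kg_ha)
  est_d <- estimate_direct_efs(doubled)
  expect_equal(est_d$country$mean, 2 * est1$country$mean)
  expect_equal(est_d$global$mean, 2 * est1$global$mean)
})

test_that("estimator recovers known country EFs as plots accumulate", {
  truths <- data.frame(country = c("X1", "X2"), region = "Europe",
                       true_ef = 0.012, stringsAsFactors = FALSE)
  spec <- world_spec(seed = 5)
  hits <- 0L; trials <- 0L
  for (s in 1:10) {
    plots <- gen_paired_plots(truths, spec, n_per_country = 200,
                              seed = 1000 + s)
    est <- estimate_country_efs(filter_synthetic_plots(plots))
    for (i in seq_len(nrow(est))) {
      trials <- trials + 1L
      tol <- 2 * est$sd[i] / sqrt(est$n_points[i])
      if (abs(est$mean[i] - 0.012) < tol) hits <- hits + 1L
    }
  }
  expect_gte(hits / trials, 0.9)
})
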