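# Synthetic-world generator: determinism, invariants of consuming modules,
# uncertainty rules, recovery chain.

test_that("generation is reproducible from (spec, seed) and seed-sensitive", {
  spec <- world_spec(seed = 17)
  expect_identical(gen_activity_table(spec), gen_activity_table(spec))
  expect_identical(gen_paired_plots(world_true_efs(spec), spec),
                   gen_paired_plots(world_true_efs(spec), spec))
  expect_identical(gen_ef_tables(spec), gen_ef_tables(spec))
  expect_identical(gen_trend_series(spec), gen_trend_series(spec))
  other <- world_spec(seed = 18)
  expect_false(identical(gen_activity_table(spec)$n_consumption_t,
                         gen_activity_table(other)$n_consumption_t))
})

test_that("generated artefacts satisfy the consuming modules' invariants", {
  spec <- world_spec(seed = 2, countries_per_region = 2,
                     plots_per_country = 4)
  act <- gen_activity_table(spec)
  expect_silent(validate_activity_table(act))
  expect_equal(sum(act$n_consumption_t), spec$world_n_tonnes)
  expect_equal(nrow(act), 2 * length(fert_regions()))

  solo <- world_spec(seed = 2, countries_per_region = 1)
  expect_equal(sum(gen_activity_table(solo)$region == "Europe"), 1)

  plots <- gen_paired_plots(world_true_efs(spec), spec)
  expect_true(all(plots$n_applied_kg_ha > 0))
  expect_true(all(is.finite(plots$n2o_treated_kg_ha)))
  expect_true(all(plots$fertiliser_type == "synthetic"))
  expect_silent(filtered <- filter_synthetic_plots(plots))
  expect_equal(nrow(filtered), nrow(plots))

  mix <- gen_sourcing_mix(spec)
  sums <- tapply(mix$share, mix$region_to, sum)
  expect_equal(as.numeric(sums), rep(1, length(fert_regions())))
})

test_that("EF tables follow the 25% / 50% uncertainty rules and are complete", {
  tabs <- gen_ef_tables(world_spec(seed = 4))
  m <- tabs$manufacturing
  expect_equal(nrow(m), length(fert_regions()) * length(fert_products()))
  expect_true(all(m$mean > 0))
  expect_equal(m$sd / m$mean, rep(0.25, nrow(m)))
  expect_true(all(m$pdf == "lognormal"))
  tr <- tabs$transport
  expect_equal(nrow(tr),
               length(fert_regions())^2 * length(fert_products()))
  expect_equal(tr$sd / tr$mean, rep(0.50, nrow(tr)))
  expect_true(all(tr$pdf == "normal"))
})

test_that("zero plot noise makes the estimator recover truth exactly", {
  spec <- world_spec(seed = 8, plot_noise_sdlog = 0,
                     countries_per_region = 1, plots_per_country = 5)
  truths <- world_true_efs(spec)
  plots <- gen_paired_plots(truths, spec)
  est <- estimate_country_efs(filter_synthetic_plots(plots))
  est <- est[match(truths$country, est$scope), ]
  expect_equal(est$mean, truths$true_ef, tolerance = 1e-12)
})

test_that("constant-growth trend generation is recovered by growth_rate", {
  spec <- world_spec(seed = 6)
  trends <- gen_trend_series(spec, years = 1961:1980, g_early = 0.03,
                             g_late = 0.03)
  one <- trends[trends$scope == "Europe" & trends$variable == "n_use",
                c("year", "value")]
  gr <- growth_rate_series(one)
  expect_equal(gr$value[-1], rep(3, nrow(one) - 1), tolerance = 1e-9)
  flat <- gen_trend_series(spec, years = 1961:1970, g_early = 0,
                           g_late = 0)
  fe <- flat[flat$scope == "Africa" & flat$variable == "n_use", ]
  expect_equal(diff(fe$value), rep(0, nrow(fe) - 1))
})

test_that("the recovery chain reproduces emissions from true EFs", {
  # true EFs -> paired plots -> estimation -> accounting should agree with
  # accounting run directly on the truths, within estimator error
  spec <- world_spec(seed = 12, countries_per_region = 2,
                     plots_per_country = 150, plot_noise_sdlog = 0.4)
  act <- gen_activity_table(spec)
  truths <- world_true_efs(spec)
  tabs <- gen_ef_tables(spec)
  plots <- gen_paired_plots(truths, spec)
  est <- estimate_direct_efs(plots)
  reg_est <- load_registry(manufacturing_ef = tabs$manufacturing,
                           transport_ef = tabs$transport, empirical = est)
  bk_est <- account_emissions(act, reg_est, "empirical_country")

  truth_emp <- list(
    country = data.frame(level = "country", scope = truths$country,
                         region = truths$region, mean = truths$true_ef,
                         sd = 0, n_points = 1, pdf = "lognormal",
                         stringsAsFactors = FALSE),
    region = NULL, global = NULL)
  reg_truth <- load_registry(manufacturing_ef = tabs$manufacturing,
                             transport_ef = tabs$transport,
                             empirical = truth_emp)
  bk_truth <- account_emissions(act, reg_truth, "empirical_country")
  # only ghg_d depends on the direct EF; compare it country-wise
  rel_err <- abs(bk_est$ghg_d - bk_truth$ghg_d) / bk_truth$ghg_d
  expect_lt(stats::median(rel_err), 0.15)
  expect_equal(bk_est$ghg_m, bk_truth$ghg_m)
})

test_that("simulate_inputs writes a complete, loadable bundle", {
  dir <- withr::local_tempdir()
  spec <- world_spec(seed = 3, countries_per_region = 2,
                     plots_per_country = 3)
  files <- simulate_inputs(spec, dir)
  expect_true(all(file.exists(files)))
  act <- read_activity_table(files[["activity"]])
  expect_equal(nrow(act), 2 * length(fert_regions()))
  reg <- load_registry(files[["config"]])
  expect_equal(nrow(reg$manufacturing_ef),
               length(fert_regions()) * length(fert_products()))
  bk <- account_emissions(act, reg, "ipcc_tier1")
  expect_true(all(bk$total > 0))
})
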