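# Deterministic accounting chain: per-component formulas, assembly,
# aggregation, and equivalence with the independent oracle.

test_that("component formulas reproduce hand arithmetic", {
  d <- direct_field_emissions(100, 0.01, 265)
  expect_equal(d$n2o_n, 1)
  expect_equal(d$co2e, 1 * 44 / 28 * 265)
  expect_equal(direct_field_emissions(0, 0.01)$co2e, 0)

  v <- indirect_volatilisation_emissions(100, 0.11, 0.010, 265)
  expect_equal(v$n2o_n, 0.11)
  expect_equal(v$co2e, 0.11 * 44 / 28 * 265)
  expect_equal(indirect_volatilisation_emissions(100, 0, 0.01)$co2e, 0)
  expect_equal(indirect_volatilisation_emissions(100, 1, 1)$n2o_n, 100)

  l <- indirect_leaching_emissions(100, 0.24, 0.011, 265)
  expect_equal(l$n2o_n, 0.264)
  expect_equal(l$co2e, 0.264 * 44 / 28 * 265)
  expect_equal(indirect_leaching_emissions(100, 0, 0.011)$co2e, 0)

  u <- urea_field_emissions(100, 0.2)
  expect_equal(u$co2_c, 20)
  expect_equal(u$co2, 20 * 44 / 12)
  expect_equal(urea_field_emissions(100, 0.3)$co2, 30 * 44 / 12)
  expect_equal(urea_field_emissions(0)$co2, 0)
})

test_that("manufacturing and transport sums follow tonnage times EF", {
  products <- data.frame(country = "C1", product = c("urea", "AN"),
                         n_tonnes = c(4.66, 1.005),
                         product_tonnes = c(10, 3),
                         stringsAsFactors = FALSE)
  m_tab <- data.frame(region = "Europe", product = c("urea", "AN"),
                      mean = c(2, 3), sd = 0, min = NA, max = NA,
                      pdf = "normal", stringsAsFactors = FALSE)
  expect_equal(
    manufacturing_emissions(products, m_tab, default_region = "Europe"),
    10 * 2 + 3 * 3)
  expect_equal(
    manufacturing_emissions(products[0, ], m_tab, default_region = "Europe"),
    0)

  t_tab <- data.frame(region = c("Europe", "Africa", "Europe", "Africa"),
                      region_to = "Europe",
                      product = c("urea", "urea", "AN", "AN"),
                      mean = c(0.05, 0.20, 0.05, 0.20), sd = 0,
                      min = NA, max = NA, pdf = "normal",
                      stringsAsFactors = FALSE)
  mix <- data.frame(region_to = "Europe",
                    region_from = c("Europe", "Africa"),
                    share = c(0.6, 0.4), stringsAsFactors = FALSE)
  expect_equal(
    transport_emissions(products[1, ], t_tab, mix, c(C1 = "Europe")),
    10 * (0.6 * 0.05 + 0.4 * 0.20))
  bad_mix <- mix
  bad_mix$share <- c(0.6, 0.3)
  expect_error(
    transport_emissions(products[1, ], t_tab, bad_mix, c(C1 = "Europe")),
    class = "fertghg_config_error")
})

test_that("national totals are exact component sums and aggregate cleanly", {
  bk <- assemble_country("X", 1, 2, 3, 4, 5, 6)
  expect_equal(bk$total, 21)
  two <- rbind(assemble_country("A", 1, 1, 1, 1, 1, 5),
               assemble_country("B", 2, 2, 2, 2, 2, 10))
  glob <- aggregate_emissions(two, "global")
  expect_equal(glob$total, 30)
  expect_equal(aggregate_emissions(two[1, ], "global")$total, two$total[1])
  expect_error(aggregate_emissions(rbind(two, two), "global"),
               class = "fertghg_schema_error")
})

test_that("engine matches the independent oracle on random small worlds", {
  for (s in 1:20) {
    act <- random_toy_inventory(s)
    reg <- toy_registry()
    bk <- account_emissions(act, reg, "ipcc_tier1")
    orc <- oracle_accounting(act, reg, "ipcc_tier1")
    for (col in c("ghg_m", "ghg_t", "ghg_d", "ghg_v", "ghg_l", "ghg_u",
                  "total")) {
      expect_equal(bk[[col]], orc[[col]], tolerance = 1e-9,
                   label = sprintf("seed %d, %s", s, col))
    }
  }
})

test_that("engine matches the oracle under a sourcing mix and wet/dry EFs", {
  act <- toy_activity(n = 4, n_consumption = c(100, 250, 40, 900))
  mix <- data.frame(region_to = c("Europe", "Europe", "Africa", "Africa"),
                    region_from = c("Europe", "Africa", "Africa", "Europe"),
                    share = c(0.7, 0.3, 0.8, 0.2), stringsAsFactors = FALSE)
  reg <- toy_registry()
  bk <- account_emissions(act, reg, "ipcc_wetdry", sourcing_mix = mix)
  orc <- oracle_accounting(act, reg, "ipcc_wetdry", sourcing_mix = mix)
  expect_equal(bk$total, orc$total, tolerance = 1e-9)
  expect_equal(bk$ghg_t, orc$ghg_t, tolerance = 1e-9)
})

test_that("emissions scale linearly with activity", {
  act <- toy_activity(n = 2, n_consumption = c(100, 300))
  act2 <- act
  act2$n_consumption_t <- act$n_consumption_t * 3
  reg <- toy_registry()
  bk1 <- account_emissions(act, reg, "ipcc_tier1")
  bk2 <- account_emissions(act2, reg, "ipcc_tier1")
  for (col in c("ghg_m", "ghg_t", "ghg_d", "ghg_v", "ghg_l", "ghg_u",
                "total")) {
    expect_equal(bk2[[col]], 3 * bk1[[col]], tolerance = 1e-12)
  }
})

test_that("region-then-global aggregation equals direct global sums", {
  act <- toy_activity(n = 4, n_consumption = c(10, 20, 30, 40))
  bk <- account_emissions(act, toy_registry(), "ipcc_tier1")
  by_region <- aggregate_emissions(bk, "region")
  direct_global <- aggregate_emissions(bk, "global")
  expect_equal(sum(by_region$total), direct_global$total, tolerance = 1e-12)
  expect_equal(colSums(by_region[, c("ghg_m", "ghg_d")]),
               unlist(direct_global[, c("ghg_m", "ghg_d")]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("co2e / n2o_n is the constant 44/28 x GWP for field components", {
  act <- toy_activity(n = 3, n_consumption = c(5, 50, 500))
  bk <- account_emissions(act, toy_registry(), "ipcc_tier1")
  ratio <- 44 / 28 * 265
  expect_equal(bk$ghg_d / bk$n2o_n_direct, rep(ratio, 3))
  expect_equal(bk$ghg_v / bk$n2o_n_volat, rep(ratio, 3))
  keep <- bk$n2o_n_leach > 0
  expect_equal(bk$ghg_l[keep] / bk$n2o_n_leach[keep],
               rep(ratio, sum(keep)))
})
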