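# Shared fixtures: tiny in-code worlds, a zero-uncertainty registry builder,
# and an independent single-expression implementation of the accounting
# chain used as the oracle against the engine.

options(fertghg.quiet = TRUE)

# A minimal activity table: `n` countries spread over two regions, simple
# two-product mixes (urea + AN), mixed climates.
toy_activity <- function(n = 2, n_consumption = rep(100, n),
                         regions = rep_len(c("Europe", "Africa"), n),
                         climates = rep_len(c("wet", "dry"), n),
                         share_urea = rep(0.5, n), share_an = rep(0.3, n)) {
  df <- data.frame(
    country = paste0("C", seq_len(n)), region = regions, year = 2018,
    n_consumption_t = n_consumption, climate = climates,
    share_ammonia = 0, share_an = share_an, share_as = 0, share_can = 0,
    share_urea = share_urea, share_uan = 0, share_ap = 0, share_npk = 0,
    population = 1e6, cropland_ha = 1e5,
    stringsAsFactors = FALSE
  )
  validate_activity_table(df)
}

# Complete manufacturing/transport EF tables over the given regions, with
# deterministic distinct means so lookups are distinguishable.
toy_ef_tables <- function(regions = c("Europe", "Africa"), sd_frac_m = 0.25,
                          sd_frac_t = 0.5) {
  grid_m <- expand.grid(region = regions, product = fert_products(),
                        stringsAsFactors = FALSE)
  grid_m$mean <- 1 + 0.1 * seq_len(nrow(grid_m))
  grid_m$sd <- sd_frac_m * grid_m$mean
  grid_m$min <- NA_real_; grid_m$max <- NA_real_
  grid_m$pdf <- "lognormal"
  grid_t <- expand.grid(region = regions, region_to = regions,
                        product = fert_products(), stringsAsFactors = FALSE)
  grid_t$mean <- 0.05 + 0.01 * seq_len(nrow(grid_t))
  grid_t$sd <- sd_frac_t * grid_t$mean
  grid_t$min <- NA_real_; grid_t$max <- NA_real_
  grid_t$pdf <- "normal"
  list(manufacturing = grid_m, transport = grid_t)
}

toy_registry <- function(regions = c("Europe", "Africa"), zero_sd = FALSE,
                         config = NULL, empirical = NULL) {
  tabs <- toy_ef_tables(regions,
                        sd_frac_m = if (zero_sd) 0 else 0.25,
                        sd_frac_t = if (zero_sd) 0 else 0.5)
  if (zero_sd) {
    config <- list(
      direct_ef_schemes = list(
        ipcc_tier1 = list(mean = 0.010, sd = 0, min = 0.010, max = 0.010),
        ipcc_wetdry = list(
          wet = list(mean = 0.016, sd = 0, min = 0.016, max = 0.016),
          dry = list(mean = 0.005, sd = 0, min = 0.005, max = 0.005))),
      indirect_factors = list(
        wet = list(frac_gasf = list(sd = 0), ef4 = list(sd = 0),
                   frac_leach = list(sd = 0), ef5 = list(sd = 0)),
        dry = list(frac_gasf = list(sd = 0), ef4 = list(sd = 0),
                   frac_leach = list(sd = 0), ef5 = list(sd = 0))),
      urea_ef = list(sd = 0))
  }
  load_registry(config, manufacturing_ef = tabs$manufacturing,
                transport_ef = tabs$transport, empirical = empirical)
}

# Independent oracle: the whole chain written as one explicit expression per
# country, structured nothing like the engine (no coefficient matrices, no
# shared evaluation), against the same registry contents.
oracle_accounting <- function(activity, registry, scheme,
                              sourcing_mix = NULL) {
  if (is.null(sourcing_mix)) {
    sourcing_mix <- data.frame(region_to = unique(activity$region),
                               region_from = unique(activity$region),
                               share = 1, stringsAsFactors = FALSE)
  }
  gwp <- registry$constants$gwp
  ncont <- c(ammonia = 0.82, AN = 0.335, AS = 0.21, CAN = 0.27,
             urea = 0.466, UAN = 0.30, AP = 0.11, NPK = 0.15)
  share_col <- c(ammonia = "share_ammonia", AN = "share_an", AS = "share_as",
                 CAN = "share_can", urea = "share_urea", UAN = "share_uan",
                 AP = "share_ap", NPK = "share_npk")
  res <- lapply(seq_len(nrow(activity)), function(i) {
    row <- activity[i, ]
    m <- 0; tr <- 0
    for (p in fert_products()) {
      tonnes <- row$n_consumption_t * row[[share_col[[p]]]] / ncont[[p]]
      if (tonnes == 0) next
      efm <- registry$manufacturing_ef
      m <- m + tonnes *
        efm$mean[efm$region == row$region & efm$product == p]
      mixrows <- sourcing_mix[sourcing_mix$region_to == row$region, ]
      for (k in seq_len(nrow(mixrows))) {
        eft <- registry$transport_ef
        tr <- tr + tonnes * mixrows$share[k] *
          eft$mean[eft$region == mixrows$region_from[k] &
                     eft$region_to == row$region & eft$product == p]
      }
    }
    d_ef <- get_direct_ef(registry, scheme, country = row$country,
                          region = row$region, climate = row$climate)$mean
    ind <- registry$indirect[[row$climate]]
    d <- row$n_consumption_t * d_ef * (44 / 28) * gwp
    v <- row$n_consumption_t * ind$frac_gasf$mean * ind$ef4$mean *
      (44 / 28) * gwp
    l <- row$n_consumption_t * ind$frac_leach$mean * ind$ef5$mean *
      (44 / 28) * gwp
    urea_eq <- row$n_consumption_t * row$share_urea / 0.466 +
      0.35 * (row$n_consumption_t * row$share_uan / 0.30)
    u <- urea_eq * registry$urea_ef$mean * (44 / 12)
    data.frame(country = row$country, ghg_m = m, ghg_t = tr, ghg_d = d,
               ghg_v = v, ghg_l = l, ghg_u = u,
               total = m + tr + d + v + l + u, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Random small inventory for the oracle-equivalence property.
random_toy_inventory <- function(seed) {
  set.seed(seed)
  n <- sample(1:5, 1)
  toy_activity(
    n = n,
    n_consumption = stats::runif(n, 10, 1e4),
    regions = sample(c("Europe", "Africa"), n, replace = TRUE),
    climates = sample(c("wet", "dry"), n, replace = TRUE),
    share_urea = stats::runif(n, 0, 0.5),
    share_an = stats::runif(n, 0, 0.4)
  )
}
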