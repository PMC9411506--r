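# Synthetic world generator: activity tables, EF tables, paired-plot
# datasets with known ground-truth EFs, sourcing mixes and historical
# series, so the full pipeline runs and is testable without the restricted
# activity and EF inputs. The generator emulates structure (uneven country
# coverage, lognormal EF dispersion, 25%/50% EF uncertainty rules), not the
# actual values of any real country.
#
# All draws flow from one master seed via named substreams, so changing one
# generator's parameters does not shift another generator's draws.

#' Specification of a synthetic fertiliser world
#'
#' Collects every parameter of the synthetic-data generator. Defaults give a
#' 9-region x 5-country world consuming 100 Mt N (the order of magnitude of
#' real global consumption), a wet-climate majority, 96% product-mix
#' coverage, and regional true direct EFs spanning 0.003-0.024 (the spread
#' reported for empirical regional estimates, with the Americas high and
#' Africa/Russian Commonwealth low).
#'
#' @param countries_per_region Countries generated per region.
#' @param world_n_tonnes Total world N consumption (t N); country draws are
#'   rescaled to sum to this exactly.
#' @param p_wet Probability a country is wet-climate.
#' @param coverage Product-mix coverage (sum of the eight shares).
#' @param ef_regional Named vector of true regional direct EFs (fractions).
#' @param ef_country_sdlog Lognormal dispersion of country truths around the
#'   regional EF.
#' @param plot_noise_sdlog Lognormal dispersion of plot-level EFs around the
#'   country truth.
#' @param control_flux_mean,control_flux_sdlog Control-plot cumulative
#'   N2O-N baseline (kg/ha): natural-scale lognormal mean and log-sd.
#' @param n_applied_range Uniform range for plot N rates (kg N/ha).
#' @param plots_per_country Baseline paired plots per country.
#' @param overrepresented_regions Regions whose countries get
#'   `overrepresentation` times more plots (mimicking the North
#'   America/Europe data bias).
#' @param overrepresentation Multiplier for the regions above.
#' @param domestic_share Intra-regional sourcing share for transport.
#' @param seed Master seed.
#' @return A list of class `world_spec`.
#' @export
world_spec <- function(countries_per_region = 5,
                       world_n_tonnes = 100e6,
                       p_wet = 0.6,
                       coverage = 0.96,
                       ef_regional = c(
                         "East Asia" = 0.005, "South Asia" = 0.007,
                         "Europe" = 0.007, "North America" = 0.011,
                         "Latin America" = 0.024, "Africa" = 0.003,
                         "Middle East" = 0.004, "Oceania" = 0.005,
                         "Russian Commonwealth" = 0.003),
                       ef_country_sdlog = 0.3,
                       plot_noise_sdlog = 1.0,
                       control_flux_mean = 0.5,
                       control_flux_sdlog = 0.7,
                       n_applied_range = c(50, 250),
                       plots_per_country = 12,
                       overrepresented_regions = c("North America", "Europe"),
                       overrepresentation = 3,
                       domestic_share = 0.79,
                       seed = 1) {
  stopifnot(countries_per_region >= 1, world_n_tonnes > 0,
            coverage > 0, coverage <= 1,
            all(names(ef_regional) %in% fert_regions()))
  structure(as.list(environment()), class = "world_spec")
}

#' @export
print.world_spec <- function(x, ...) {
  cat(sprintf("<world_spec> %d regions x %d countries, world N = %g Mt, seed %d\n",
              length(fert_regions()), x$countries_per_region,
              x$world_n_tonnes / 1e6, x$seed))
  invisible(x)
}

region_code <- function(region) {
  c("East Asia" = "EAS", "South Asia" = "SAS", "Europe" = "EUR",
    "North America" = "NAM", "Latin America" = "LAM", "Africa" = "AFR",
    "Middle East" = "MEA", "Oceania" = "OCE",
    "Russian Commonwealth" = "RUC")[region]
}

world_countries <- function(spec) {
  regions <- rep(fert_regions(), each = spec$countries_per_region)
  data.frame(
    country = paste0(region_code(regions),
                     rep(seq_len(spec$countries_per_region),
                         times = length(fert_regions()))),
    region = regions,
    stringsAsFactors = FALSE
  )
}

#' True country-level direct EFs of a synthetic world
#'
#' The ground truth the recovery tests measure against: each country's EF is
#' its regional EF perturbed by a lognormal factor with natural-scale mean 1.
#'
#' @param spec A [world_spec()].
#' @return Data.frame `country, region, true_ef, climate`.
#' @export
world_true_efs <- function(spec) {
  cset <- world_countries(spec)
  withr_seed(substream_seed(spec$seed, "true_efs"), {
    base <- spec$ef_regional[cset$region]
    mult <- stats::rlnorm(nrow(cset),
                          meanlog = -spec$ef_country_sdlog^2 / 2,
                          sdlog = spec$ef_country_sdlog)
    cset$true_ef <- unname(base * mult)
    cset$climate <- ifelse(stats::runif(nrow(cset)) < spec$p_wet, "wet", "dry")
  })
  cset
}

# run code with a local seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Generate a synthetic activity table
#'
#' Country N consumption is lognormal across countries and rescaled so the
#' world total equals `spec$world_n_tonnes` exactly; product-mix shares are
#' Dirichlet draws per region (applied uniformly to member countries) scaled
#' to the configured coverage; climate, population and cropland complete the
#' rows. The result passes [validate_activity_table()].
#'
#' @param spec A [world_spec()].
#' @return Activity data.frame (see [read_activity_table()] for columns).
#' @export
gen_activity_table <- function(spec) {
  cset <- world_true_efs(spec)
  nC <- nrow(cset)
  withr_seed(substream_seed(spec$seed, "activity"), {
    n_raw <- stats::rlnorm(nC, meanlog = 0, sdlog = 1)
    n_cons <- n_raw / sum(n_raw) * spec$world_n_tonnes
    mix <- matrix(0, nrow = nC, ncol = length(fert_products()))
    for (reg in fert_regions()) {
      g <- stats::rgamma(length(fert_products()),
                         shape = c(2, 3, 1, 2, 8, 2, 1.5, 2))
      shares <- spec$coverage * g / sum(g)
      mix[cset$region == reg, ] <- matrix(shares, ncol = length(shares),
                                          nrow = sum(cset$region == reg),
                                          byrow = TRUE)
    }
    population <- stats::rlnorm(nC, meanlog = log(3e7), sdlog = 1)
    cropland <- stats::rlnorm(nC, meanlog = log(5e6), sdlog = 1)
  })
  colnames(mix) <- paste0("share_", tolower(fert_products()))
  out <- data.frame(
    country = cset$country, region = cset$region, year = 2018,
    n_consumption_t = n_cons, climate = cset$climate,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(mix))
  out$population <- population
  out$cropland_ha <- cropland
  validate_activity_table(out)
}

#' Generate paired-plot records with known true EFs
#'
#' Builds the field dataset the EF estimator consumes: for each country,
#' `n_per_country` paired plots where the treated flux is the control flux
#' plus `n_applied x ef_plot`, with `ef_plot` lognormal around the country
#' truth (natural-scale mean equal to the truth, so the estimator is
#' unbiased) and the control flux an independent positive baseline, so the
#' treated-minus-control subtraction is genuinely exercised. Regions listed
#' in `spec$overrepresented_regions` get proportionally more plots,
#' mimicking the reported data bias towards North America and Europe.
#'
#' @param true_efs Data.frame `country, region, true_ef` (and optional
#'   `climate`), e.g. from [world_true_efs()].
#' @param spec A [world_spec()] providing the noise model.
#' @param n_per_country Baseline plots per country; scalar or per-country
#'   vector. Defaults to `spec$plots_per_country`.
#' @param seed Seed; defaults to the spec's `paired_plots` substream.
#' @return Data.frame in the paired-plot CSV schema, `fertiliser_type`
#'   all `"synthetic"`.
#' @export
gen_paired_plots <- function(true_efs, spec = world_spec(),
                             n_per_country = NULL, seed = NULL) {
  n_per <- n_per_country %||% spec$plots_per_country
  if (length(n_per) == 1) {
    n_per <- rep(n_per, nrow(true_efs))
    boost <- true_efs$region %in% spec$overrepresented_regions
    n_per[boost] <- n_per[boost] * spec$overrepresentation
  }
  stopifnot(length(n_per) == nrow(true_efs), all(n_per >= 1))
  seed <- seed %||% substream_seed(spec$seed, "paired_plots")
  total <- sum(n_per)
  idx <- rep(seq_len(nrow(true_efs)), times = n_per)
  withr_seed(seed, {
    n_applied <- stats::runif(total, spec$n_applied_range[1],
                              spec$n_applied_range[2])
    ef_plot <- true_efs$true_ef[idx] *
      stats::rlnorm(total, meanlog = -spec$plot_noise_sdlog^2 / 2,
                    sdlog = spec$plot_noise_sdlog)
    control <- stats::rlnorm(total,
                             meanlog = log(spec$control_flux_mean) -
                               spec$control_flux_sdlog^2 / 2,
                             sdlog = spec$control_flux_sdlog)
    crop <- sample(c("maize", "wheat", "rice", "soybean", "vegetables"),
                   total, replace = TRUE)
  })
  climate <- if ("climate" %in% names(true_efs)) true_efs$climate[idx] else "unknown"
  data.frame(
    record_id = sprintf("rec%05d", seq_len(total)),
    country = true_efs$country[idx],
    region = true_efs$region[idx],
    crop = crop,
    n_applied_kg_ha = n_applied,
    n2o_treated_kg_ha = control + n_applied * ef_plot,
    n2o_control_kg_ha = control,
    climate = climate,
    fertiliser_type = "synthetic",
    stringsAsFactors = FALSE
  )
}

#' Generate manufacturing and transport EF tables
#'
#' Stand-ins for the licence-restricted factory-gate and transport EF
#' datasets: every (region, product) gets a positive manufacturing EF
#' (plausible tCO2e/t magnitudes per product, times a lognormal regional
#' spread so some regions sit above the reference average) with sd = 25% of
#' the mean and a lognormal pdf; every (origin, destination, product) gets a
#' transport EF (higher for inter-regional flows) with sd = 50% of the mean
#' and a normal pdf truncated at zero.
#'
#' @param spec A [world_spec()].
#' @param regional_spread Log-sd of the regional multiplier on manufacturing
#'   EFs.
#' @return List with `manufacturing` and `transport` data.frames in the
#'   registry's table format.
#' @export
gen_ef_tables <- function(spec, regional_spread = 0.2) {
  base <- c(ammonia = 2.6, AN = 2.4, AS = 0.6, CAN = 2.2,
            urea = 1.6, UAN = 1.5, AP = 0.7, NPK = 1.2)
  regions <- fert_regions()
  withr_seed(substream_seed(spec$seed, "ef_tables"), {
    reg_mult <- stats::rlnorm(length(regions), meanlog = 0,
                              sdlog = regional_spread)
    names(reg_mult) <- regions
    grid_m <- expand.grid(region = regions, product = fert_products(),
                          stringsAsFactors = FALSE)
    mean_m <- base[grid_m$product] * reg_mult[grid_m$region]
    grid_t <- expand.grid(region = regions, region_to = regions,
                          product = fert_products(), stringsAsFactors = FALSE)
    dist_fac <- ifelse(grid_t$region == grid_t$region_to, 1,
                       stats::runif(nrow(grid_t), 2, 4))
    base_t <- c(ammonia = 0.10, AN = 0.06, AS = 0.05, CAN = 0.06,
                urea = 0.05, UAN = 0.08, AP = 0.05, NPK = 0.06)
    mean_t <- base_t[grid_t$product] * dist_fac
  })
  manufacturing <- data.frame(
    grid_m,
    mean = unname(mean_m), sd = 0.25 * unname(mean_m),
    min = 0.4 * unname(mean_m), max = 2.5 * unname(mean_m),
    pdf = "lognormal", stringsAsFactors = FALSE
  )
  transport <- data.frame(
    grid_t,
    mean = unname(mean_t), sd = 0.50 * unname(mean_t),
    min = 0, max = 3 * unname(mean_t),
    pdf = "normal", stringsAsFactors = FALSE
  )
  list(manufacturing = manufacturing, transport = transport)
}

#' Generate a sourcing-mix table
#'
#' Per consuming region: `domestic_share` of each product is sourced
#' intra-regionally and the remainder is split across the other regions by
#' a Dirichlet draw; shares sum to 1 exactly.
#'
#' @param spec A [world_spec()].
#' @return Data.frame `region_to, region_from, share`.
#' @export
gen_sourcing_mix <- function(spec) {
  regions <- fert_regions()
  rows <- list()
  withr_seed(substream_seed(spec$seed, "sourcing"), {
    for (reg in regions) {
      others <- setdiff(regions, reg)
      w <- stats::rgamma(length(others), shape = 1)
      foreign <- (1 - spec$domestic_share) * w / sum(w)
      domestic <- 1 - sum(foreign)  # exact complement
      rows[[length(rows) + 1]] <- data.frame(
        region_to = reg, region_from = c(reg, others),
        share = c(domestic, foreign), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Generate historical trend series
#'
#' Smooth exponential growth with slowdown per region: the annual growth
#' rate decays from `g_early` to `g_late` with timescale `tau` years,
#' mimicking the observed fall of fertiliser-use growth from ~15%/yr in the
#' 1960s to ~2.5%/yr today. Variables generated: `n_use` (t N),
#' `population` (persons), `cropland` (ha), `crop_production` (t) and the
#' derived `n_rate` (kg N/ha).
#'
#' @param spec A [world_spec()].
#' @param years Year range (default 1961:2018).
#' @param g_early,g_late Early and late annual growth rates of N use
#'   (fractions).
#' @param tau Decay timescale in years.
#' @return Long data.frame `scope, variable, year, value`.
#' @export
gen_trend_series <- function(spec, years = 1961:2018, g_early = 0.15,
                             g_late = 0.025, tau = 15) {
  t_rel <- seq_along(years) - 1
  g_nuse <- g_late + (g_early - g_late) * exp(-t_rel / tau)
  rows <- list()
  withr_seed(substream_seed(spec$seed, "trends"), {
    for (reg in fert_regions()) {
      v0_n <- stats::rlnorm(1, log(2e5), 0.5)
      v0_pop <- stats::rlnorm(1, log(2e8), 0.5)
      v0_crop <- stats::rlnorm(1, log(3e7), 0.5)
      v0_prod <- stats::rlnorm(1, log(5e7), 0.5)
      n_use <- v0_n * cumprod(1 + c(0, g_nuse[-1]))
      population <- v0_pop * cumprod(1 + rep(0.015, length(years)))
      cropland <- v0_crop * cumprod(1 + rep(0.004, length(years)))
      crop_production <- v0_prod * cumprod(1 + rep(0.027, length(years)))
      add <- function(variable, value) {
        rows[[length(rows) + 1]] <<- data.frame(
          scope = reg, variable = variable, year = years, value = value,
          stringsAsFactors = FALSE)
      }
      add("n_use", n_use)
      add("population", population)
      add("cropland", cropland)
      add("crop_production", crop_production)
      add("n_rate", n_use * 1000 / cropland)
    }
  })
  do.call(rbind, rows)
}

#' Write a complete synthetic input bundle
#'
#' Generates and writes everything the pipeline consumes: the activity CSV,
#' paired-plot CSV, manufacturing/transport EF CSVs, sourcing-mix CSV,
#' trend CSV and a YAML config pointing at the EF tables. The bundle is
#' byte-identical across runs with the same spec.
#'
#' @param spec A [world_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written (invisibly).
#' @export
simulate_inputs <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  activity <- gen_activity_table(spec)
  truths <- world_true_efs(spec)
  plots <- gen_paired_plots(truths, spec)
  tables <- gen_ef_tables(spec)
  mix <- gen_sourcing_mix(spec)
  trends <- gen_trend_series(spec)

  files <- c(
    activity = file.path(dir, "activity.csv"),
    paired_plots = file.path(dir, "paired_plots.csv"),
    true_efs = file.path(dir, "true_efs_synthetic.csv"),
    manufacturing_ef = file.path(dir, "manufacturing_ef.csv"),
    transport_ef = file.path(dir, "transport_ef.csv"),
    sourcing_mix = file.path(dir, "sourcing_mix.csv"),
    trends = file.path(dir, "trends.csv"),
    config = file.path(dir, "config.yaml")
  )
  wr <- function(df, path) utils::write.csv(df, path, row.names = FALSE)
  wr(activity, files["activity"])
  wr(plots, files["paired_plots"])
  wr(truths, files["true_efs"])
  m <- tables$manufacturing
  names(m)[names(m) == "mean"] <- "mean_tco2e_per_t"
  wr(m, files["manufacturing_ef"])
  tr <- tables$transport
  names(tr)[names(tr) == "mean"] <- "mean_tco2e_per_t"
  wr(tr, files["transport_ef"])
  wr(mix, files["sourcing_mix"])
  wr(trends, files["trends"])
  yaml::write_yaml(list(
    constants = list(gwp = 265),
    manufacturing_ef = unname(files["manufacturing_ef"]),
    transport_ef = unname(files["transport_ef"])
  ), files["config"])
  fert_log("INFO", "synthetic_data", "bundle_written", dir = dir,
           files = length(files))
  invisible(files)
}
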