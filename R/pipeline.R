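# Pipeline entry points: file-in/file-out wrappers over the analysis
# functions, plus the run manifest. These back the `inst/cli/fertghg.R`
# dispatcher; error classes map to exit codes there (2 schema, 3 config,
# 4 numerical).

write_manifest <- function(out_dir, inputs, outputs, seed = NULL,
                           scheme = NULL) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  digests <- vapply(unlist(inputs), function(p) {
    unname(tools::md5sum(p))
  }, character(1))
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("fertghg")),
    inputs = as.list(digests),
    seed = seed,
    scheme = scheme,
    outputs = unname(unlist(outputs))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Estimate direct EFs from a paired-plot CSV
#'
#' Reads and filters the paired-plot table, estimates country, regional and
#' global direct EFs, and writes them as CSVs
#' (`scope_level, scope, mean, sd, n_points`) plus a JSON filter log and a
#' run manifest.
#'
#' @param paired_plot_csv Input CSV (see [read_paired_plots()]).
#' @param out_dir Output directory, created if needed.
#' @return Named vector of output files (invisibly).
#' @export
cmd_estimate_efs <- function(paired_plot_csv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_paired_plots(paired_plot_csv)
  est <- estimate_direct_efs(records)
  out_cols <- c("level", "scope", "mean", "sd", "n_points")
  files <- c(country = file.path(out_dir, "ef_country.csv"),
             region = file.path(out_dir, "ef_region.csv"),
             global = file.path(out_dir, "ef_global.csv"),
             filter_log = file.path(out_dir, "filter_log.json"))
  for (lvl in c("country", "region", "global")) {
    df <- est[[lvl]][, out_cols]
    names(df)[1] <- "scope_level"
    utils::write.csv(df, files[[lvl]], row.names = FALSE)
  }
  jsonlite::write_json(as.list(est$filter_log), files[["filter_log"]],
                       auto_unbox = TRUE)
  manifest <- write_manifest(out_dir, list(paired_plots = paired_plot_csv),
                             files)
  invisible(c(files, manifest = manifest))
}

build_registry_for_cmd <- function(config, scheme, paired_plot_csv = NULL) {
  empirical <- NULL
  if (startsWith(scheme, "empirical")) {
    if (is.null(paired_plot_csv)) {
      fert_stop("fertghg_config_error",
                "scheme '%s' requires a paired-plot CSV to estimate EFs from",
                scheme)
    }
    empirical <- estimate_direct_efs(read_paired_plots(paired_plot_csv))
  }
  load_registry(config, empirical = empirical)
}

#' Run the deterministic accounting from files
#'
#' Reads the activity table and config (which must point at manufacturing
#' and transport EF CSVs), resolves the registry, and writes a per-country
#' emissions table in Mt CO2e plus regional/global aggregates. With
#' `scheme = "all"` one table per scheme is written (empirical schemes only
#' if a paired-plot CSV is given), for scheme-comparison summaries.
#'
#' @param activity_csv Activity CSV path.
#' @param config YAML config path or list (see [load_registry()]).
#' @param scheme Direct-EF scheme, or `"all"`.
#' @param out_dir Output directory.
#' @param sourcing_mix_csv Optional sourcing-mix CSV
#'   (`region_to, region_from, share`).
#' @param paired_plot_csv Optional paired-plot CSV enabling empirical
#'   schemes.
#' @return Named vector of output files (invisibly).
#' @export
cmd_account <- function(activity_csv, config, scheme = "ipcc_tier1",
                        out_dir = ".", sourcing_mix_csv = NULL,
                        paired_plot_csv = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  activity <- read_activity_table(activity_csv)
  mix <- if (!is.null(sourcing_mix_csv)) {
    utils::read.csv(sourcing_mix_csv, stringsAsFactors = FALSE)
  }
  schemes <- if (identical(scheme, "all")) {
    base <- c("ipcc_tier1", "ipcc_wetdry")
    if (!is.null(paired_plot_csv)) {
      base <- c(base, "empirical_country", "empirical_regional",
                "empirical_global")
    }
    base
  } else {
    scheme
  }
  files <- character()
  for (sch in schemes) {
    registry <- build_registry_for_cmd(config, sch, paired_plot_csv)
    breakdown <- account_emissions(activity, registry, sch,
                                   sourcing_mix = mix)
    tab <- format_emissions_table(breakdown, digits = NA)
    f_country <- file.path(out_dir, sprintf("emissions_country_%s.csv", sch))
    utils::write.csv(tab, f_country, row.names = FALSE)
    agg_r <- aggregate_emissions(breakdown, "region")
    f_region <- file.path(out_dir, sprintf("emissions_region_%s.csv", sch))
    utils::write.csv(agg_r, f_region, row.names = FALSE)
    agg_g <- aggregate_emissions(breakdown, "global")
    f_global <- file.path(out_dir, sprintf("emissions_global_%s.csv", sch))
    utils::write.csv(agg_g, f_global, row.names = FALSE)
    files <- c(files, f_country, f_region, f_global)
  }
  manifest <- write_manifest(
    out_dir,
    list(activity = activity_csv,
         config = if (is.character(config)) config else NULL,
         paired_plots = paired_plot_csv, sourcing_mix = sourcing_mix_csv),
    files, scheme = scheme)
  invisible(c(files, manifest = manifest))
}

#' Run the Monte Carlo propagation from files
#'
#' As [cmd_account()], but samples every EF `draws` times and writes the
#' per-scope, per-component Monte Carlo summary CSV
#' (`scope_level, scope, component, mean_mt, sd_mt, cv_pct, n_draws, seed`).
#'
#' @inheritParams cmd_account
#' @param draws Number of Monte Carlo draws (default 5000).
#' @param seed Integer seed (required for reproducible runs; if missing a
#'   random seed is drawn and logged).
#' @return Named vector of output files (invisibly).
#' @export
cmd_mc <- function(activity_csv, config, scheme = "ipcc_tier1", draws = 5000,
                   seed = NULL, out_dir = ".", sourcing_mix_csv = NULL,
                   paired_plot_csv = NULL) {
  if (draws < 1) {
    fert_stop("fertghg_config_error", "cmd_mc: --draws must be >= 1")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  activity <- read_activity_table(activity_csv)
  mix <- if (!is.null(sourcing_mix_csv)) {
    utils::read.csv(sourcing_mix_csv, stringsAsFactors = FALSE)
  }
  registry <- build_registry_for_cmd(config, scheme, paired_plot_csv)
  res <- propagate_uncertainty(activity, registry, scheme, n = draws,
                               seed = seed, sourcing_mix = mix)
  out <- data.frame(
    scope_level = res$scope_level, scope = res$scope,
    component = res$component,
    mean_mt = res$mean / 1e6, sd_mt = res$sd / 1e6, cv_pct = res$cv,
    n_draws = res$n_draws, seed = res$seed, stringsAsFactors = FALSE
  )
  f <- file.path(out_dir, sprintf("mc_%s.csv", scheme))
  utils::write.csv(out, f, row.names = FALSE)
  manifest <- write_manifest(
    out_dir,
    list(activity = activity_csv,
         config = if (is.character(config)) config else NULL,
         paired_plots = paired_plot_csv, sourcing_mix = sourcing_mix_csv),
    f, seed = res$seed[1], scheme = scheme)
  invisible(c(mc = f, manifest = manifest))
}

#' Compute indicators from accounting output and activity data
#'
#' Joins a per-country emissions table with the activity table to compute
#' carbon intensity, per-capita footprint, fertilisation rate and component
#' shares; optionally adds growth-rate series (5-year moving average, then
#' annual rate) from a long-format trend CSV.
#'
#' @param breakdown_csv Per-country emissions CSV written by
#'   [cmd_account()] (Mt CO2e).
#' @param activity_csv Activity CSV.
#' @param out_dir Output directory.
#' @param trend_csv Optional long-format CSV `scope, variable, year, value`.
#' @param ma_window Moving-average window for trend smoothing (default 5).
#' @return Named vector of output files (invisibly).
#' @export
cmd_indicators <- function(breakdown_csv, activity_csv, out_dir = ".",
                           trend_csv = NULL, ma_window = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- utils::read.csv(breakdown_csv, stringsAsFactors = FALSE)
  assert_columns(tab, c("country", "n_consumption_mt", "ghg_m", "ghg_t",
                        "ghg_u", "ghg_d", "ghg_v", "ghg_l", "total"),
                 "emissions table")
  activity <- read_activity_table(activity_csv)
  unmatched <- setdiff(tab$country, activity$country)
  if (length(unmatched)) {
    fert_stop("fertghg_schema_error",
              "countries in emissions table missing from activity table: %s",
              paste(unmatched, collapse = ", "))
  }
  act <- activity[match(tab$country, activity$country), ]
  ind <- data.frame(
    country = tab$country,
    carbon_intensity_tco2e_per_tn = carbon_intensity(tab$total,
                                                     tab$n_consumption_mt),
    stringsAsFactors = FALSE
  )
  if (all(is.finite(act$population)) && all(act$population > 0)) {
    ind$per_capita_kgco2e <- per_capita_footprint(tab$total * 1e9,
                                                  act$population)
  } else {
    fert_log("WARN", "cli_io", "per_capita_skipped",
             reason = "missing_population")
  }
  if (all(is.finite(act$cropland_ha)) && all(act$cropland_ha > 0)) {
    ind$fertilisation_rate_kgn_ha <- fertilisation_rate(
      act$n_consumption_t * 1000, act$cropland_ha)
  } else {
    fert_log("WARN", "cli_io", "fertilisation_rate_skipped",
             reason = "missing_cropland")
  }
  shares <- t(apply(tab[, c("ghg_m", "ghg_t", "ghg_d", "ghg_v", "ghg_l",
                            "ghg_u")], 1, component_shares))
  colnames(shares) <- paste0("share_", colnames(shares), "_pct")
  ind <- cbind(ind, as.data.frame(shares))

  files <- c(indicators = file.path(out_dir, "indicators.csv"))
  utils::write.csv(ind, files[["indicators"]], row.names = FALSE)

  if (!is.null(trend_csv)) {
    trends <- utils::read.csv(trend_csv, stringsAsFactors = FALSE)
    assert_columns(trends, c("scope", "variable", "year", "value"),
                   "trend CSV")
    out_rows <- list()
    for (key in split(trends, list(trends$scope, trends$variable),
                      drop = TRUE)) {
      smoothed <- moving_average(key[, c("year", "value")],
                                 window = min(ma_window, nrow(key)))
      rates <- growth_rate_series(smoothed)
      out_rows[[length(out_rows) + 1]] <- data.frame(
        scope = key$scope[1], variable = key$variable[1],
        indicator = "growth_rate_pct", year = rates$year,
        value = rates$value, stringsAsFactors = FALSE)
    }
    gr <- do.call(rbind, out_rows)
    files["growth_rates"] <- file.path(out_dir, "growth_rates.csv")
    utils::write.csv(gr, files[["growth_rates"]], row.names = FALSE)
  }
  manifest <- write_manifest(
    out_dir, list(breakdown = breakdown_csv, activity = activity_csv,
                  trends = trend_csv), files)
  invisible(c(files, manifest = manifest))
}

#' Map a pipeline error to its CLI exit code
#'
#' Exit-code contract: 0 success, 2 input-schema error, 3 configuration
#' error, 4 numerical error, 1 anything else.
#'
#' @param e A condition object.
#' @return Integer exit code.
#' @export
cli_exit_code <- function(e) {
  if (inherits(e, "fertghg_schema_error")) return(2L)
  if (inherits(e, "fertghg_config_error")) return(3L)
  if (inherits(e, "fertghg_numeric_error")) return(4L)
  1L
}
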