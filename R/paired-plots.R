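# Empirical direct soil N2O emission factors from paired-plot measurements.
#
# A paired plot is a fertilised plot and a matched unfertilised control (same
# site, crop and season); the difference between their cumulative N2O-N fluxes,
# divided by the N applied, is the plot-level emission factor. Country EFs are
# means over plots, regional EFs are country means weighted by plot counts,
# and the global EF is the mean of regional EFs weighted by the number of
# countries with data per region.

PAIRED_PLOT_COLUMNS <- c("record_id", "country", "region", "crop",
                         "n_applied_kg_ha", "n2o_treated_kg_ha",
                         "n2o_control_kg_ha", "climate", "fertiliser_type")

#' Read a paired-plot measurement table
#'
#' Reads a CSV of paired-plot N2O flux records. Required columns:
#' `record_id, country, region, crop, n_applied_kg_ha, n2o_treated_kg_ha,
#' n2o_control_kg_ha, climate, fertiliser_type`. Empty cells are missing.
#'
#' @param path Path to a UTF-8 CSV file with "." decimal separator.
#' @return A data.frame with the columns above.
#' @export
read_paired_plots <- function(path) {
  if (!file.exists(path)) {
    fert_stop("fertghg_schema_error", "paired-plot file not found: %s", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  assert_columns(df, PAIRED_PLOT_COLUMNS, sprintf("paired-plot CSV '%s'", path))
  df
}

#' Filter paired-plot records to usable synthetic-fertiliser pairs
#'
#' Keeps only records where synthetic N fertiliser was applied and a valid
#' control pair exists; drops organic/mixed/unfertilised records, records with
#' missing or non-positive N applied, records with missing fluxes, and exact
#' duplicates (same country, crop, N rate and both fluxes). The number of
#' records removed per reason is logged and attached as the
#' `"filter_log"` attribute.
#'
#' @param records Data.frame of raw paired-plot records (see
#'   [read_paired_plots()]).
#' @return The filtered data.frame, with a `filter_log` attribute (named
#'   integer vector of removal counts).
#' @export
#' @examples
#' raw <- data.frame(
#'   record_id = 1:3, country = "FRA", region = "Europe", crop = "wheat",
#'   n_applied_kg_ha = 100, n2o_treated_kg_ha = c(1.2, 1.2, 0.9),
#'   n2o_control_kg_ha = 0.4, climate = "wet",
#'   fertiliser_type = c("synthetic", "organic", "synthetic")
#' )
#' nrow(filter_synthetic_plots(raw))
filter_synthetic_plots <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    fert_stop("fertghg_schema_error",
              "no paired-plot records supplied: unusable dataset")
  }
  assert_columns(records, PAIRED_PLOT_COLUMNS, "paired-plot table")
  log <- c(non_synthetic = 0L, missing_control = 0L, missing_treated = 0L,
           invalid_n_applied = 0L, duplicate = 0L)

  keep <- records$fertiliser_type %in% "synthetic"
  log["non_synthetic"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  bad_control <- is.na(records$n2o_control_kg_ha) |
    !is.finite(records$n2o_control_kg_ha)
  log["missing_control"] <- sum(bad_control)
  records <- records[!bad_control, , drop = FALSE]

  bad_treated <- is.na(records$n2o_treated_kg_ha) |
    !is.finite(records$n2o_treated_kg_ha)
  log["missing_treated"] <- sum(bad_treated)
  records <- records[!bad_treated, , drop = FALSE]

  bad_n <- is.na(records$n_applied_kg_ha) | records$n_applied_kg_ha <= 0
  log["invalid_n_applied"] <- sum(bad_n)
  records <- records[!bad_n, , drop = FALSE]

  dup <- duplicated(records[, c("country", "crop", "n_applied_kg_ha",
                                "n2o_treated_kg_ha", "n2o_control_kg_ha")])
  log["duplicate"] <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  if (nrow(records) == 0) {
    fert_stop("fertghg_schema_error",
              "no usable synthetic-fertiliser paired-plot records remain")
  }
  for (reason in names(log)) {
    if (log[[reason]] > 0) {
      fert_log("INFO", "ef_direct", "records_removed",
               reason = reason, n = log[[reason]])
    }
  }
  attr(records, "filter_log") <- log
  records
}

#' Plot-level emission factor
#'
#' The fertiliser-attributable N2O-N flux (treated minus control plot),
#' expressed as a dimensionless fraction of the N applied. Negative values
#' occur when the control plot out-emitted the fertilised plot and are
#' retained (truncating them would bias country means upward).
#'
#' @param n2o_treated Cumulative N2O-N from the fertilised plot (kg/ha).
#' @param n2o_control Cumulative N2O-N from the paired control plot (kg/ha).
#' @param n_applied N applied to the fertilised plot (kg N/ha); must be > 0.
#' @return kg N2O-N emitted per kg N applied (dimensionless fraction).
#' @export
#' @examples
#' plot_level_ef(1.5, 0.5, 100)   # 0.01
#' plot_level_ef(0.3, 0.5, 100)   # -0.002, negative EFs are kept
plot_level_ef <- function(n2o_treated, n2o_control, n_applied) {
  if (any(!is.finite(n_applied)) || any(n_applied <= 0)) {
    fert_stop("fertghg_schema_error",
              "plot_level_ef: n_applied must be finite and > 0")
  }
  (n2o_treated - n2o_control) / n_applied
}

#' Country-level direct emission factors
#'
#' For each country, the mean and sample standard deviation (n - 1
#' denominator) of its plot-level EFs. Countries contributing a single plot
#' get `sd = 0` and a logged warning. The estimates carry a lognormal pdf
#' label, the distribution family used downstream for empirical EFs.
#'
#' @param records Filtered paired-plot data.frame
#'   (see [filter_synthetic_plots()]).
#' @return Data.frame with columns `level, scope, region, mean, sd, n_points,
#'   pdf`, one row per country.
#' @export
estimate_country_efs <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    fert_stop("fertghg_schema_error", "estimate_country_efs: no records")
  }
  ef <- plot_level_ef(records$n2o_treated_kg_ha, records$n2o_control_kg_ha,
                      records$n_applied_kg_ha)
  split_idx <- split(seq_along(ef), records$country)
  rows <- lapply(names(split_idx), function(ctry) {
    idx <- split_idx[[ctry]]
    n <- length(idx)
    sd_val <- if (n == 1) 0 else stats::sd(ef[idx])
    if (n == 1) {
      fert_log("WARN", "ef_direct", "single_record_country",
               country = ctry, sd = 0)
    }
    data.frame(level = "country", scope = ctry,
               region = records$region[idx[1]],
               mean = mean(ef[idx]), sd = sd_val, n_points = n,
               pdf = "lognormal", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "plot_efs") <- data.frame(country = records$country,
                                      region = records$region, ef = ef,
                                      stringsAsFactors = FALSE)
  out
}

#' Regional direct emission factors
#'
#' Regional mean = sum(country mean x country n_points) / sum(n_points) over
#' member countries, i.e. national EFs weighted by the number of plots behind
#' each. The regional sd is the sample sd of the pooled plot-level EFs of all
#' member countries (pooling preserves within-country dispersion, which
#' country-level sds alone would lose). Regions with no member countries are
#' absent from the output.
#'
#' @param country_efs Output of [estimate_country_efs()] (must carry its
#'   `plot_efs` attribute, or pass `plot_efs` explicitly).
#' @param plot_efs Optional data.frame `country, region, ef` of plot-level
#'   EFs used for the pooled regional sd.
#' @return Data.frame `level, scope, mean, sd, n_points, n_countries, pdf`,
#'   one row per region with data.
#' @export
estimate_regional_efs <- function(country_efs, plot_efs = NULL) {
  stopifnot(nrow(country_efs) >= 1)
  plot_efs <- plot_efs %||% attr(country_efs, "plot_efs")
  split_idx <- split(seq_len(nrow(country_efs)), country_efs$region)
  rows <- lapply(names(split_idx), function(reg) {
    idx <- split_idx[[reg]]
    n_pts <- sum(country_efs$n_points[idx])
    m <- sum(country_efs$mean[idx] * country_efs$n_points[idx]) / n_pts
    if (!is.null(plot_efs)) {
      pooled <- plot_efs$ef[plot_efs$region == reg]
      sd_val <- if (length(pooled) > 1) stats::sd(pooled) else 0
    } else {
      # no plot-level data available (e.g. user-supplied country table):
      # fall back to the points-weighted sd of country means
      sd_val <- sqrt(sum(country_efs$n_points[idx] *
                           (country_efs$mean[idx] - m)^2) / max(n_pts - 1, 1))
    }
    data.frame(level = "region", scope = reg, mean = m, sd = sd_val,
               n_points = n_pts, n_countries = length(idx),
               pdf = "lognormal", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Global direct emission factor
#'
#' Mean of the regional EFs weighted by the number of countries contributing
#' data in each region (countries-with-data, not all countries of the
#' region). The sd is the country-count-weighted sample sd of the regional
#' means.
#'
#' @param regional_efs Output of [estimate_regional_efs()].
#' @param countries_per_region Optional named vector overriding the
#'   country-count weights; defaults to the `n_countries` column.
#' @return One-row data.frame `level, scope, mean, sd, n_points, pdf`.
#' @export
estimate_global_ef <- function(regional_efs, countries_per_region = NULL) {
  if (is.null(regional_efs) || nrow(regional_efs) == 0) {
    fert_stop("fertghg_schema_error", "estimate_global_ef: no regional EFs")
  }
  w <- if (is.null(countries_per_region)) {
    regional_efs$n_countries
  } else {
    unname(countries_per_region[regional_efs$scope])
  }
  if (any(is.na(w)) || any(w < 1)) {
    fert_stop("fertghg_schema_error",
              "estimate_global_ef: every region needs a country count >= 1")
  }
  m <- sum(regional_efs$mean * w) / sum(w)
  sd_val <- if (nrow(regional_efs) > 1) {
    sqrt(sum(w * (regional_efs$mean - m)^2) / max(sum(w) - 1, 1))
  } else {
    regional_efs$sd[1]
  }
  data.frame(level = "global", scope = "global", mean = m, sd = sd_val,
             n_points = sum(regional_efs$n_points), pdf = "lognormal",
             stringsAsFactors = FALSE)
}

#' Estimate direct EFs at all levels
#'
#' Convenience wrapper: filters the raw records, then computes country,
#' regional and global EF estimates.
#'
#' @param records Raw paired-plot data.frame.
#' @return List with elements `country`, `region`, `global` (data.frames) and
#'   `filter_log`.
#' @export
estimate_direct_efs <- function(records) {
  kept <- filter_synthetic_plots(records)
  country <- estimate_country_efs(kept)
  region <- estimate_regional_efs(country)
  globl <- estimate_global_ef(region)
  list(country = country, region = region, global = globl,
       filter_log = attr(kept, "filter_log"))
}
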