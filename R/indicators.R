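# Derived indicators (carbon intensity, per-capita footprint, component
# shares, fertilisation rate) and historical-trend computations (two-point
# growth rates, centred moving averages).

#' Carbon intensity of the fertiliser supply chain
#'
#' Total GHG emissions divided by total N consumed, tCO2e per tonne N. The
#' ratio is invariant under joint rescaling of both arguments.
#'
#' @param total_co2e Total emissions (tCO2e).
#' @param total_n Total N consumed (t N); must be > 0.
#' @return tCO2e per t N.
#' @export
#' @examples
#' carbon_intensity(1129.1, 107.74)  # ~10.48
carbon_intensity <- function(total_co2e, total_n) {
  if (any(total_n <= 0)) {
    fert_stop("fertghg_schema_error", "carbon_intensity: total_n must be > 0")
  }
  total_co2e / total_n
}

#' Per-capita carbon footprint
#'
#' @param total_co2e_kg Total emissions in kg CO2e.
#' @param population Persons; must be > 0.
#' @return kg CO2e per person.
#' @export
#' @examples
#' per_capita_footprint(296.2, 2)  # 148.1
per_capita_footprint <- function(total_co2e_kg, population) {
  if (any(population <= 0)) {
    fert_stop("fertghg_schema_error",
              "per_capita_footprint: population must be > 0")
  }
  total_co2e_kg / population
}

#' Component shares of a total emissions breakdown
#'
#' Each of the six components as a percentage of the breakdown's total.
#' Shares sum to 100 within 1e-9.
#'
#' @param breakdown A one-row emissions breakdown (or any list/row with
#'   `ghg_m, ghg_t, ghg_d, ghg_v, ghg_l, ghg_u`). The total used is the
#'   exact component sum.
#' @return Named numeric vector of percentages.
#' @export
component_shares <- function(breakdown) {
  comp <- c(ghg_m = breakdown[["ghg_m"]], ghg_t = breakdown[["ghg_t"]],
            ghg_d = breakdown[["ghg_d"]], ghg_v = breakdown[["ghg_v"]],
            ghg_l = breakdown[["ghg_l"]], ghg_u = breakdown[["ghg_u"]])
  total <- sum(comp)
  if (total <= 0) {
    fert_stop("fertghg_schema_error", "component_shares: total must be > 0")
  }
  100 * comp / total
}

#' Two-point growth rate
#'
#' `(v_t1 / v_t0 - 1) x 100`, percent. Undefined for a zero base value, in
#' which case `NA` is returned.
#'
#' @param v_t1 Value at the later time.
#' @param v_t0 Value at the earlier time.
#' @return Percent growth.
#' @export
#' @examples
#' growth_rate(115, 100)  # 15
growth_rate <- function(v_t1, v_t0) {
  ifelse(is.na(v_t0) | is.na(v_t1) | v_t0 == 0, NA_real_,
         (v_t1 / v_t0 - 1) * 100)
}

#' Annual growth-rate series
#'
#' Applies [growth_rate()] along a year-indexed series with a configurable
#' lag (default 1 year). Rates spanning a gap in the years are reported
#' missing rather than interpolated (no gap-filling).
#'
#' @param series Data.frame with columns `year` and `value`.
#' @param lag Years between the compared points.
#' @return Data.frame `year, value` where `value` is the percent growth at
#'   each year with a valid base `lag` years earlier.
#' @export
growth_rate_series <- function(series, lag = 1) {
  stopifnot(lag >= 1)
  series <- series[order(series$year), , drop = FALSE]
  base_idx <- match(series$year - lag, series$year)
  data.frame(
    year = series$year,
    value = ifelse(is.na(base_idx), NA_real_,
                   growth_rate(series$value, series$value[base_idx]))
  )
}

#' Centred moving average of a yearly series
#'
#' Arithmetic mean over a centred window; edge years whose window is
#' incomplete are omitted from the output.
#'
#' @param series Data.frame with columns `year` and `value`, years
#'   contiguous and strictly increasing.
#' @param window Window length (default 5); must be between 1 and the series
#'   length.
#' @return Data.frame `year, value`, shorter than the input by
#'   `window - 1` rows.
#' @export
#' @examples
#' moving_average(data.frame(year = 1:5, value = 1:5), window = 5)
moving_average <- function(series, window = 5) {
  series <- series[order(series$year), , drop = FALSE]
  if (window < 1 || window > nrow(series)) {
    fert_stop("fertghg_schema_error",
              "moving_average: window must be in [1, length(series)]")
  }
  if (any(diff(series$year) != 1)) {
    fert_stop("fertghg_schema_error",
              "moving_average: series years must be contiguous")
  }
  sm <- stats::filter(series$value, rep(1 / window, window), sides = 2)
  keep <- !is.na(sm)
  data.frame(year = series$year[keep], value = as.numeric(sm[keep]))
}

#' Fertilisation rate
#'
#' N applied per hectare of cropland.
#'
#' @param n_use_kg N use in kg.
#' @param cropland_ha Cropland area in hectares; must be > 0.
#' @return kg N per ha.
#' @export
#' @examples
#' fertilisation_rate(110000, 1000)  # 110 kg N/ha
fertilisation_rate <- function(n_use_kg, cropland_ha) {
  if (any(cropland_ha <= 0)) {
    fert_stop("fertghg_schema_error",
              "fertilisation_rate: cropland_ha must be > 0")
  }
  n_use_kg / cropland_ha
}
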