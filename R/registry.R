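# Central registry of emission factors and constants: direct-EF schemes,
# indirect (volatilisation/leaching) factors, urea hydrolysis, and the
# manufacturing and transport EF tables. Everything is overridable via a
# YAML config; defaults carry provenance labels so substituted values stay
# visible in logs and output.

default_constants <- function() {
  list(gwp = 265,                 # N2O GWP-100; configurable
       urea_n_content = 0.466,
       uan_n_content = 0.30,
       uan_urea_fraction = 0.35)
}

# Direct soil EF schemes. The IPCC aggregated (Tier 1) factor is 0.010 with
# sd 0.009 on range 0.001-0.018; the wet/dry disaggregation gives wet
# 0.016 +/- 0.003 (0.013-0.019) and dry 0.005 +/- 0.006 (-0.001 to 0.011).
# Both are sampled as truncated normals; empirical EFs are lognormal.
default_direct_schemes <- function() {
  list(
    ipcc_tier1 = ef_spec("direct|global", 0.010, 0.009, 0.001, 0.018,
                         "normal", "paper"),
    ipcc_wetdry = list(
      wet = ef_spec("direct|wet", 0.016, 0.003, 0.013, 0.019, "normal", "paper"),
      dry = ef_spec("direct|dry", 0.005, 0.006, -0.001, 0.011, "normal", "paper")
    )
  )
}

# Indirect-emission factors by climate class. The accounting text cites the
# IPCC 2019 Refinement (ch. 11) without printing numbers, so these defaults
# are explicit stand-ins labelled "IPCC-2019-default" and overridable by
# config. FRAC terms carry sd 0.05 (normal); the dry-climate leaching
# fraction is a structural zero, so its sd is 0.
default_indirect_factors <- function() {
  lab <- "IPCC-2019-default"
  list(
    wet = list(
      frac_gasf = ef_spec("frac_gasf|wet", 0.11, 0.05, 0, 1, "normal", lab),
      ef4 = ef_spec("ef4|wet", 0.014, 0.004, 0.011, 0.017, "normal", lab),
      frac_leach = ef_spec("frac_leach|wet", 0.24, 0.05, 0.01, 0.73, "normal", lab),
      ef5 = ef_spec("ef5|wet", 0.011, 0.005, 0.000, 0.020, "normal", lab)
    ),
    dry = list(
      frac_gasf = ef_spec("frac_gasf|dry", 0.11, 0.05, 0, 1, "normal", lab),
      ef4 = ef_spec("ef4|dry", 0.005, 0.004, 0.000, 0.011, "normal", lab),
      frac_leach = ef_spec("frac_leach|dry", 0.00, 0.00, 0, 0, "normal", lab),
      ef5 = ef_spec("ef5|dry", 0.011, 0.005, 0.000, 0.020, "normal", lab)
    )
  )
}

default_urea_ef <- function() {
  # tCO2-C released per tonne of urea-equivalent product hydrolysing in soil
  ef_spec("ef_urea", 0.2, 0.1, 0, 0.4, "normal", "paper")
}

#' Read a manufacturing EF table
#'
#' CSV columns: `region, product, mean_tco2e_per_t, sd, min, max, pdf`; one
#' row per (region of production, product group), units tCO2e per tonne of
#' product at the factory gate.
#'
#' @param path CSV path.
#' @return Data.frame keyed by (region, product) with `ef_spec` columns.
#' @export
read_manufacturing_ef <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  assert_columns(df, c("region", "product", "mean_tco2e_per_t", "sd", "min",
                       "max", "pdf"), sprintf("manufacturing EF CSV '%s'", path))
  names(df)[names(df) == "mean_tco2e_per_t"] <- "mean"
  df
}

#' Read a transport EF table
#'
#' As [read_manufacturing_ef()] plus a `region_to` column: one row per
#' (region of production, region of consumption, product group), tCO2e per
#' tonne of product transported.
#'
#' @param path CSV path.
#' @return Data.frame keyed by (region, region_to, product).
#' @export
read_transport_ef <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  assert_columns(df, c("region", "region_to", "product", "mean_tco2e_per_t",
                       "sd", "min", "max", "pdf"),
                 sprintf("transport EF CSV '%s'", path))
  names(df)[names(df) == "mean_tco2e_per_t"] <- "mean"
  df
}

#' Build a fully resolved EF registry
#'
#' Assembles every constant and emission factor the accounting uses, starting
#' from package defaults and applying overrides from a YAML config. The
#' config may contain sections `constants` (gwp, urea_n_content,
#' uan_n_content, uan_urea_fraction), `direct_ef_schemes`,
#' `indirect_factors`, `urea_ef`, and `manufacturing_ef` / `transport_ef`
#' (paths to the EF CSVs). Every overridden value is relabelled with
#' provenance `"user"` and logged. The stoichiometric conversions 44/28
#' (N2O-N to N2O) and 44/12 (CO2-C to CO2) are constants, not configurable.
#'
#' @param config `NULL` (all defaults), a path to a YAML file, or an
#'   equivalent nested list.
#' @param manufacturing_ef,transport_ef Optional EF tables (data.frames as
#'   returned by the readers) taking precedence over config paths.
#' @param empirical Optional result of [estimate_direct_efs()], enabling the
#'   `empirical_*` direct-EF schemes.
#' @return An object of class `ef_registry`.
#' @export
load_registry <- function(config = NULL, manufacturing_ef = NULL,
                          transport_ef = NULL, empirical = NULL) {
  cfg <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config)
  } else {
    config
  }
  constants <- default_constants()
  for (key in intersect(names(cfg$constants %||% list()), names(constants))) {
    constants[[key]] <- cfg$constants[[key]]
    fert_log("INFO", "ef_registry", "constant_override", key = key,
             value = constants[[key]], provenance = "user")
  }

  schemes <- default_direct_schemes()
  for (nm in names(cfg$direct_ef_schemes %||% list())) {
    ov <- cfg$direct_ef_schemes[[nm]]
    if (nm == "ipcc_tier1") {
      schemes$ipcc_tier1 <- ef_spec("direct|global", ov$mean, ov$sd,
                                    ov$min %||% -Inf, ov$max %||% Inf,
                                    ov$pdf %||% "normal", "user")
    } else if (nm == "ipcc_wetdry") {
      for (cl in intersect(names(ov), c("wet", "dry"))) {
        o <- ov[[cl]]
        schemes$ipcc_wetdry[[cl]] <- ef_spec(paste0("direct|", cl), o$mean,
                                             o$sd, o$min %||% -Inf,
                                             o$max %||% Inf,
                                             o$pdf %||% "normal", "user")
      }
    }
  }

  indirect <- default_indirect_factors()
  for (cl in intersect(names(cfg$indirect_factors %||% list()), c("wet", "dry"))) {
    for (term in intersect(names(cfg$indirect_factors[[cl]]),
                           c("frac_gasf", "ef4", "frac_leach", "ef5"))) {
      o <- cfg$indirect_factors[[cl]][[term]]
      cur <- indirect[[cl]][[term]]
      indirect[[cl]][[term]] <- ef_spec(cur$name, o$mean %||% cur$mean,
                                        o$sd %||% cur$sd, o$min %||% cur$min,
                                        o$max %||% cur$max,
                                        o$pdf %||% cur$pdf, "user")
    }
  }

  urea <- default_urea_ef()
  if (!is.null(cfg$urea_ef)) {
    o <- cfg$urea_ef
    urea <- ef_spec("ef_urea", o$mean %||% urea$mean, o$sd %||% urea$sd,
                    o$min %||% urea$min, o$max %||% urea$max,
                    o$pdf %||% urea$pdf, "user")
  }

  if (is.null(manufacturing_ef) && !is.null(cfg$manufacturing_ef)) {
    manufacturing_ef <- read_manufacturing_ef(cfg$manufacturing_ef)
  }
  if (is.null(transport_ef) && !is.null(cfg$transport_ef)) {
    transport_ef <- read_transport_ef(cfg$transport_ef)
  }

  structure(
    list(constants = constants, direct_schemes = schemes, indirect = indirect,
         urea_ef = urea, manufacturing_ef = manufacturing_ef,
         transport_ef = transport_ef, empirical = empirical),
    class = "ef_registry"
  )
}

#' @export
print.ef_registry <- function(x, ...) {
  cat("<ef_registry>\n")
  cat(sprintf("  gwp: %g\n", x$constants$gwp))
  cat(sprintf("  manufacturing EF rows: %s\n",
              if (is.null(x$manufacturing_ef)) "none" else nrow(x$manufacturing_ef)))
  cat(sprintf("  transport EF rows: %s\n",
              if (is.null(x$transport_ef)) "none" else nrow(x$transport_ef)))
  cat(sprintf("  empirical direct EFs: %s\n",
              if (is.null(x$empirical)) "none" else
                sprintf("%d countries", nrow(x$empirical$country))))
  invisible(x)
}

#' Resolve the direct soil EF for a country under a scheme
#'
#' Pure lookup: the same inputs always return the same `ef_spec`.
#' Schemes:
#' \describe{
#'   \item{ipcc_tier1}{the single global factor 0.010 for every country.}
#'   \item{ipcc_wetdry}{0.016 (wet) or 0.005 (dry) by the country's climate.}
#'   \item{empirical_country}{the country's own empirical estimate, falling
#'     back to its region and then to the global empirical estimate.}
#'   \item{empirical_regional}{the region's empirical estimate (global
#'     fallback).}
#'   \item{empirical_global}{the global empirical estimate.}
#' }
#' Empirical estimates are lognormal; an empirical mean <= 0 cannot be
#' moment-matched to a lognormal, so such estimates are returned with a
#' normal pdf instead.
#'
#' @param registry An `ef_registry`.
#' @param scheme One of the scheme names above.
#' @param country Country code (empirical_country lookup).
#' @param region Region label (wet/dry has no use for it; empirical fallback
#'   does).
#' @param climate `"wet"` or `"dry"` (ipcc_wetdry and unknown-climate
#'   fallback resolves to wet with a warning).
#' @return An `ef_spec`.
#' @export
get_direct_ef <- function(registry, scheme, country = NULL, region = NULL,
                          climate = c("wet", "dry")) {
  schemes <- c("ipcc_tier1", "ipcc_wetdry", "empirical_global",
               "empirical_regional", "empirical_country")
  if (!scheme %in% schemes) {
    fert_stop("fertghg_config_error", "unknown direct-EF scheme '%s'", scheme)
  }
  if (scheme == "ipcc_tier1") return(registry$direct_schemes$ipcc_tier1)
  if (scheme == "ipcc_wetdry") {
    climate <- match.arg(climate)
    return(registry$direct_schemes$ipcc_wetdry[[climate]])
  }
  emp <- registry$empirical
  if (is.null(emp)) {
    fert_stop("fertghg_config_error",
              "scheme '%s' requires empirical EF estimates in the registry",
              scheme)
  }
  empirical_spec <- function(row, level_tag) {
    pdf <- if (row$mean > 0) "lognormal" else "normal"
    ef_spec(paste0("direct|", level_tag), row$mean, row$sd,
            pdf = pdf, provenance = "empirical")
  }
  if (scheme == "empirical_country" && !is.null(country)) {
    hit <- emp$country[emp$country$scope == country, , drop = FALSE]
    if (nrow(hit) == 1) return(empirical_spec(hit, country))
  }
  if (scheme %in% c("empirical_country", "empirical_regional") &&
      !is.null(region)) {
    hit <- emp$region[emp$region$scope == region, , drop = FALSE]
    if (nrow(hit) == 1) return(empirical_spec(hit, region))
  }
  if (nrow(emp$global) == 1) return(empirical_spec(emp$global, "global"))
  fert_stop("fertghg_config_error",
            "no empirical EF available for country=%s region=%s at any level",
            country %||% "?", region %||% "?")
}

# Lookup of one manufacturing EF row; errors name the missing pair.
lookup_manufacturing_ef <- function(table, region, product) {
  hit <- table[table$region == region & table$product == product, , drop = FALSE]
  if (nrow(hit) != 1) {
    fert_stop("fertghg_config_error",
              "manufacturing EF missing for (region=%s, product=%s)",
              region, product)
  }
  hit
}

lookup_transport_ef <- function(table, region_from, region_to, product) {
  hit <- table[table$region == region_from & table$region_to == region_to &
                 table$product == product, , drop = FALSE]
  if (nrow(hit) != 1) {
    fert_stop("fertghg_config_error",
              "transport EF missing for (from=%s, to=%s, product=%s)",
              region_from, region_to, product)
  }
  hit
}
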