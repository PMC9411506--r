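#' Emission-factor specification
#'
#' An `ef_spec` bundles an emission factor's central value with its
#' uncertainty description: standard deviation, truncation bounds and the
#' probability density family used when the factor is sampled in Monte Carlo
#' propagation. It is the atom of every uncertainty calculation in the
#' package: field EFs are dimensionless fractions of N applied, manufacturing
#' and transport EFs are tCO2e per tonne of product, and the urea hydrolysis
#' EF is tCO2-C per tonne of urea-equivalent product.
#'
#' @param name Identifier, unique within a registry.
#' @param mean Central value (units depend on context, see above).
#' @param sd Standard deviation on the same scale; must be >= 0.
#' @param min,max Truncation bounds for sampling; default unbounded. Draws
#'   outside `[min, max]` are rejected and redrawn, never clamped.
#' @param pdf `"normal"` or `"lognormal"`. Lognormal specs are
#'   moment-matched so the natural-scale mean and sd equal `mean` and `sd`.
#' @param provenance Free-text label recording where the value came from
#'   (e.g. `"default"`, `"IPCC-2019-default"`, `"user"`, `"empirical"`).
#'
#' @return An object of class `ef_spec` (a named list).
#' @export
#' @examples
#' ef_spec("ipcc_tier1", mean = 0.010, sd = 0.009, min = 0.001, max = 0.018)
ef_spec <- function(name, mean, sd, min = -Inf, max = Inf,
                    pdf = c("normal", "lognormal"), provenance = "default") {
  pdf <- match.arg(pdf)
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(mean), length(mean) == 1, is.finite(mean),
            is.numeric(sd), length(sd) == 1, is.finite(sd))
  if (sd < 0) fert_stop("fertghg_config_error", "ef_spec '%s': sd must be >= 0", name)
  if (min > mean || mean > max) {
    fert_stop("fertghg_config_error",
              "ef_spec '%s': requires min <= mean <= max (got %g, %g, %g)",
              name, min, mean, max)
  }
  structure(
    list(name = name, mean = mean, sd = sd, min = min, max = max,
         pdf = pdf, provenance = provenance),
    class = "ef_spec"
  )
}

#' @export
print.ef_spec <- function(x, ...) {
  bounds <- if (is.finite(x$min) || is.finite(x$max)) {
    sprintf(" in [%g, %g]", x$min, x$max)
  } else ""
  cat(sprintf("<ef_spec> %s: %g +/- %g (%s%s) [%s]\n",
              x$name, x$mean, x$sd, x$pdf, bounds, x$provenance))
  invisible(x)
}

#' @export
as.data.frame.ef_spec <- function(x, ...) {
  data.frame(name = x$name, mean = x$mean, sd = x$sd, min = x$min,
             max = x$max, pdf = x$pdf, provenance = x$provenance,
             stringsAsFactors = FALSE)
}

ef_spec_from_row <- function(row, name, provenance = "user") {
  ef_spec(name,
          mean = as.numeric(row[["mean"]]),
          sd = as.numeric(row[["sd"]]),
          min = if (is.na(row[["min"]])) -Inf else as.numeric(row[["min"]]),
          max = if (is.na(row[["max"]])) Inf else as.numeric(row[["max"]]),
          pdf = as.character(row[["pdf"]]),
          provenance = provenance)
}
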