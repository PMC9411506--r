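# Shared constants and small internal helpers.

#' World regions used for aggregation
#'
#' The nine-region classification used throughout the accounting: country
#' estimates roll up to these regions and regions roll up to the global total.
#'
#' @return Character vector of the nine region labels.
#' @export
#' @examples
#' fert_regions()
fert_regions <- function() {
  c("East Asia", "South Asia", "Europe", "North America", "Latin America",
    "Africa", "Middle East", "Oceania", "Russian Commonwealth")
}

#' Fertiliser product groups
#'
#' The eight product groups over which national nitrogen consumption is
#' allocated for manufacturing and transport accounting: anhydrous ammonia,
#' ammonium nitrate (AN), ammonium sulphate (AS), calcium ammonium nitrate
#' (CAN), urea, urea-ammonium-nitrate solutions (UAN), ammonium phosphates
#' (AP) and NPK compounds.
#'
#' @return Character vector of the eight product-group codes.
#' @export
#' @examples
#' fert_products()
fert_products <- function() {
  c("ammonia", "AN", "AS", "CAN", "urea", "UAN", "AP", "NPK")
}

# Mass-conversion constants. These are stoichiometric and not configurable:
# 44/28 converts t N2O-N to t N2O; 44/12 converts t CO2-C to t CO2.
N2O_N_TO_N2O <- 44 / 28
CO2_C_TO_CO2 <- 44 / 12

# Structured logging: one line per event on stderr, suppressible via option.
fert_log <- function(level, module, event, ...) {
  if (isTRUE(getOption("fertghg.quiet", FALSE)) &&
      !level %in% c("WARN", "ERROR")) {
    return(invisible(NULL))
  }
  extras <- list(...)
  kv <- if (length(extras)) {
    paste(names(extras), unlist(extras), sep = "=", collapse = " ")
  } else {
    ""
  }
  message(sprintf("[%s] %s: %s %s", level, module, event, kv))
  invisible(NULL)
}

# Deterministic sub-seed derivation: one named substream per generator so that
# changing one generator's parameters does not shift another's draws. Kept
# below 2^31 - 1 for R's 32-bit integer seeds.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(seed) * 2654435 + h * 97 + 1) %% (2^31 - 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stops with a classed condition so the CLI layer can map error families to
# exit codes without string matching.
fert_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "fertghg_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    fert_stop("fertghg_schema_error", "%s is missing required column(s): %s",
              what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
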