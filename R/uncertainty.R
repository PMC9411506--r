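# Monte Carlo propagation of emission-factor uncertainty through the
# accounting chain. Each EF is sampled once per iteration and the draw is
# shared by every country that uses that EF (full correlation within an EF,
# independence across EFs): national randomness comes entirely from the EFs,
# which is why aggregate uncertainty is smaller than the most uncertain
# component but does not vanish with the number of countries.

#' Sample an emission factor
#'
#' Draws `n` values from the spec's distribution. Normal specs use
#' `rnorm(mean, sd)`; lognormal specs are moment-matched so that the
#' natural-scale mean and sd of the distribution equal `spec$mean` and
#' `spec$sd`. Draws outside `[min, max]` are rejected and redrawn (never
#' clamped: clamping would pile probability mass on the bounds and bias the
#' mean). Identical `(spec, n, seed)` give identical draws.
#'
#' @param spec An [ef_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored afterwards).
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' spec <- ef_spec("tier1", 0.010, 0.009, 0.001, 0.018, "normal")
#' mean(sample_ef(spec, 5000, seed = 1))
sample_ef <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "ef_spec"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (spec$sd == 0) return(rep(spec$mean, n))
  if (spec$pdf == "lognormal" && spec$mean <= 0) {
    fert_stop("fertghg_config_error",
              paste("ef_spec '%s': lognormal sampling needs mean > 0;",
                    "use a shifted-lognormal or a normal pdf override"),
              spec$name)
  }
  draw <- if (spec$pdf == "lognormal") {
    sigma2 <- log(1 + (spec$sd / spec$mean)^2)
    mu <- log(spec$mean) - sigma2 / 2
    function(k) stats::rlnorm(k, meanlog = mu, sdlog = sqrt(sigma2))
  } else {
    function(k) stats::rnorm(k, mean = spec$mean, sd = spec$sd)
  }
  out <- draw(n)
  bad <- which(out < spec$min | out > spec$max)
  tries <- 0
  while (length(bad) > 0) {
    out[bad] <- draw(length(bad))
    bad <- bad[out[bad] < spec$min | out[bad] > spec$max]
    tries <- tries + 1
    if (tries > 10000) {
      fert_stop("fertghg_numeric_error",
                "ef_spec '%s': rejection sampling cannot satisfy [%g, %g]",
                spec$name, spec$min, spec$max)
    }
  }
  out
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`. Undefined for a zero mean, in which case `NA` is
#' returned (reported as missing downstream).
#'
#' @param mean,sd Summary statistics on the same scale.
#' @return Percent CV, or `NA` when `mean == 0`.
#' @export
#' @examples
#' coefficient_of_variation(1129.1, 171.1)  # ~15.2
coefficient_of_variation <- function(mean, sd) {
  ifelse(mean == 0, NA_real_, 100 * sd / mean)
}

#' Propagate EF uncertainty through the accounting chain
#'
#' Runs the full accounting `n` times, once per Monte Carlo iteration: every
#' emission factor is sampled once per iteration and the same draw is used
#' by all countries sharing that EF, then the Eqs.-style chain is evaluated
#' and the per-country components summed to regional and global scopes.
#' Results are summarised per scope x component as the sample mean, sample
#' sd and CV over draws.
#'
#' @inheritParams build_inventory_model
#' @param n Number of draws (default 5000).
#' @param seed Integer seed; required for reproducible runs. If `NULL`, a
#'   random seed is taken and logged.
#' @param keep_draws If `TRUE`, the raw per-draw global component matrix is
#'   attached as attribute `"draws"` (for diagnostics and tests).
#' @return Data.frame of class `mc_result`: `scope_level, scope, component,
#'   mean, sd, cv, n_draws, seed` with emissions in tCO2e.
#' @export
propagate_uncertainty <- function(activity, registry, scheme = "ipcc_tier1",
                                  n = 5000, seed = NULL, sourcing_mix = NULL,
                                  region_of_production = NULL,
                                  keep_draws = FALSE) {
  if (n < 1) {
    fert_stop("fertghg_config_error", "propagate_uncertainty: n must be >= 1")
  }
  if (is.null(seed)) {
    seed <- sample.int(2^31 - 2, 1)
    fert_log("WARN", "uncertainty_mc", "random_seed_drawn", seed = seed)
  }
  model <- build_inventory_model(activity, registry, scheme, sourcing_mix,
                                 region_of_production)
  S <- length(model$specs)
  draws <- matrix(0, nrow = n, ncol = S)
  for (s in seq_len(S)) {
    draws[, s] <- sample_ef(model$specs[[s]], n,
                            seed = substream_seed(seed, names(model$specs)[s]))
  }
  comps <- evaluate_model(model, draws)

  components <- c("ghg_m", "ghg_t", "ghg_d", "ghg_v", "ghg_l", "ghg_u", "total")
  region_of <- model$activity$region
  summarise_scope <- function(level, scope, cols) {
    do.call(rbind, lapply(components, function(cmp) {
      v <- if (length(cols) == 1) comps[[cmp]][, cols] else
        rowSums(comps[[cmp]][, cols, drop = FALSE])
      m <- mean(v)
      s_d <- stats::sd(v)
      data.frame(scope_level = level, scope = scope, component = cmp,
                 mean = m, sd = s_d, cv = coefficient_of_variation(m, s_d),
                 n_draws = n, seed = seed, stringsAsFactors = FALSE)
    }))
  }

  out <- list()
  for (c_i in seq_along(model$activity$country)) {
    out[[length(out) + 1]] <-
      summarise_scope("country", model$activity$country[c_i], c_i)
  }
  for (reg in unique(region_of)) {
    out[[length(out) + 1]] <-
      summarise_scope("region", reg, which(region_of == reg))
  }
  out[[length(out) + 1]] <-
    summarise_scope("global", "global", seq_along(region_of))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mc_result", "data.frame")
  if (keep_draws) {
    glob <- vapply(components, function(cmp) rowSums(comps[[cmp]]),
                   numeric(n))
    attr(res, "draws") <- glob
  }
  res
}
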