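# Deterministic accounting of the synthetic-N fertiliser chain: per-country
# manufacturing, transport, direct soil, indirect (volatilisation, leaching)
# and urea-hydrolysis emissions in tCO2e, and their regional/global
# aggregation. The per-country computation is expressed once as a linear
# model in the emission factors (coefficient matrices x EF vector); the
# deterministic engine evaluates it at the EF means and the Monte Carlo
# engine evaluates the same model at sampled EF draws, so the two can never
# disagree about the accounting itself.

#' Manufacturing emissions for a set of product consumptions
#'
#' Consumption-based accounting: the tonnes of each fertiliser product
#' consumed, multiplied by the factory-gate EF of the region where it was
#' produced, summed over products.
#'
#' @param products Data.frame `country, product, n_tonnes, product_tonnes`
#'   (see [allocate_products()]).
#' @param table Manufacturing EF table ([read_manufacturing_ef()]).
#' @param region_of_production Named character vector mapping country to its
#'   region of production; defaults to the single region given in
#'   `default_region`.
#' @param default_region Region used for countries absent from
#'   `region_of_production`.
#' @return Total tCO2e (EF means; the stochastic version lives in
#'   [propagate_uncertainty()]).
#' @export
manufacturing_emissions <- function(products, table,
                                    region_of_production = NULL,
                                    default_region = NULL) {
  if (nrow(products) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(products))) {
    reg <- region_of_production[[products$country[i]]] %||% default_region
    if (is.null(reg)) {
      fert_stop("fertghg_config_error",
                "no region of production for country '%s'", products$country[i])
    }
    ef <- lookup_manufacturing_ef(table, reg, products$product[i])
    total <- total + products$product_tonnes[i] * ef$mean
  }
  total
}

#' Transport emissions for a set of product consumptions
#'
#' Tonnes of each product, split over regions of origin by the sourcing mix,
#' multiplied by the (origin, destination, product) transport EF, summed.
#' Sourcing shares must sum to 1 per product (tolerance 1e-9).
#'
#' @param products As in [manufacturing_emissions()].
#' @param table Transport EF table ([read_transport_ef()]).
#' @param sourcing_mix Data.frame `region_to, region_from, share` (optional
#'   `product` column for product-specific sourcing).
#' @param region Named character vector mapping country to its region of
#'   consumption.
#' @return Total tCO2e at EF means.
#' @export
transport_emissions <- function(products, table, sourcing_mix, region) {
  if (nrow(products) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(products))) {
    dest <- region[[products$country[i]]]
    mix <- sourcing_shares(sourcing_mix, dest, products$product[i])
    for (k in seq_len(nrow(mix))) {
      ef <- lookup_transport_ef(table, mix$region_from[k], dest,
                                products$product[i])
      total <- total + products$product_tonnes[i] * mix$share[k] * ef$mean
    }
  }
  total
}

sourcing_shares <- function(sourcing_mix, region_to, product) {
  mix <- sourcing_mix[sourcing_mix$region_to == region_to, , drop = FALSE]
  if ("product" %in% names(mix)) {
    mix <- mix[mix$product == product, , drop = FALSE]
  }
  if (nrow(mix) == 0) {
    fert_stop("fertghg_config_error",
              "no sourcing shares for region '%s', product '%s'",
              region_to, product)
  }
  if (abs(sum(mix$share) - 1) > 1e-9) {
    fert_stop("fertghg_config_error",
              "sourcing shares for region '%s', product '%s' sum to %g, not 1",
              region_to, product, sum(mix$share))
  }
  mix
}

#' Direct soil N2O emissions from applied N
#'
#' `n2o_n = n_applied x ef`; CO2-equivalents via the stoichiometric 44/28
#' (t N2O-N to t N2O) and the N2O global warming potential.
#'
#' @param n_applied Tonnes of N applied (total national consumption,
#'   including any N not allocated to a product group).
#' @param ef Direct soil EF (dimensionless fraction).
#' @param gwp N2O GWP-100 factor (default 265).
#' @return List with `n2o_n` (t N2O-N) and `co2e` (tCO2e).
#' @export
#' @examples
#' direct_field_emissions(100, 0.01, 265)  # 1 t N2O-N, 416.43 tCO2e
direct_field_emissions <- function(n_applied, ef, gwp = 265) {
  if (any(n_applied < 0)) {
    fert_stop("fertghg_schema_error", "direct_field_emissions: n_applied < 0")
  }
  n2o_n <- n_applied * ef
  list(n2o_n = n2o_n, co2e = n2o_n * N2O_N_TO_N2O * gwp)
}

#' Indirect N2O emissions from volatilisation and redeposition
#'
#' The volatilised fraction of applied N (`vf`, the IPCC FRACGASF term)
#' re-deposits and a fraction `ef` of it (the IPCC EF4 term) is emitted as
#' N2O-N.
#'
#' @param n_applied Tonnes of N applied.
#' @param vf Fraction of applied N volatilised, in `[0, 1]`.
#' @param ef Fraction of volatilised N emitted as N2O-N, in `[0, 1]`.
#' @param gwp N2O GWP-100 factor.
#' @return List with `n2o_n` and `co2e`.
#' @export
indirect_volatilisation_emissions <- function(n_applied, vf, ef, gwp = 265) {
  stopifnot(all(vf >= 0 & vf <= 1), all(ef >= 0 & ef <= 1))
  n2o_n <- n_applied * vf * ef
  list(n2o_n = n2o_n, co2e = n2o_n * N2O_N_TO_N2O * gwp)
}

#' Indirect N2O emissions from leaching and runoff
#'
#' The leached fraction of applied N (`vf_leach`, the IPCC FRACLEACH term)
#' reaches water systems and a fraction `ef5` of it is emitted as N2O-N.
#' Dry-climate countries have a zero leaching fraction by default.
#'
#' @param n_applied Tonnes of N applied.
#' @param vf_leach Fraction of applied N leached, in `[0, 1]`.
#' @param ef5 Fraction of leached N emitted as N2O-N, in `[0, 1]`.
#' @param gwp N2O GWP-100 factor.
#' @return List with `n2o_n` and `co2e`.
#' @export
indirect_leaching_emissions <- function(n_applied, vf_leach, ef5, gwp = 265) {
  stopifnot(all(vf_leach >= 0 & vf_leach <= 1), all(ef5 >= 0 & ef5 <= 1))
  n2o_n <- n_applied * vf_leach * ef5
  list(n2o_n = n2o_n, co2e = n2o_n * N2O_N_TO_N2O * gwp)
}

#' CO2 released by urea hydrolysis in soil
#'
#' The CO2 captured during urea manufacture is released when the product
#' dissolves in soil: tonnes of urea-equivalent product times the urea EF
#' (tCO2-C per tonne product), converted to CO2 via 44/12.
#'
#' @param urea_product_tonnes Tonnes of urea-equivalent product applied.
#' @param ef_u Urea hydrolysis EF (default 0.2 tCO2-C/t).
#' @return List with `co2_c` (t CO2-C) and `co2` (t CO2).
#' @export
#' @examples
#' urea_field_emissions(100, 0.2)  # 20 t CO2-C, 73.33 t CO2
urea_field_emissions <- function(urea_product_tonnes, ef_u = 0.2) {
  if (any(urea_product_tonnes < 0)) {
    fert_stop("fertghg_schema_error", "urea_field_emissions: tonnage < 0")
  }
  co2_c <- urea_product_tonnes * ef_u
  list(co2_c = co2_c, co2 = co2_c * CO2_C_TO_CO2)
}

#' Assemble a country's emissions breakdown
#'
#' The national total is the exact sum of the six components:
#' manufacturing + transport + direct + volatilisation + leaching + urea.
#'
#' @param country Country code.
#' @param ghg_m,ghg_t,ghg_d,ghg_v,ghg_l,ghg_u Component emissions, tCO2e.
#' @param ... Optional intermediate columns (e.g. `n2o_n_direct`).
#' @return One-row data.frame with a `total` column.
#' @export
assemble_country <- function(country, ghg_m, ghg_t, ghg_d, ghg_v, ghg_l,
                             ghg_u, ...) {
  data.frame(country = country, ghg_m = ghg_m, ghg_t = ghg_t, ghg_d = ghg_d,
             ghg_v = ghg_v, ghg_l = ghg_l, ghg_u = ghg_u,
             total = ghg_m + ghg_t + ghg_d + ghg_v + ghg_l + ghg_u, ...,
             stringsAsFactors = FALSE)
}

#' Aggregate country breakdowns to regions or the globe
#'
#' Component-wise sums over countries. Regional then global aggregation
#' equals direct global summation (addition is associative), and the total
#' column remains the exact sum of the aggregated components.
#'
#' @param breakdown Data.frame of per-country breakdowns (must include a
#'   `region` column for `level = "region"`).
#' @param level `"region"` or `"global"`.
#' @return Aggregated data.frame with a `scope` column.
#' @export
aggregate_emissions <- function(breakdown, level = c("region", "global")) {
  level <- match.arg(level)
  if (anyDuplicated(breakdown$country)) {
    fert_stop("fertghg_schema_error", "duplicate country in breakdown: %s",
              paste(unique(breakdown$country[duplicated(breakdown$country)]),
                    collapse = ", "))
  }
  num_cols <- setdiff(names(breakdown)[vapply(breakdown, is.numeric, TRUE)],
                      character())
  if (level == "global") {
    out <- as.data.frame(as.list(colSums(breakdown[, num_cols, drop = FALSE])))
    out <- cbind(data.frame(scope = "global", stringsAsFactors = FALSE), out)
    return(out)
  }
  groups <- split(breakdown, breakdown$region)
  out <- do.call(rbind, lapply(names(groups), function(reg) {
    sums <- colSums(groups[[reg]][, num_cols, drop = FALSE])
    cbind(data.frame(scope = reg, stringsAsFactors = FALSE),
          as.data.frame(as.list(sums)))
  }))
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Linear inventory model: the whole Eqs. 2-9 chain expressed as coefficient
# structures over a vector of EF specs, shared by the deterministic and the
# Monte Carlo engines.

#' Build the inventory model for an activity table
#'
#' Collects every EF the accounting touches into one indexed spec table and
#' precomputes, per country, the coefficients that multiply each EF:
#' product tonnage for manufacturing, tonnage times sourcing share for
#' transport, total N (times 44/28 x GWP) for the field components, and
#' urea-equivalent tonnage for hydrolysis. Countries sharing an EF (e.g. all
#' countries of one production region, or wet-climate indirect factors)
#' reference the same spec index, which is what makes Monte Carlo draws
#' fully correlated across them.
#'
#' @param activity Validated activity table.
#' @param registry An `ef_registry` with manufacturing and transport tables.
#' @param scheme Direct-EF scheme name (see [get_direct_ef()]).
#' @param sourcing_mix Sourcing-share table; default 100% intra-regional.
#' @param region_of_production Named country-to-region map; default each
#'   country's own region.
#' @return An object of class `inventory_model`.
#' @export
build_inventory_model <- function(activity, registry, scheme,
                                  sourcing_mix = NULL,
                                  region_of_production = NULL) {
  activity <- validate_activity_table(activity)
  if (is.null(registry$manufacturing_ef) || is.null(registry$transport_ef)) {
    fert_stop("fertghg_config_error",
              "registry lacks manufacturing and/or transport EF tables")
  }
  nC <- nrow(activity)
  alloc <- allocate_products(activity)
  tonnes <- matrix(alloc$products$product_tonnes, nrow = nC,
                   dimnames = list(activity$country, fert_products()))

  if (is.null(sourcing_mix)) {
    sourcing_mix <- data.frame(region_to = unique(activity$region),
                               region_from = unique(activity$region),
                               share = 1, stringsAsFactors = FALSE)
  }

  specs <- list()
  spec_index <- function(spec) {
    if (!is.null(specs[[spec$name]])) return(match(spec$name, names(specs)))
    specs[[spec$name]] <<- spec
    length(specs)
  }

  m_entries <- list()  # (spec, country) -> coefficient triplets
  t_entries <- list()
  for (c_i in seq_len(nC)) {
    ctry <- activity$country[c_i]
    dest <- activity$region[c_i]
    prod_reg <- region_of_production[[ctry]] %||% dest
    for (j in fert_products()) {
      if (tonnes[c_i, j] <= 0) next
      row <- lookup_manufacturing_ef(registry$manufacturing_ef, prod_reg, j)
      s_i <- spec_index(ef_spec(paste("manuf", prod_reg, j, sep = "|"),
                                row$mean, row$sd,
                                if (is.na(row$min)) -Inf else row$min,
                                if (is.na(row$max)) Inf else row$max,
                                row$pdf, "table"))
      m_entries[[length(m_entries) + 1]] <- c(s_i, c_i, tonnes[c_i, j])
      mix <- sourcing_shares(sourcing_mix, dest, j)
      for (k in seq_len(nrow(mix))) {
        trow <- lookup_transport_ef(registry$transport_ef,
                                    mix$region_from[k], dest, j)
        ts_i <- spec_index(ef_spec(
          paste("trans", mix$region_from[k], dest, j, sep = "|"),
          trow$mean, trow$sd,
          if (is.na(trow$min)) -Inf else trow$min,
          if (is.na(trow$max)) Inf else trow$max, trow$pdf, "table"))
        t_entries[[length(t_entries) + 1]] <-
          c(ts_i, c_i, tonnes[c_i, j] * mix$share[k])
      }
    }
  }

  gwp <- registry$constants$gwp
  d_idx <- integer(nC); vf_idx <- integer(nC); ef4_idx <- integer(nC)
  fl_idx <- integer(nC); ef5_idx <- integer(nC)
  for (c_i in seq_len(nC)) {
    spec <- get_direct_ef(registry, scheme, country = activity$country[c_i],
                          region = activity$region[c_i],
                          climate = activity$climate[c_i])
    # a zero-sd country estimate (single plot) understates uncertainty:
    # substitute the regional sd when the registry carries empirical EFs
    if (spec$sd == 0 && scheme == "empirical_country" &&
        !is.null(registry$empirical) && !is.null(registry$empirical$region)) {
      reg_row <- registry$empirical$region[
        registry$empirical$region$scope == activity$region[c_i], , drop = FALSE]
      if (nrow(reg_row) == 1 && reg_row$sd > 0) {
        fert_log("WARN", "uncertainty_mc", "zero_sd_country_substituted",
                 country = activity$country[c_i], sd = reg_row$sd)
        spec <- ef_spec(spec$name, spec$mean, reg_row$sd, spec$min, spec$max,
                        spec$pdf, spec$provenance)
      }
    }
    d_idx[c_i] <- spec_index(spec)
    cl <- activity$climate[c_i]
    vf_idx[c_i] <- spec_index(registry$indirect[[cl]]$frac_gasf)
    ef4_idx[c_i] <- spec_index(registry$indirect[[cl]]$ef4)
    fl_idx[c_i] <- spec_index(registry$indirect[[cl]]$frac_leach)
    ef5_idx[c_i] <- spec_index(registry$indirect[[cl]]$ef5)
  }
  u_idx <- spec_index(registry$urea_ef)

  urea_eq <- urea_equivalent_tonnage(
    tonnes[, "urea"] * product_n_content()[["urea"]],
    tonnes[, "UAN"] * product_n_content()[["UAN"]],
    registry$constants$urea_n_content, registry$constants$uan_n_content,
    registry$constants$uan_urea_fraction)

  S <- length(specs)
  triplet_matrix <- function(entries) {
    m <- matrix(0, nrow = S, ncol = nC)
    for (e in entries) m[e[1], e[2]] <- m[e[1], e[2]] + e[3]
    m
  }

  structure(list(
    activity = activity,
    specs = specs,
    coef_m = triplet_matrix(m_entries),          # S x C, tonnes
    coef_t = triplet_matrix(t_entries),          # S x C, tonnes x share
    d_idx = d_idx, vf_idx = vf_idx, ef4_idx = ef4_idx,
    fl_idx = fl_idx, ef5_idx = ef5_idx, u_idx = u_idx,
    n_total = activity$n_consumption_t,          # incl. unallocated remainder
    urea_eq = unname(urea_eq),
    gwp = gwp
  ), class = "inventory_model")
}

#' @export
print.inventory_model <- function(x, ...) {
  cat(sprintf("<inventory_model> %d countries, %d EF specs\n",
              nrow(x$activity), length(x$specs)))
  invisible(x)
}

# Evaluate the model at a matrix of EF values (n_draws x n_specs). Returns
# per-component n_draws x n_countries matrices plus intermediates.
evaluate_model <- function(model, draws) {
  n <- nrow(draws)
  co2_fac <- N2O_N_TO_N2O * model$gwp
  col <- function(idx) draws[, idx, drop = FALSE]
  rep_row <- function(v) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

  n2o_d <- col(model$d_idx) * rep_row(model$n_total)
  n2o_v <- col(model$vf_idx) * col(model$ef4_idx) * rep_row(model$n_total)
  n2o_l <- col(model$fl_idx) * col(model$ef5_idx) * rep_row(model$n_total)
  co2_c_u <- col(rep(model$u_idx, length(model$urea_eq))) *
    rep_row(model$urea_eq)

  comps <- list(
    ghg_m = draws %*% model$coef_m,
    ghg_t = draws %*% model$coef_t,
    ghg_d = n2o_d * co2_fac,
    ghg_v = n2o_v * co2_fac,
    ghg_l = n2o_l * co2_fac,
    ghg_u = co2_c_u * CO2_C_TO_CO2
  )
  comps$total <- Reduce(`+`, comps)
  comps$n2o_n_direct <- n2o_d
  comps$n2o_n_volat <- n2o_v
  comps$n2o_n_leach <- n2o_l
  comps$co2_c_urea <- co2_c_u
  comps
}

spec_means <- function(model) {
  matrix(vapply(model$specs, function(s) s$mean, numeric(1)), nrow = 1)
}

#' Run the deterministic accounting for an activity table
#'
#' Evaluates the full emissions chain at the EF means and returns one row
#' per country: the six components (tCO2e), their exact-sum total, and the
#' N2O-N / CO2-C intermediates.
#'
#' @inheritParams build_inventory_model
#' @return Data.frame of class `emissions_breakdown` with columns `country,
#'   region, n_consumption_t, ghg_m, ghg_t, ghg_d, ghg_v, ghg_l, ghg_u,
#'   total, n2o_n_direct, n2o_n_volat, n2o_n_leach, co2_c_urea`.
#' @export
account_emissions <- function(activity, registry, scheme = "ipcc_tier1",
                              sourcing_mix = NULL,
                              region_of_production = NULL) {
  model <- build_inventory_model(activity, registry, scheme, sourcing_mix,
                                 region_of_production)
  comps <- evaluate_model(model, spec_means(model))
  out <- data.frame(
    country = model$activity$country,
    region = model$activity$region,
    n_consumption_t = model$activity$n_consumption_t,
    ghg_m = comps$ghg_m[1, ], ghg_t = comps$ghg_t[1, ],
    ghg_d = comps$ghg_d[1, ], ghg_v = comps$ghg_v[1, ],
    ghg_l = comps$ghg_l[1, ], ghg_u = comps$ghg_u[1, ],
    total = comps$total[1, ],
    n2o_n_direct = comps$n2o_n_direct[1, ],
    n2o_n_volat = comps$n2o_n_volat[1, ],
    n2o_n_leach = comps$n2o_n_leach[1, ],
    co2_c_urea = comps$co2_c_urea[1, ],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("emissions_breakdown", "data.frame")
  out
}

#' Format a breakdown as a reporting table in Mt CO2e
#'
#' Converts the per-country breakdown from tonnes to Mt, adds the share of
#' the global total, and rounds to one decimal for presentation.
#'
#' @param breakdown Output of [account_emissions()].
#' @param digits Decimals to round to (default 1); `NA` for no rounding.
#' @return Data.frame `country, n_consumption_mt, ghg_m, ghg_t, ghg_u,
#'   ghg_d, ghg_v, ghg_l, total, share_of_global` in Mt CO2e and percent.
#' @export
format_emissions_table <- function(breakdown, digits = 1) {
  mt <- function(x) x / 1e6
  out <- data.frame(
    country = breakdown$country,
    n_consumption_mt = mt(breakdown$n_consumption_t),
    ghg_m = mt(breakdown$ghg_m), ghg_t = mt(breakdown$ghg_t),
    ghg_u = mt(breakdown$ghg_u), ghg_d = mt(breakdown$ghg_d),
    ghg_v = mt(breakdown$ghg_v), ghg_l = mt(breakdown$ghg_l),
    total = mt(breakdown$total),
    share_of_global = 100 * breakdown$total / sum(breakdown$total),
    stringsAsFactors = FALSE
  )
  if (!is.na(digits)) {
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}
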