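# Country-level activity data: synthetic-N consumption, product-mix
# allocation over the eight product groups, nutrient-to-product conversion
# for urea/UAN, and wet/dry climate assignment.

activity_columns <- function() {
  c("country", "region", "year", "n_consumption_t", "climate",
    share_columns(), "population", "cropland_ha")
}

share_columns <- function() paste0("share_", tolower(fert_products()))

#' Read a country-level activity table
#'
#' Reads the activity CSV: one row per country with total synthetic-N
#' consumption (tonnes N), wet/dry climate class, the eight product-group
#' market-mix shares, and optional population and cropland. Shares are
#' fractions in `[0, 1]` summing to at most 1 per row; the uncovered
#' remainder (about 4% of N globally in the real data) is tracked separately
#' by [allocate_products()].
#'
#' @param path Path to a CSV with columns `country, region, year,
#'   n_consumption_t, climate, share_ammonia, share_an, share_as, share_can,
#'   share_urea, share_uan, share_ap, share_npk, population, cropland_ha`.
#' @return A validated data.frame.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) {
    fert_stop("fertghg_schema_error", "activity file not found: %s", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_activity_table(df)
}

#' Validate an activity table
#'
#' Checks the schema and invariants: non-negative consumption, shares in
#' `[0, 1]` with row sums at most 1 (tolerance 1e-9), known climate classes,
#' no duplicate countries.
#'
#' @param df Data.frame shaped like the activity CSV.
#' @return `df` invisibly reorganised (invariants checked), for chaining.
#' @export
validate_activity_table <- function(df) {
  assert_columns(df, activity_columns(), "activity table")
  if (anyDuplicated(df$country)) {
    fert_stop("fertghg_schema_error", "activity table: duplicate country rows: %s",
              paste(unique(df$country[duplicated(df$country)]), collapse = ", "))
  }
  if (any(!is.finite(df$n_consumption_t)) || any(df$n_consumption_t < 0)) {
    fert_stop("fertghg_schema_error",
              "activity table: n_consumption_t must be finite and >= 0")
  }
  sh <- as.matrix(df[, share_columns()])
  if (any(is.na(sh)) || any(sh < 0) || any(sh > 1)) {
    fert_stop("fertghg_schema_error",
              "activity table: product shares must all lie in [0, 1]")
  }
  if (any(rowSums(sh) > 1 + 1e-9)) {
    bad <- df$country[rowSums(sh) > 1 + 1e-9]
    fert_stop("fertghg_schema_error",
              "activity table: shares sum to > 1 for: %s",
              paste(bad, collapse = ", "))
  }
  if (any(!df$climate %in% c("wet", "dry"))) {
    fert_stop("fertghg_schema_error",
              "activity table: climate must be 'wet' or 'dry'")
  }
  df
}

#' Allocate national N consumption over product groups
#'
#' Splits each country's nitrogen consumption over the eight product groups
#' by its market-mix shares. The unallocated remainder (1 - sum of shares) is
#' returned per country: it is excluded from manufacturing and transport
#' accounting (no product information exists for it) but included in field
#' emission accounting, which uses total N. Allocation conserves nitrogen
#' exactly: per-product tonnes plus remainder equal consumption.
#'
#' @param activity Validated activity table.
#' @return List with `products` (data.frame `country, product, n_tonnes,
#'   product_tonnes`) and `remainder` (data.frame `country, n_tonnes`).
#'   `product_tonnes` converts nutrient to product mass via the product's N
#'   content.
#' @export
#' @examples
#' act <- data.frame(country = "X", region = "Europe", year = 2018,
#'   n_consumption_t = 100, climate = "wet",
#'   share_ammonia = 0, share_an = 0.3, share_as = 0, share_can = 0,
#'   share_urea = 0.5, share_uan = 0, share_ap = 0, share_npk = 0,
#'   population = NA, cropland_ha = NA)
#' allocate_products(act)$products
allocate_products <- function(activity) {
  activity <- validate_activity_table(activity)
  sh <- as.matrix(activity[, share_columns()])
  colnames(sh) <- fert_products()
  n_alloc <- sh * activity$n_consumption_t
  products <- data.frame(
    country = rep(activity$country, times = length(fert_products())),
    product = rep(fert_products(), each = nrow(activity)),
    n_tonnes = as.vector(n_alloc),
    stringsAsFactors = FALSE
  )
  products$product_tonnes <- products$n_tonnes /
    product_n_content()[products$product]
  remainder <- data.frame(
    country = activity$country,
    n_tonnes = activity$n_consumption_t - rowSums(n_alloc),
    stringsAsFactors = FALSE
  )
  list(products = products, remainder = remainder)
}

# Typical N mass fractions of the product groups, used to convert nutrient
# tonnes to product tonnes for manufacturing/transport EFs (which are per
# tonne of product). Urea and UAN values are the ones used in the
# urea-equivalent conversion.
product_n_content <- function() {
  c(ammonia = 0.82, AN = 0.335, AS = 0.21, CAN = 0.27,
    urea = 0.466, UAN = 0.30, AP = 0.11, NPK = 0.15)
}

#' Urea-equivalent product tonnage for hydrolysis accounting
#'
#' Converts urea and UAN nitrogen consumption (tonnes N) to the tonnes of
#' urea product that will hydrolyse in soil: urea N is divided by 0.466 (the
#' N content of urea) and UAN N is divided by 0.30 (the N content of UAN)
#' and multiplied by 0.35 (the average urea content of one unit of UAN).
#'
#' @param urea_n Tonnes of N consumed as urea.
#' @param uan_n Tonnes of N consumed as UAN solutions.
#' @param urea_n_content,uan_n_content,uan_urea_fraction Conversion
#'   constants; defaults 0.466, 0.30 and 0.35.
#' @return Tonnes of urea-equivalent product.
#' @export
#' @examples
#' urea_equivalent_tonnage(46.6, 0)  # 100 t product
#' urea_equivalent_tonnage(0, 30)    # 35 t urea-equivalent
urea_equivalent_tonnage <- function(urea_n, uan_n, urea_n_content = 0.466,
                                    uan_n_content = 0.30,
                                    uan_urea_fraction = 0.35) {
  if (any(urea_n < 0) || any(uan_n < 0)) {
    fert_stop("fertghg_schema_error",
              "urea_equivalent_tonnage: inputs must be >= 0")
  }
  urea_n / urea_n_content + uan_urea_fraction * (uan_n / uan_n_content)
}

#' Assign a predominant climate class to a country
#'
#' A country is "wet" or "dry" according to which climatic zone holds the
#' larger share of its cropland. Ties resolve to "wet" with a warning (the
#' conservative choice: wet-climate emission factors are higher).
#'
#' @param country Country code (used only for logging).
#' @param cropland_by_zone Named numeric vector with elements `wet` and
#'   `dry`, cropland area (ha) per zone; at least one must be > 0.
#' @return `"wet"` or `"dry"`.
#' @export
#' @examples
#' assign_climate("X", c(wet = 70, dry = 30))  # "wet"
#' assign_climate("Y", c(wet = 0, dry = 10))   # "dry"
assign_climate <- function(country, cropland_by_zone) {
  wet <- cropland_by_zone[["wet"]]
  dry <- cropland_by_zone[["dry"]]
  if (!is.finite(wet) || !is.finite(dry) || (wet <= 0 && dry <= 0)) {
    fert_stop("fertghg_schema_error",
              "assign_climate(%s): at least one zone needs cropland > 0", country)
  }
  if (wet == dry) {
    fert_log("WARN", "activity_data", "climate_tie", country = country,
             resolved = "wet")
    return("wet")
  }
  if (wet > dry) "wet" else "dry"
}
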