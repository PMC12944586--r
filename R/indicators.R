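#' Raw yearbook field schema
#'
#' Column names required by [compute_indicators()].
#' @export
RAW_STAT_FIELDS <- c(
  "unit_id", "year", "area_km2",
  "pop_total", "pop_urban", "pop_rural", "pop_employed",
  "gdp", "gdp_primary", "gdp_secondary", "gdp_tertiary",
  "grain_output_kg", "grain_sown_area_ha",
  "income_urban", "income_rural",
  "fiscal_revenue", "fiscal_expenditure",
  "retail_sales", "fixed_asset_investment"
)

#' Build socioeconomic driver indicators from raw yearbook fields
#'
#' Computes the per-capita / per-area driver indicators from raw city
#' statistics, so that regional comparisons are not dominated by city size:
#' \describe{
#'   \item{PD}{population density = total population / area (persons/km2)}
#'   \item{EPR}{employed population / total population}
#'   \item{PI}{fixed-asset investment / total population (per capita)}
#'   \item{FR}{fiscal expenditure / fiscal revenue}
#'   \item{GY}{grain output / sown grain area (kg/ha)}
#'   \item{PG}{GDP / total population (per capita)}
#'   \item{PC}{retail sales / total population (per capita)}
#'   \item{IS}{tertiary-industry GDP / secondary-industry GDP}
#'   \item{IOR}{GDP / fixed-asset investment}
#'   \item{IR}{urban disposable income per capita / rural net income per capita}
#' }
#' Records with a zero denominator for any indicator are excluded and
#' reported via the `excluded` attribute (unit, year, reason) and a message.
#'
#' @param records data.frame with the columns in [RAW_STAT_FIELDS].
#' @return data.frame of `unit_id`, `year` and the ten indicators, with
#'   attribute `excluded`.
#' @export
compute_indicators <- function(records) {
  missing <- setdiff(RAW_STAT_FIELDS, names(records))
  if (length(missing))
    stopf("schema error: missing raw fields: %s", paste(missing, collapse = ", "))
  num_fields <- setdiff(RAW_STAT_FIELDS, c("unit_id", "year"))
  for (f in num_fields) {
    if (any(records[[f]] < 0, na.rm = TRUE))
      stopf("invalid raw data: negative values in '%s'", f)
  }
  denoms <- list(
    pop_total = "total population", area_km2 = "city area",
    fiscal_revenue = "fiscal revenue", grain_sown_area_ha = "sown grain area",
    gdp_secondary = "secondary-industry GDP", income_rural = "rural net income",
    fixed_asset_investment = "fixed-asset investment"
  )
  bad <- rep(FALSE, nrow(records))
  reasons <- character(nrow(records))
  for (f in names(denoms)) {
    z <- !is.finite(records[[f]]) | records[[f]] == 0
    reasons[z & !bad] <- paste("zero or missing", denoms[[f]])
    bad <- bad | z
  }
  excluded <- data.frame(unit_id = records$unit_id[bad], year = records$year[bad],
                         reason = reasons[bad])
  if (nrow(excluded))
    message(sprintf("compute_indicators: excluded %d record(s) with zero denominators",
                    nrow(excluded)))
  r <- records[!bad, , drop = FALSE]
  out <- data.frame(
    unit_id = r$unit_id, year = r$year,
    PD = r$pop_total / r$area_km2,
    EPR = r$pop_employed / r$pop_total,
    PI = r$fixed_asset_investment / r$pop_total,
    FR = r$fiscal_expenditure / r$fiscal_revenue,
    GY = r$grain_output_kg / r$grain_sown_area_ha,
    PG = r$gdp / r$pop_total,
    PC = r$retail_sales / r$pop_total,
    IS = r$gdp_tertiary / r$gdp_secondary,
    IOR = r$gdp / r$fixed_asset_investment,
    IR = r$income_urban / r$income_rural
  )
  attr(out, "excluded") <- excluded
  out
}

#' Permanent-cropland mask
#'
#' A cell is permanent cropland iff it is classified cropland in every
#' baseline year (strict conjunction).
#'
#' @param lu a [landuse_series()].
#' @param baseline_years years defining permanence; all must be present in
#'   the series.
#' @return logical matrix, `TRUE` for permanent cropland.
#' @export
permanent_cropland_mask <- function(lu, baseline_years) {
  if (!inherits(lu, "landuse_series")) stopf("'lu' must be a landuse_series")
  miss <- setdiff(baseline_years, lu$years)
  if (length(miss))
    stopf("missing baseline year(s): %s", paste(miss, collapse = ", "))
  idx <- match(baseline_years, lu$years)
  crop <- lu$codes[["cropland"]]
  m <- lu$values[, , idx, drop = FALSE] == crop
  apply(m, c(1L, 2L), all)
}

#' Grain-for-Green conversion ratio per unit and year
#'
#' For each zone (administrative unit) and target year, the ratio of
#' permanent-cropland cells that have EVER been forest, shrubland or
#' grassland in any conversion-window year up to and including the target
#' year, to the zone's cropland base. The "ever converted" numerator makes
#' the ratio cumulative and nondecreasing in time; reversion to cropland
#' does not decrement it.
#'
#' @param lu a [landuse_series()].
#' @param zones integer matrix of unit ids, same shape as the land-use
#'   grids (cell-centre zonal assignment).
#' @param years target years (each must be >= the first window year).
#' @param baseline_years years defining permanent cropland.
#' @param window conversion-window years (default 2001:2020).
#' @param denominator cropland base per zone: `"baseline_union"` (cells
#'   cropland in ANY baseline year; default), `"permanent_only"`, or
#'   `"per_year"` (cropland in the target year).
#' @param mask optional precomputed permanent-cropland mask.
#' @return data.frame `unit_id`, `year`, `grgr` (NA where the zone has an
#'   empty denominator, with a message).
#' @export
compute_grgr <- function(lu, zones, years,
                         baseline_years = 1980:2000,
                         window = 2001:2020,
                         denominator = c("baseline_union", "permanent_only", "per_year"),
                         mask = NULL) {
  denominator <- match.arg(denominator)
  if (!inherits(lu, "landuse_series")) stopf("'lu' must be a landuse_series")
  d <- dim(lu$values)
  if (!identical(dim(zones), d[1:2]))
    stopf("zone grid shape %s != land-use grid shape %s",
          paste(dim(zones), collapse = "x"), paste(d[1:2], collapse = "x"))
  if (any(years < min(window)))
    stopf("target year(s) before the conversion window start (%d)", min(window))
  if (is.null(mask)) mask <- permanent_cropland_mask(lu, baseline_years)

  conv_codes <- lu$codes[c("forest", "shrubland", "grassland")]
  crop <- lu$codes[["cropland"]]
  win_years <- intersect(window, lu$years)

  bidx <- match(intersect(baseline_years, lu$years), lu$years)
  crop_union <- apply(lu$values[, , bidx, drop = FALSE] == crop, c(1L, 2L), any)

  zid <- sort(unique(as.vector(zones[!is.na(zones)])))
  out <- expand.grid(unit_id = zid, year = sort(unique(as.integer(years))))
  out$grgr <- NA_real_

  # cumulative "ever converted" state, advanced year by year through the window
  ever <- matrix(FALSE, d[1L], d[2L])
  state <- list()
  for (yr in sort(win_years)) {
    k <- match(yr, lu$years)
    ever <- ever | (matrix(lu$values[, , k] %in% conv_codes, d[1L], d[2L]) & mask)
    state[[as.character(yr)]] <- ever
  }
  n_empty <- 0L
  for (i in seq_len(nrow(out))) {
    yr <- out$year[i]
    usable <- win_years[win_years <= yr]
    ev <- if (length(usable)) state[[as.character(max(usable))]] else matrix(FALSE, d[1L], d[2L])
    zin <- !is.na(zones) & zones == out$unit_id[i]
    den <- switch(denominator,
                  baseline_union = sum(crop_union & zin),
                  permanent_only = sum(mask & zin),
                  per_year = {
                    k <- match(yr, lu$years)
                    if (is.na(k)) stopf("target year %d not in the land-use series", yr)
                    sum((lu$values[, , k] == crop) & zin)
                  })
    if (den == 0) { n_empty <- n_empty + 1L; next }
    out$grgr[i] <- sum(ev & zin) / den
  }
  if (n_empty)
    message(sprintf("compute_grgr: %d zone-year(s) with empty cropland base emitted as NA", n_empty))
  attr(out, "denominator") <- denominator
  out
}

#' Standardize panel variables
#'
#' Z-scores the requested variables across all unit-years and stores the
#' centring/scaling parameters so the transform is invertible with
#' [unstandardize_panel()].
#'
#' @param panel data.frame panel.
#' @param vars variables to standardize; defaults to all numeric columns
#'   except `unit_id`, `x`, `y`, `year`.
#' @return the panel with standardized columns and attribute
#'   `standardization` (data.frame of variable, center, scale).
#' @export
standardize_panel <- function(panel, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(panel)[vapply(panel, is.numeric, TRUE)],
                    c("unit_id", "x", "y", "year"))
  params <- data.frame(variable = vars, center = NA_real_, scale = NA_real_)
  for (i in seq_along(vars)) {
    v <- panel[[vars[i]]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stopf("standardization error: variable '%s' has zero variance", vars[i])
    m <- mean(v, na.rm = TRUE)
    panel[[vars[i]]] <- (v - m) / s
    params$center[i] <- m; params$scale[i] <- s
  }
  attr(panel, "standardization") <- params
  panel
}

#' Invert a panel standardization
#'
#' @param panel a panel returned by [standardize_panel()] (or any panel,
#'   with `params` supplied).
#' @param params optional standardization parameter table.
#' @return the panel on the original scale.
#' @export
unstandardize_panel <- function(panel, params = NULL) {
  if (is.null(params)) params <- attr(panel, "standardization")
  if (is.null(params)) stopf("no standardization parameters found")
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    panel[[v]] <- panel[[v]] * params$scale[i] + params$center[i]
  }
  attr(panel, "standardization") <- NULL
  panel
}
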