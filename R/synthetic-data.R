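#' Configuration for a synthetic space-time panel
#'
#' Defines the data-generating process for a city-level panel whose response
#' follows a locally linear model: at unit coordinates (u, v) and year t,
#' \deqn{y = \beta_0(u,v,t) + \sum_k \beta_k(u,v,t) x_k + \varepsilon,}
#' with every coefficient surface affine in space and time,
#' \eqn{\beta_k(u,v,t) = a_k + b_k u + c_k v + d_k (t - t_0)}. Affine
#' surfaces are smooth enough for a local regression to track while keeping
#' the ground truth in closed form.
#'
#' @param n_units number of spatial units (>= 5).
#' @param years integer vector of consecutive calendar years (>= 3).
#' @param domain named numeric `c(xmin, xmax, ymin, ymax)` in km.
#' @param intercept surface coefficients `c(a, b, c, d)` for \eqn{\beta_0}.
#' @param predictors named list; each element is a length-4 numeric
#'   `c(a, b, c, d)` giving that predictor's coefficient surface.
#' @param predictor_mean,predictor_sd mean and sd of the Gaussian predictor
#'   draws (recycled across predictors).
#' @param predictor_cor common pairwise correlation between predictors
#'   (default 0; positive values exercise the collinearity screen).
#' @param noise_sd standard deviation of the Gaussian error term, in
#'   response units (>= 0).
#' @param t0 time origin of the coefficient surfaces; defaults to the first
#'   year.
#' @return an object of class `panel_config`.
#' @seealso [generate_panel()]
#' @export
panel_config <- function(n_units = 50,
                         years = 1980:2019,
                         domain = c(xmin = 0, xmax = 1000, ymin = 0, ymax = 600),
                         intercept = c(a = 1, b = 5e-4, c = -5e-4, d = 0.01),
                         predictors = list(
                           x1 = c(a = 0.5,  b = 1e-3,  c = 0,     d = 0.01),
                           x2 = c(a = -0.3, b = 0,     c = 2e-3,  d = -0.005),
                           x3 = c(a = 0.2,  b = -1e-3, c = 1e-3,  d = 0)
                         ),
                         predictor_mean = 0,
                         predictor_sd = 1,
                         predictor_cor = 0,
                         noise_sd = 0.1,
                         t0 = NULL) {
  check_number(n_units, "n_units", lower = 5)
  if (length(years) < 3L) stopf("configuration error: 'years' must span at least 3 years")
  if (any(diff(years) <= 0)) stopf("configuration error: 'years' must be strictly increasing")
  if (length(domain) != 4L) stopf("configuration error: 'domain' must be c(xmin, xmax, ymin, ymax)")
  domain <- stats::setNames(as.numeric(domain), c("xmin", "xmax", "ymin", "ymax"))
  if (domain["xmax"] <= domain["xmin"] || domain["ymax"] <= domain["ymin"])
    stopf("configuration error: 'domain' extents must be positive")
  if (length(intercept) != 4L) stopf("configuration error: 'intercept' must have 4 surface coefficients")
  if (length(predictors) < 1L || is.null(names(predictors)) || any(names(predictors) == ""))
    stopf("configuration error: 'predictors' must be a named list")
  for (nm in names(predictors)) {
    if (length(predictors[[nm]]) != 4L || !is.numeric(predictors[[nm]]))
      stopf("configuration error: predictor '%s' must have 4 surface coefficients (a, b, c, d)", nm)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(predictor_cor, "predictor_cor", lower = -0.99, upper = 0.99)
  p <- length(predictors)
  predictor_mean <- rep_len(predictor_mean, p)
  predictor_sd <- rep_len(predictor_sd, p)
  if (any(predictor_sd <= 0)) stopf("configuration error: 'predictor_sd' must be positive")
  if (is.null(t0)) t0 <- years[1L]
  structure(list(
    n_units = as.integer(n_units), years = as.integer(years), domain = domain,
    intercept = stats::setNames(as.numeric(intercept), c("a", "b", "c", "d")),
    predictors = lapply(predictors, function(s) stats::setNames(as.numeric(s), c("a", "b", "c", "d"))),
    predictor_mean = predictor_mean, predictor_sd = predictor_sd,
    predictor_cor = predictor_cor, noise_sd = noise_sd, t0 = as.integer(t0)
  ), class = "panel_config")
}

# Evaluate an affine coefficient surface at (u, v, t).
surface_eval <- function(s, u, v, t, t0) {
  s[["a"]] + s[["b"]] * u + s[["c"]] * v + s[["d"]] * (t - t0)
}

#' Generate a synthetic panel with known coefficient surfaces
#'
#' Places `n_units` units on a jittered regular grid over the domain
#' (jitter sd = 5% of the grid spacing, so spatial neighbourhoods are
#' non-degenerate), draws predictors as (optionally equicorrelated)
#' Gaussians, evaluates the true coefficient surfaces at every unit-year,
#' and forms the response as systematic part plus Gaussian noise.
#'
#' @param config a [panel_config()].
#' @param seed integer seed; the panel substream is derived from it, so the
#'   same seed gives a bit-identical panel.
#' @return a list with elements
#'   \describe{
#'     \item{panel}{data.frame with `unit_id`, `x`, `y`, `year`, `response`
#'       and one column per predictor.}
#'     \item{truth}{data.frame aligned row-for-row with `panel`: true
#'       `beta0`, one `beta_<name>` per predictor, the systematic part
#'       `mu`, and the realized noise draw `eps`.}
#'     \item{config}{the config used.}
#'   }
#' @export
generate_panel <- function(config, seed = 1L) {
  if (!inherits(config, "panel_config")) stopf("'config' must be a panel_config")
  set.seed(derive_seed(seed, "panel"))
  n <- config$n_units
  years <- config$years
  ny <- length(years)
  p <- length(config$predictors)
  pnames <- names(config$predictors)

  # jittered grid of unit coordinates
  nx <- ceiling(sqrt(n * (config$domain["xmax"] - config$domain["xmin"]) /
                       (config$domain["ymax"] - config$domain["ymin"])))
  nx <- max(1L, as.integer(nx))
  nyg <- as.integer(ceiling(n / nx))
  dx <- (config$domain["xmax"] - config$domain["xmin"]) / nx
  dy <- (config$domain["ymax"] - config$domain["ymin"]) / nyg
  centers <- expand.grid(
    x = config$domain["xmin"] + (seq_len(nx) - 0.5) * dx,
    y = config$domain["ymin"] + (seq_len(nyg) - 0.5) * dy
  )[seq_len(n), ]
  ux <- centers$x + stats::rnorm(n, sd = 0.05 * dx)
  uy <- centers$y + stats::rnorm(n, sd = 0.05 * dy)

  unit_id <- rep(seq_len(n), each = ny)
  year <- rep(years, times = n)
  u <- ux[unit_id]
  v <- uy[unit_id]
  nrec <- n * ny

  # equicorrelated Gaussian predictors via Cholesky of the exchangeable matrix
  Z <- matrix(stats::rnorm(nrec * p), nrec, p)
  if (p > 1L && config$predictor_cor != 0) {
    R <- matrix(config$predictor_cor, p, p)
    diag(R) <- 1
    Z <- Z %*% chol(R)
  }
  X <- sweep(sweep(Z, 2L, config$predictor_sd, `*`), 2L, config$predictor_mean, `+`)
  colnames(X) <- pnames

  beta0 <- surface_eval(config$intercept, u, v, year, config$t0)
  B <- vapply(config$predictors,
              function(s) surface_eval(s, u, v, year, config$t0),
              numeric(nrec))
  mu <- beta0 + rowSums(B * X)
  eps <- if (config$noise_sd > 0) stats::rnorm(nrec, sd = config$noise_sd) else numeric(nrec)

  panel <- data.frame(unit_id = unit_id, x = u, y = v, year = year,
                      response = mu + eps, X, check.names = FALSE)
  truth <- data.frame(unit_id = unit_id, year = year, beta0 = beta0, B,
                      mu = mu, eps = eps, check.names = FALSE)
  names(truth)[3L + seq_len(p)] <- paste0("beta_", pnames)
  list(panel = panel, truth = truth, config = config)
}

#' Configuration for a synthetic trend raster
#'
#' Each cell is assigned one of four intended trend classes (significant or
#' non-significant, increasing or decreasing) and receives a linear signal
#' plus i.i.d. Gaussian noise. Slopes for the "significant" classes default
#' to magnitudes detectable at alpha = 0.05 with high probability given the
#' noise level and series length; "non-significant" classes get slopes small
#' relative to the slope standard error.
#'
#' @param nrow,ncol grid shape.
#' @param years integer years (one raster band per year).
#' @param fraction_increasing proportion of cells with a positive intended
#'   slope, in \[0, 1\].
#' @param fraction_sig_increasing proportion with a strong (detectable)
#'   positive slope; must not exceed `fraction_increasing`.
#' @param fraction_sig_decreasing proportion with a strong negative slope;
#'   must not exceed `1 - fraction_increasing`.
#' @param slopes named numeric `c(sig_inc, nonsig_inc, nonsig_dec, sig_dec)`
#'   slope magnitudes per intended class (signs applied internally).
#' @param baseline mean level of the field at the first year.
#' @param noise_sd standard deviation of per-cell-per-year noise.
#' @return object of class `raster_config`.
#' @export
raster_config <- function(nrow = 100, ncol = 100, years = 1980:2000,
                          fraction_increasing = 0.57,
                          fraction_sig_increasing = 0.11,
                          fraction_sig_decreasing = 0.02,
                          slopes = c(sig_inc = 0.02, nonsig_inc = 0.004,
                                     nonsig_dec = 0.004, sig_dec = 0.02),
                          baseline = 2, noise_sd = 0.1) {
  check_number(nrow, "nrow", lower = 1)
  check_number(ncol, "ncol", lower = 1)
  if (length(years) < 3L) stopf("configuration error: 'years' must span at least 3 years")
  check_number(fraction_increasing, "fraction_increasing", 0, 1)
  check_number(fraction_sig_increasing, "fraction_sig_increasing", 0, 1)
  check_number(fraction_sig_decreasing, "fraction_sig_decreasing", 0, 1)
  if (fraction_sig_increasing > fraction_increasing)
    stopf("configuration error: 'fraction_sig_increasing' must not exceed 'fraction_increasing'")
  if (fraction_sig_decreasing > 1 - fraction_increasing)
    stopf("configuration error: 'fraction_sig_decreasing' must not exceed 1 - 'fraction_increasing'")
  if (length(slopes) != 4L)
    stopf("configuration error: 'slopes' must name sig_inc, nonsig_inc, nonsig_dec, sig_dec")
  slopes <- stats::setNames(abs(as.numeric(slopes)),
                            c("sig_inc", "nonsig_inc", "nonsig_dec", "sig_dec"))
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 years = as.integer(years),
                 fraction_increasing = fraction_increasing,
                 fraction_sig_increasing = fraction_sig_increasing,
                 fraction_sig_decreasing = fraction_sig_decreasing,
                 slopes = slopes, baseline = baseline, noise_sd = noise_sd),
            class = "raster_config")
}

#' Raster time-series container
#'
#' A minimal year-indexed grid stack: a 3-D numeric array (rows x cols x
#' years) with a `years` vector. `NA` cells are treated as nodata.
#'
#' @param values 3-D array, third dimension indexed by year.
#' @param years integer years, one per band.
#' @return object of class `raster_series`.
#' @export
raster_series <- function(values, years) {
  if (length(dim(values)) != 3L) stopf("'values' must be a 3-D array")
  if (dim(values)[3L] != length(years))
    stopf("band count (%d) != year list length (%d)", dim(values)[3L], length(years))
  structure(list(values = values, years = as.integer(years)), class = "raster_series")
}

#' @export
print.raster_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_series> %d x %d cells, %d years (%d-%d)\n",
              d[1L], d[2L], d[3L], min(x$years), max(x$years)))
  invisible(x)
}

#' Generate a trend raster with a declared label grid
#'
#' @param config a [raster_config()].
#' @param seed integer seed (raster substream derived from it).
#' @return a [raster_series()] with an extra element `labels`: a character
#'   matrix recording each cell's intended class
#'   (`"sig_inc"`, `"nonsig_inc"`, `"nonsig_dec"`, `"sig_dec"`).
#' @export
generate_trend_raster <- function(config, seed = 1L) {
  if (!inherits(config, "raster_config")) stopf("'config' must be a raster_config")
  set.seed(derive_seed(seed, "raster"))
  ncell <- config$nrow * config$ncol
  n_sig_inc <- round(config$fraction_sig_increasing * ncell)
  n_inc <- round(config$fraction_increasing * ncell)
  n_nonsig_inc <- max(0L, n_inc - n_sig_inc)
  n_sig_dec <- round(config$fraction_sig_decreasing * ncell)
  n_nonsig_dec <- ncell - n_sig_inc - n_nonsig_inc - n_sig_dec
  lab <- sample(rep(c("sig_inc", "nonsig_inc", "nonsig_dec", "sig_dec"),
                    times = c(n_sig_inc, n_nonsig_inc, n_nonsig_dec, n_sig_dec)))
  slope_sign <- ifelse(lab %in% c("sig_inc", "nonsig_inc"), 1, -1)
  slope <- slope_sign * config$slopes[lab]
  ny <- length(config$years)
  tt <- config$years - config$years[1L]
  vals <- config$baseline + outer(slope, tt) +
    matrix(stats::rnorm(ncell * ny, sd = config$noise_sd), ncell, ny)
  rs <- raster_series(array(vals, dim = c(config$nrow, config$ncol, ny)), config$years)
  rs$labels <- matrix(lab, config$nrow, config$ncol)
  rs$true_slope <- matrix(slope, config$nrow, config$ncol)
  rs
}

#' Configuration for a synthetic land-use class series
#'
#' Emulates a Grain-for-Green-style conversion process: a baseline period in
#' which a configured fraction of cells is cropland (a small "churn"
#' fraction of cropland cells flips class during the baseline so that the
#' permanent-cropland conjunction is non-trivial), followed by a conversion
#' window in which a nondecreasing schedule of fractions of the permanent
#' cropland is converted to forest, shrubland or grassland. Converted cells
#' never revert.
#'
#' @param nrow,ncol grid shape.
#' @param years integer years covering baseline and conversion window.
#' @param codes named integer class codes; names must include `cropland`,
#'   `forest`, `shrubland`, `grassland`, `other`.
#' @param cropland_fraction baseline fraction of cells that are cropland.
#' @param churn_fraction fraction of baseline cropland cells that flip to
#'   grassland in at least one baseline year (and are therefore not
#'   "permanent" cropland).
#' @param baseline_years years defining permanence (default 1980:2000).
#' @param conversion_schedule named numeric vector, names are years, values
#'   are cumulative fractions of permanent cropland converted by that year;
#'   must be nondecreasing in year, all in \[0, 1\]. May be empty (no
#'   conversion).
#' @return object of class `landuse_config`.
#' @export
landuse_config <- function(nrow = 40, ncol = 40, years = 1980:2020,
                           codes = c(cropland = 1L, forest = 2L, shrubland = 3L,
                                     grassland = 4L, other = 5L),
                           cropland_fraction = 0.4,
                           churn_fraction = 0.05,
                           baseline_years = 1980:2000,
                           conversion_schedule = c("2005" = 0.018, "2010" = 0.182,
                                                   "2015" = 0.185, "2020" = 0.2)) {
  check_number(nrow, "nrow", lower = 1)
  check_number(ncol, "ncol", lower = 1)
  req <- c("cropland", "forest", "shrubland", "grassland", "other")
  if (!all(req %in% names(codes)))
    stopf("configuration error: 'codes' must name %s", paste(req, collapse = ", "))
  check_number(cropland_fraction, "cropland_fraction", 0, 1)
  check_number(churn_fraction, "churn_fraction", 0, 1)
  if (length(conversion_schedule)) {
    sy <- as.integer(names(conversion_schedule))
    if (anyNA(sy)) stopf("configuration error: schedule names must be years")
    o <- order(sy)
    sy <- sy[o]; sv <- as.numeric(conversion_schedule[o])
    if (any(sv < 0 | sv > 1)) stopf("configuration error: schedule fractions must lie in [0, 1]")
    if (is.unsorted(sv)) stopf("configuration error: conversion schedule must be nondecreasing in year")
    conversion_schedule <- stats::setNames(sv, sy)
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 years = as.integer(years), codes = vapply(codes, as.integer, 0L),
                 cropland_fraction = cropland_fraction,
                 churn_fraction = churn_fraction,
                 baseline_years = as.integer(baseline_years),
                 conversion_schedule = conversion_schedule),
            class = "landuse_config")
}

#' Land-use class series container
#'
#' @param values 3-D integer array (rows x cols x years) of class codes.
#' @param years integer years.
#' @param codes named integer class-code table.
#' @return object of class `landuse_series`.
#' @export
landuse_series <- function(values, years, codes) {
  if (length(dim(values)) != 3L) stopf("'values' must be a 3-D array")
  if (dim(values)[3L] != length(years))
    stopf("band count (%d) != year list length (%d)", dim(values)[3L], length(years))
  if (!all(values[!is.na(values)] %in% codes))
    stopf("grid contains codes absent from the code table")
  structure(list(values = values, years = as.integer(years), codes = codes),
            class = "landuse_series")
}

#' @export
print.landuse_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<landuse_series> %d x %d cells, %d years (%d-%d); classes: %s\n",
              d[1L], d[2L], d[3L], min(x$years), max(x$years),
              paste(names(x$codes), collapse = ", ")))
  invisible(x)
}

#' Generate a land-use series with scheduled cropland conversion
#'
#' @param config a [landuse_config()].
#' @param seed integer seed (land-use substream derived from it).
#' @return a [landuse_series()] with extra elements `permanent` (logical
#'   matrix of cells cropland in every baseline year) and `conversion_year`
#'   (integer matrix, NA where never converted).
#' @export
generate_landuse_series <- function(config, seed = 1L) {
  if (!inherits(config, "landuse_config")) stopf("'config' must be a landuse_config")
  set.seed(derive_seed(seed, "landuse"))
  nrow <- config$nrow; ncol <- config$ncol
  ncell <- nrow * ncol
  codes <- config$codes
  years <- config$years
  ny <- length(years)

  n_crop <- round(config$cropland_fraction * ncell)
  cells <- sample.int(ncell)
  crop_cells <- cells[seq_len(n_crop)]
  other_cells <- setdiff(cells, crop_cells)
  base <- integer(ncell)
  base[crop_cells] <- codes[["cropland"]]
  if (length(other_cells))
    base[other_cells] <- sample(codes[c("forest", "shrubland", "grassland", "other")],
                                length(other_cells), replace = TRUE)

  # churn cells flip cropland -> grassland in a random interior baseline year
  n_churn <- round(config$churn_fraction * n_crop)
  churn_cells <- if (n_churn > 0L) crop_cells[seq_len(n_churn)] else integer(0)
  base_years_present <- intersect(config$baseline_years, years)
  churn_year <- if (n_churn > 0L && length(base_years_present) > 2L)
    sample(base_years_present[-c(1L, length(base_years_present))], n_churn, replace = TRUE)
  else rep(NA_integer_, n_churn)

  permanent_cells <- setdiff(crop_cells, churn_cells[!is.na(churn_year)])
  n_perm <- length(permanent_cells)

  # cumulative conversion ordering: the first k permanent cells convert first
  conv_order <- sample(permanent_cells)
  sched <- config$conversion_schedule
  conv_year_of <- rep(NA_integer_, ncell)
  target_of <- rep(NA_integer_, ncell)
  if (length(sched) && n_perm > 0L) {
    prev_n <- 0L
    for (j in seq_along(sched)) {
      n_by <- round(sched[[j]] * n_perm)
      if (n_by > prev_n) {
        newly <- conv_order[(prev_n + 1L):n_by]
        conv_year_of[newly] <- as.integer(names(sched)[j])
        target_of[newly] <- sample(codes[c("forest", "shrubland", "grassland")],
                                   length(newly), replace = TRUE)
        prev_n <- n_by
      }
    }
  }

  vals <- array(NA_integer_, dim = c(nrow, ncol, ny))
  for (k in seq_len(ny)) {
    yr <- years[k]
    g <- base
    if (n_churn > 0L) {
      flip <- churn_cells[!is.na(churn_year) & churn_year == yr]
      g[flip] <- codes[["grassland"]]
    }
    conv <- which(!is.na(conv_year_of) & conv_year_of <= yr)
    g[conv] <- target_of[conv]
    vals[, , k] <- g
  }
  lu <- landuse_series(vals, years, codes)
  perm <- matrix(FALSE, nrow, ncol)
  perm[permanent_cells] <- TRUE
  lu$permanent <- perm
  lu$conversion_year <- matrix(conv_year_of, nrow, ncol)
  lu
}
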