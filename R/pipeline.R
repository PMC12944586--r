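#' Read a panel CSV
#'
#' Required columns: `unit_id`, `x`, `y`, `year`, the response, and at
#' least one predictor. Rows with a missing response are dropped with a
#' logged count; rows where any required field fails to parse are dropped
#' likewise.
#'
#' @param path CSV path.
#' @param response response column name (default `"response"`).
#' @return panel data.frame with attribute `n_dropped`.
#' @export
read_panel <- function(path, response = "response") {
  panel <- tryCatch(utils::read.csv(path, check.names = FALSE),
                    error = function(e) stopf("schema error: cannot read '%s': %s",
                                              path, conditionMessage(e)))
  req <- c("unit_id", "x", "y", "year", response)
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stopf("schema error: missing required column(s): %s", paste(miss, collapse = ", "))
  for (col in c("x", "y", "year", response))
    panel[[col]] <- suppressWarnings(as.numeric(panel[[col]]))
  bad <- !is.finite(panel[[response]]) | !is.finite(panel$x) |
    !is.finite(panel$y) | !is.finite(panel$year)
  if (any(bad)) message(sprintf("read_panel: dropped %d malformed/missing row(s)", sum(bad)))
  panel <- panel[!bad, , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "n_dropped") <- sum(bad)
  panel
}

#' Write a panel CSV
#'
#' @param panel panel data.frame.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Write a raster series as long-format CSV
#'
#' Plain-text serialization of the year-indexed grid stack: columns `row`,
#' `col`, `year`, `value`. NA (nodata) cells are written as empty fields.
#'
#' @param rs a [raster_series()] or [landuse_series()].
#' @param path output CSV path. For a land-use series, the class-code table
#'   is written to a JSON sidecar at `paste0(path, ".codes.json")`.
#' @export
write_raster_series <- function(rs, path) {
  d <- dim(rs$values)
  df <- data.frame(
    row = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    col = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    year = rep(rs$years, each = d[1L] * d[2L]),
    value = as.vector(rs$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (inherits(rs, "landuse_series"))
    jsonlite::write_json(as.list(rs$codes), paste0(path, ".codes.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raster series from long-format CSV
#'
#' @param path CSV written by [write_raster_series()].
#' @param landuse if `TRUE`, read the JSON code-table sidecar and return a
#'   [landuse_series()].
#' @return a [raster_series()] or [landuse_series()].
#' @export
read_raster_series <- function(path, landuse = FALSE) {
  df <- utils::read.csv(path)
  req <- c("row", "col", "year", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("schema error: missing column(s): %s", paste(miss, collapse = ", "))
  years <- sort(unique(df$year))
  nr <- max(df$row); nc <- max(df$col)
  arr <- array(NA_real_, dim = c(nr, nc, length(years)))
  idx <- cbind(df$row, df$col, match(df$year, years))
  arr[idx] <- df$value
  if (landuse) {
    codes_path <- paste0(path, ".codes.json")
    if (!file.exists(codes_path)) stopf("missing code-table sidecar '%s'", codes_path)
    codes <- unlist(jsonlite::read_json(codes_path))
    storage.mode(arr) <- "integer"
    landuse_series(arr, years, vapply(codes, as.integer, 0L))
  } else {
    raster_series(arr, years)
  }
}

#' Partition a grid into a zone-id grid for n units
#'
#' Splits the grid into roughly equal rectangular blocks, one per unit, for
#' zonal statistics on synthetic land-use stacks (cell-centre assignment is
#' implicit: every cell belongs to exactly one block).
#'
#' @param nrow,ncol grid shape.
#' @param n_units number of zones.
#' @return integer matrix of unit ids in 1..n_units.
#' @export
make_zone_grid <- function(nrow, ncol, n_units) {
  kr <- max(1L, as.integer(floor(sqrt(n_units))))
  kc <- as.integer(ceiling(n_units / kr))
  rb <- pmin(ceiling(seq_len(nrow) / (nrow / kr)), kr)
  cb <- pmin(ceiling(seq_len(ncol) / (ncol / kc)), kc)
  z <- outer(rb, cb, function(r, c) (r - 1L) * kc + c)
  z[z > n_units] <- n_units
  storage.mode(z) <- "integer"
  z
}

#' Default pipeline configuration
#'
#' A complete, self-contained configuration for a synthetic end-to-end run:
#' generator settings for the panel, trend raster, and land-use stack, plus
#' all stage parameters. Any element can be overridden via `...` (nested
#' lists are replaced wholesale).
#'
#' @param seed global seed feeding every stage's substream.
#' @param ... named overrides of the defaults.
#' @return a nested list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = list(trends = TRUE, landuse = TRUE, gtwr = TRUE, geodetector = TRUE),
    panel = list(n_units = 50, years = 1980:2019, noise_sd = 0.1),
    raster = list(nrow = 60, ncol = 60, years = 1980:2000,
                  fraction_increasing = 0.57, fraction_sig_increasing = 0.11),
    landuse = list(nrow = 40, ncol = 40, years = 1980:2020),
    alpha = 0.05,
    split_year = 2000,
    vif_threshold = 7.5,
    gtwr = list(kernel = "gaussian", tau = 1, bandwidth = NULL),
    geodetector = list(L = 5, method = "quantile", B = 199,
                       years = c(1980, 1990, 2000, 2010, 2019))
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Run the full attribution pipeline on synthetic inputs
#'
#' Executes, in order: synthetic generation (panel, trend raster, land-use
#' stack) -> per-cell trend analysis with area fractions and basin-mean
#' segment rates -> permanent cropland and Grain-for-Green ratio ->
#' standardization -> VIF screen -> GTWR with coefficient summaries and
#' dominant factors -> factor-detector q table with dimension averages.
#' All tabular outputs are written as CSV under `out_dir`, and a JSON
#' manifest (parameters, seed, package version, md5 checksum per output)
#' makes the run reproducible: identical config + seed gives identical
#' outputs byte for byte.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file holding
#'   one).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    class(cfg) <- "run_config"
    config <- cfg
  }
  if (!inherits(config, "run_config")) stopf("'config' must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character(0)
  results <- list()
  status <- list()
  wout <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  run_stage <- function(name, expr) {
    r <- tryCatch(list(ok = TRUE, value = force(expr)),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    status[[name]] <<- if (r$ok) "completed" else paste("failed:", r$error)
    if (!r$ok) message(sprintf("stage '%s' failed: %s", name, r$error))
    r
  }

  # synthetic inputs
  pcfg <- do.call(panel_config, config$panel)
  gen <- generate_panel(pcfg, seed = seed)
  panel <- gen$panel
  predictors <- names(pcfg$predictors)
  wout(panel, "panel.csv")
  wout(gen$truth, "panel_truth.csv")
  status$synthetic <- "completed"

  if (isTRUE(config$stages$trends)) {
    r <- run_stage("trends", {
      rcfg <- do.call(raster_config, config$raster)
      rs <- generate_trend_raster(rcfg, seed = seed)
      tr <- trend_raster(rs, alpha = config$alpha)
      fr <- area_fractions(tr$class)
      # basin-mean series and its segment rates around the split year
      d <- dim(rs$values)
      basin_mean <- apply(matrix(rs$values, d[1L] * d[2L], d[3L]), 2L, mean)
      seg <- segment_rates(rs$years, basin_mean, config$split_year)
      wout(data.frame(class = names(fr), fraction = as.numeric(fr)),
           "trend_fractions.csv")
      wout(data.frame(segment = c("before", "after"),
                      slope = c(seg$before$slope, seg$after$slope),
                      p_value = c(seg$before$p_value, seg$after$p_value)),
           "trend_segments.csv")
      list(fractions = fr, segments = seg, trend = tr)
    })
    if (r$ok) results$trends <- r$value
  }

  if (isTRUE(config$stages$landuse)) {
    r <- run_stage("landuse", {
      lcfg <- do.call(landuse_config, config$landuse)
      lu <- generate_landuse_series(lcfg, seed = seed)
      zones <- make_zone_grid(lcfg$nrow, lcfg$ncol, pcfg$n_units)
      win <- intersect(2001:2020, lu$years)
      grgr <- compute_grgr(lu, zones, years = win,
                           baseline_years = intersect(1980:2000, lu$years),
                           window = win)
      wout(grgr, "grgr.csv")
      list(lu = lu, zones = zones, grgr = grgr)
    })
    if (r$ok) results$landuse <- r$value
  }

  screened <- predictors
  if (isTRUE(config$stages$gtwr)) {
    r <- run_stage("gtwr", {
      std <- standardize_panel(panel, vars = c("response", predictors))
      scr <- vif_screen(std, predictors, threshold = config$vif_threshold)
      screened <- scr$retained
      wout(scr$report, "vif_report.csv")
      gcfg <- do.call(gtwr_config, config$gtwr)
      fit <- fit_gtwr(std, "response", screened, gcfg)
      wout(fit$coefficients, "gtwr_coefficients.csv")
      wout(coefficient_summary(fit, "year"), "coef_by_year.csv")
      wout(coefficient_summary(fit, "unit"), "coef_by_unit.csv")
      dom <- dominant_factors(fit)
      wout(dom, "dominant_factors.csv")
      list(screen = scr, fit = fit, dominant = dom)
    })
    if (r$ok) results$gtwr <- r$value
  }

  if (isTRUE(config$stages$geodetector)) {
    r <- run_stage("geodetector", {
      gd <- config$geodetector
      qt <- factor_detector(panel, "response", predictors,
                            years = intersect(gd$years, panel$year),
                            L = gd$L, method = gd$method, B = gd$B,
                            seed = seed)
      wout(as.data.frame(qt), "q_table.csv")
      dims <- dimension_map()
      if (!all(unique(qt$factor) %in% names(dims)))
        dims <- stats::setNames(rep("all", length(predictors)), predictors)
      davg <- dimension_average_q(qt, dims)
      wout(davg, "dimension_average_q.csv")
      list(q_table = qt, dim_avg = davg)
    })
    if (r$ok) results$geodetector <- r$value
  }

  manifest <- list(
    package = "vegdrivers",
    version = as.character(utils::packageVersion("vegdrivers")),
    seed = seed,
    config = unclass(config),
    stages = status,
    outputs = as.list(stats::setNames(unname(tools::md5sum(sort(outputs))),
                                      basename(sort(outputs))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$results <- results
  invisible(manifest)
}
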