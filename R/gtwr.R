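#' GTWR configuration
#'
#' Settings for the geographically and temporally weighted regression. The
#' spatiotemporal distance between records i and j is
#' \deqn{d_{ij}^2 = \lambda[(u_i-u_j)^2 + (v_i-v_j)^2] + \mu (t_i-t_j)^2,}
#' with the spatial scale fixed at \eqn{\lambda = 1} and the space-time
#' trade-off carried entirely by \eqn{\tau = \mu/\lambda} (km^2/year^2).
#' `tau = 0` reduces the model to a purely spatial GWR.
#'
#' @param kernel `"gaussian"` (default) or `"bisquare"`.
#' @param tau space-time equivalence factor \eqn{\mu/\lambda} (>= 0),
#'   km^2/year^2.
#' @param tau_grid optional candidates for selecting `tau` on the same
#'   criterion as the bandwidth (outer grid).
#' @param bandwidth kernel bandwidth in spatiotemporal distance units
#'   (fixed kernel), or the neighbour count when `adaptive = TRUE`; `NULL`
#'   selects it from `bandwidth_grid`.
#' @param bandwidth_grid candidate bandwidths; `NULL` uses a geometric grid
#'   of 10 values from 0.05 to 2 times the data diameter.
#' @param adaptive if `TRUE`, `bandwidth` is a k-nearest-neighbour count
#'   and each focal point uses the distance to its k-th neighbour as its
#'   local bandwidth.
#' @param criterion bandwidth-selection criterion, `"loocv"` (default) or
#'   `"aicc"`.
#' @param ridge_eps relative diagonal regularization applied when a local
#'   weighted cross-product matrix is numerically singular.
#' @param min_effective_weight lower bound on the total non-self weight at
#'   a focal point for its leave-one-out prediction to count.
#' @param coords `"planar"` (km; default) or `"lonlat"` (converted to
#'   planar km by an equirectangular projection about the domain centroid).
#' @return object of class `gtwr_config`.
#' @export
gtwr_config <- function(kernel = c("gaussian", "bisquare"),
                        tau = 1, tau_grid = NULL,
                        bandwidth = NULL, bandwidth_grid = NULL,
                        adaptive = FALSE,
                        criterion = c("loocv", "aicc"),
                        ridge_eps = 1e-8,
                        min_effective_weight = 1e-10,
                        coords = c("planar", "lonlat")) {
  kernel <- match.arg(kernel)
  criterion <- match.arg(criterion)
  coords <- match.arg(coords)
  check_number(tau, "tau", lower = 0)
  if (!is.null(bandwidth)) check_number(bandwidth, "bandwidth", lower = .Machine$double.xmin)
  check_number(ridge_eps, "ridge_eps", lower = 0)
  check_flag(adaptive, "adaptive")
  if (!is.null(tau_grid) && any(tau_grid < 0)) stopf("configuration error: 'tau_grid' must be >= 0")
  structure(list(kernel = kernel, tau = tau, tau_grid = tau_grid,
                 bandwidth = bandwidth, bandwidth_grid = bandwidth_grid,
                 adaptive = adaptive, criterion = criterion,
                 ridge_eps = ridge_eps,
                 min_effective_weight = min_effective_weight,
                 coords = coords),
            class = "gtwr_config")
}

#' Spatiotemporal distance between two points
#'
#' @param a,b numeric `c(u, v, t)`.
#' @param tau space-time equivalence factor (>= 0).
#' @param lambda spatial scale (fixed at 1 by convention).
#' @return nonnegative scalar distance.
#' @examples
#' st_distance(c(0, 0, 2000), c(3, 4, 2000))          # 5
#' st_distance(c(0, 0, 2000), c(0, 0, 2002), tau = 4) # 4
#' @export
st_distance <- function(a, b, tau = 1, lambda = 1) {
  check_number(tau, "tau", lower = 0)
  sqrt(lambda * ((a[1L] - b[1L])^2 + (a[2L] - b[2L])^2) + tau * (a[3L] - b[3L])^2)
}

# Full pairwise spatiotemporal distance matrix.
st_distance_matrix <- function(u, v, t, tau = 1, lambda = 1) {
  du2 <- outer(u, u, `-`)^2 + outer(v, v, `-`)^2
  dt2 <- outer(t, t, `-`)^2
  sqrt(lambda * du2 + tau * dt2)
}

#' Kernel weight as a function of distance
#'
#' Gaussian: `exp(-d^2 / b^2)`; bisquare: `(1 - (d/b)^2)^2` for `d < b`,
#' else 0. Both equal 1 at distance zero and are nonincreasing in distance.
#'
#' @param d nonnegative distances (vectorized).
#' @param bandwidth positive kernel scale.
#' @param kernel `"gaussian"` or `"bisquare"`.
#' @return weights in \[0, 1\].
#' @export
kernel_weight <- function(d, bandwidth, kernel = c("gaussian", "bisquare")) {
  kernel <- match.arg(kernel)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stopf("bandwidth must be a positive scalar")
  if (any(d < 0)) stopf("distances must be nonnegative")
  if (kernel == "gaussian") {
    exp(-(d / bandwidth)^2)
  } else {
    w <- (1 - (d / bandwidth)^2)^2
    w[d >= bandwidth] <- 0
    w
  }
}

#' Weighted least squares at one focal point
#'
#' Solves the weighted normal equations `(X'WX) beta = X'Wy`. If the
#' cross-product matrix is singular within tolerance, retries once with a
#' trace-scaled ridge (`ridge_eps * mean(diag)` added to the diagonal) and
#' flags the fit; if still unsolvable, returns missing coefficients.
#'
#' @param X design matrix including the intercept column.
#' @param y response vector.
#' @param w nonnegative weights (sum > 0).
#' @param ridge_eps relative ridge used on fallback.
#' @return list `coef` (NA vector if unsolvable), `flagged` (logical),
#'   `XtWXi` (inverse of the possibly-ridged cross-product, or NULL).
#' @export
fit_local_wls <- function(X, y, w, ridge_eps = 1e-8) {
  if (sum(w) <= 0) stopf("fit error: all weights are zero")
  Xw <- X * w
  A <- crossprod(Xw, X)
  b <- crossprod(Xw, y)
  flagged <- FALSE
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) {
    flagged <- TRUE
    Ar <- A + diag(ridge_eps * mean(diag(A)), ncol(A))
    Ai <- tryCatch(solve(Ar), error = function(e) NULL)
  }
  if (is.null(Ai))
    return(list(coef = rep(NA_real_, ncol(X)), flagged = TRUE, XtWXi = NULL))
  list(coef = drop(Ai %*% b), flagged = flagged, XtWXi = Ai)
}

# Resolve per-focal bandwidths: fixed scalar, or adaptive k-NN distances.
focal_bandwidths <- function(D, bandwidth, adaptive) {
  n <- ncol(D)
  if (!adaptive) return(rep(bandwidth, n))
  k <- max(2L, min(as.integer(round(bandwidth)), n))
  apply(D, 2L, function(d) sort(d, partial = k)[k])
}

# One full pass of local fits. Returns coefficient matrix, hat diagonal,
# flags, and (optionally) leave-one-out predictions.
gtwr_pass <- function(X, y, D, bandwidth, kernel, ridge_eps, adaptive,
                      min_effective_weight, loo = FALSE) {
  n <- nrow(X); p1 <- ncol(X)
  bws <- focal_bandwidths(D, bandwidth, adaptive)
  coefs <- matrix(NA_real_, n, p1, dimnames = list(NULL, colnames(X)))
  hat <- rep(NA_real_, n)
  flags <- logical(n)
  pred_loo <- if (loo) rep(NA_real_, n) else NULL
  for (i in seq_len(n)) {
    w <- kernel_weight(D[, i], bws[i], kernel)
    if (loo) {
      w[i] <- 0
      if (sum(w) < min_effective_weight) next
    }
    fit <- fit_local_wls(X, y, w, ridge_eps)
    flags[i] <- fit$flagged
    if (anyNA(fit$coef)) { flags[i] <- TRUE; next }
    coefs[i, ] <- fit$coef
    if (loo) {
      pred_loo[i] <- sum(X[i, ] * fit$coef)
    } else if (!is.null(fit$XtWXi)) {
      # hat_ii = x_i' (X'WX)^{-1} x_i w_i
      hat[i] <- drop(X[i, , drop = FALSE] %*% fit$XtWXi %*% X[i, ]) * w[i]
    }
  }
  list(coefs = coefs, hat = hat, flags = flags, pred_loo = pred_loo)
}

panel_design <- function(panel, response, predictors) {
  req <- c("unit_id", "x", "y", "year", response, predictors)
  miss <- setdiff(req, names(panel))
  if (length(miss)) stopf("panel is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(panel[, c("unit_id", "year")]))
    stopf("panel has duplicate (unit_id, year) records")
  X <- cbind(`(Intercept)` = 1, as.matrix(panel[, predictors, drop = FALSE]))
  list(X = X, y = panel[[response]])
}

panel_coords <- function(panel, config) {
  u <- panel$x; v <- panel$y
  if (config$coords == "lonlat") {
    R <- 6371
    lon0 <- mean(range(u)); lat0 <- mean(range(v))
    list(u = R * cos(lat0 * pi / 180) * (u - lon0) * pi / 180,
         v = R * (v - lat0) * pi / 180, t = as.numeric(panel$year))
  } else {
    list(u = u, v = v, t = as.numeric(panel$year))
  }
}

#' Leave-one-out cross-validation score for a bandwidth
#'
#' Sum of squared leave-one-out prediction errors: each record's local fit
#' is recomputed with its own weight forced to zero. Records whose
#' remaining total weight falls below `min_effective_weight`, or whose
#' local system is unsolvable, make the score `Inf` (the bandwidth is
#' unusable).
#'
#' @param panel panel data.frame (`unit_id`, `x`, `y`, `year`, response,
#'   predictors).
#' @param response,predictors column names.
#' @param config a [gtwr_config()].
#' @param bandwidth candidate bandwidth.
#' @return scalar score (possibly `Inf`).
#' @export
gtwr_loocv <- function(panel, response, predictors, config, bandwidth) {
  des <- panel_design(panel, response, predictors)
  co <- panel_coords(panel, config)
  D <- st_distance_matrix(co$u, co$v, co$t, config$tau)
  gtwr_loocv_D(des$X, des$y, D, config, bandwidth)
}

gtwr_loocv_D <- function(X, y, D, config, bandwidth) {
  pass <- gtwr_pass(X, y, D, bandwidth, config$kernel, config$ridge_eps,
                    config$adaptive, config$min_effective_weight, loo = TRUE)
  if (anyNA(pass$pred_loo)) return(Inf)
  sum((y - pass$pred_loo)^2)
}

gtwr_aicc_D <- function(X, y, D, config, bandwidth) {
  pass <- gtwr_pass(X, y, D, bandwidth, config$kernel, config$ridge_eps,
                    config$adaptive, config$min_effective_weight, loo = FALSE)
  if (anyNA(pass$coefs) || anyNA(pass$hat)) return(Inf)
  n <- nrow(X)
  fitted <- rowSums(X * pass$coefs)
  sse <- sum((y - fitted)^2)
  trS <- sum(pass$hat)
  if (n - 2 - trS <= 0) return(Inf)
  n * log(sse / n) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

#' Select the GTWR bandwidth
#'
#' Evaluates the criterion (LOOCV by default, AICc optionally) over the
#' candidate grid, then refines by golden-section search between the grid
#' neighbours of the argmin. Ties resolve to the smaller bandwidth.
#'
#' @inheritParams gtwr_loocv
#' @param verbose print per-candidate scores.
#' @return list `bandwidth`, `score`, `grid`, `scores`.
#' @export
select_bandwidth <- function(panel, response, predictors, config, verbose = FALSE) {
  des <- panel_design(panel, response, predictors)
  co <- panel_coords(panel, config)
  D <- st_distance_matrix(co$u, co$v, co$t, config$tau)
  select_bandwidth_D(des$X, des$y, D, config, verbose)
}

select_bandwidth_D <- function(X, y, D, config, verbose = FALSE) {
  grid <- config$bandwidth_grid
  if (is.null(grid)) {
    diam <- max(D)
    if (diam <= 0) stopf("degenerate panel: all records at one space-time point")
    grid <- exp(seq(log(0.05), log(2), length.out = 10)) * diam
  }
  if (length(grid) == 0L) stopf("empty bandwidth grid")
  grid <- sort(unique(as.numeric(grid)))
  score_fn <- if (config$criterion == "loocv") gtwr_loocv_D else gtwr_aicc_D
  scores <- vapply(grid, function(b) score_fn(X, y, D, config, b), numeric(1))
  if (verbose) for (i in seq_along(grid))
    message(sprintf("  bandwidth %.4g: score %.6g", grid[i], scores[i]))
  if (all(!is.finite(scores)))
    stopf("no usable bandwidth in the grid (all scores infinite); widen the grid")
  i0 <- which.min(scores)   # first minimum = smaller bandwidth on ties
  best_b <- grid[i0]; best_s <- scores[i0]
  if (length(grid) > 1L && !config$adaptive) {
    lo <- if (i0 > 1L) grid[i0 - 1L] else grid[i0] * 0.5
    hi <- if (i0 < length(grid)) grid[i0 + 1L] else grid[i0]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- score_fn(X, y, D, config, x1); f2 <- score_fn(X, y, D, config, x2)
    iter <- 0L
    while (b - a > 1e-3 * hi && iter < 40L) {
      if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a)
                      f1 <- score_fn(X, y, D, config, x1) }
      else          { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a)
                      f2 <- score_fn(X, y, D, config, x2) }
      iter <- iter + 1L
    }
    xr <- (a + b) / 2
    fr <- score_fn(X, y, D, config, xr)
    if (is.finite(fr) && fr < best_s) { best_b <- xr; best_s <- fr }
  }
  list(bandwidth = best_b, score = best_s, grid = grid, scores = scores)
}

#' Fit a geographically and temporally weighted regression
#'
#' One local weighted least-squares fit per record, using kernel weights on
#' the spatiotemporal distances to all records (the focal record included,
#' standard GWR practice; leave-one-out removal happens only inside the
#' selection criterion). If `config$bandwidth` is `NULL` the bandwidth is
#' selected first; if `config$tau_grid` is given, `tau` is selected on the
#' same criterion by an outer grid search.
#'
#' @param panel screened panel data.frame (`unit_id`, `x`, `y`, `year`,
#'   response, predictors); typically standardized.
#' @param response name of the response column.
#' @param predictors names of the predictor columns.
#' @param config a [gtwr_config()].
#' @param verbose print selection progress.
#' @return object of class `gtwr_fit`: per-record `coefficients`
#'   (data.frame with `unit_id`, `year`, intercept and one column per
#'   predictor), `fitted`, `residuals`, `local_r2`, `flagged`, and global
#'   diagnostics `r_squared`, `rmse`, `aicc`, `bandwidth`, `tau`,
#'   `kernel`, `config`.
#' @export
fit_gtwr <- function(panel, response = "response", predictors, config = gtwr_config(),
                     verbose = FALSE) {
  if (!inherits(config, "gtwr_config")) stopf("'config' must be a gtwr_config")
  des <- panel_design(panel, response, predictors)
  co <- panel_coords(panel, config)
  n <- nrow(des$X)
  if (n < ncol(des$X) + 2L) stopf("panel too small for GTWR (%d records)", n)

  taus <- if (!is.null(config$tau_grid)) sort(unique(config$tau_grid)) else config$tau
  best <- NULL
  for (tau in taus) {
    cfg <- config; cfg$tau <- tau
    D <- st_distance_matrix(co$u, co$v, co$t, tau)
    if (is.null(cfg$bandwidth)) {
      sel <- select_bandwidth_D(des$X, des$y, D, cfg, verbose)
      bw <- sel$bandwidth; sc <- sel$score
    } else {
      bw <- cfg$bandwidth
      score_fn <- if (cfg$criterion == "loocv") gtwr_loocv_D else gtwr_aicc_D
      sc <- if (length(taus) > 1L) score_fn(des$X, des$y, D, cfg, bw) else NA_real_
    }
    if (is.null(best) || (is.finite(sc) && sc < best$score))
      best <- list(tau = tau, bandwidth = bw, score = sc, D = D)
  }

  D <- best$D
  pass <- gtwr_pass(des$X, des$y, D, best$bandwidth, config$kernel,
                    config$ridge_eps, config$adaptive,
                    config$min_effective_weight, loo = FALSE)
  n_bad <- sum(pass$flags & apply(pass$coefs, 1L, anyNA))
  if (n_bad > 0.1 * n)
    stopf("%d of %d local systems unsolvable; increase the bandwidth", n_bad, n)

  fitted <- rowSums(des$X * pass$coefs)
  resid <- des$y - fitted
  sse <- sum(resid^2, na.rm = TRUE)
  sst <- sum((des$y - mean(des$y))^2)
  trS <- sum(pass$hat, na.rm = TRUE)
  aicc <- if (n - 2 - trS > 0 && sse > 0)
    n * log(sse / n) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS) else NA_real_

  # local weighted R^2 at each focal point
  bws <- focal_bandwidths(D, best$bandwidth, config$adaptive)
  local_r2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (anyNA(pass$coefs[i, ])) next
    w <- kernel_weight(D[, i], bws[i], config$kernel)
    ri <- des$y - drop(des$X %*% pass$coefs[i, ])
    ybar_w <- sum(w * des$y) / sum(w)
    denom <- sum(w * (des$y - ybar_w)^2)
    if (denom > 0) local_r2[i] <- 1 - sum(w * ri^2) / denom
  }

  coefs <- data.frame(unit_id = panel$unit_id, year = panel$year,
                      x = panel$x, y = panel$y, pass$coefs, check.names = FALSE)
  structure(list(
    coefficients = coefs, predictors = predictors, response = response,
    fitted = fitted, residuals = resid, local_r2 = local_r2,
    flagged = pass$flags,
    r_squared = 1 - sse / sst, rmse = sqrt(sse / n), aicc = aicc,
    effective_parameters = trS,
    bandwidth = best$bandwidth, tau = best$tau, kernel = config$kernel,
    selection_score = best$score, config = config
  ), class = "gtwr_fit")
}

#' @export
print.gtwr_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<gtwr_fit> %d records, %d predictors\n",
    "  kernel %s, bandwidth %.4g, tau %.4g\n",
    "  R^2 = %.4f, RMSE = %.4g, AICc = %.4g, flagged = %d\n"),
    nrow(x$coefficients), length(x$predictors),
    x$kernel, x$bandwidth, x$tau,
    x$r_squared, x$rmse, x$aicc, sum(x$flagged)))
  invisible(x)
}

#' Summaries of local coefficients
#'
#' `group_by = "year"` gives, for each year and factor, the distribution of
#' local coefficients across units (min, quartiles, mean, max) — the
#' box-plot-by-year view. `group_by = "unit"` gives each unit's time-mean
#' coefficient per factor with its coordinates — the map-ready view.
#' Flagged (ridge-fallback or unsolvable) records are excluded.
#'
#' @param fit a `gtwr_fit`.
#' @param group_by `"year"` or `"unit"`.
#' @return data.frame of grouped summaries.
#' @export
coefficient_summary <- function(fit, group_by = c("year", "unit")) {
  group_by <- match.arg(group_by)
  if (!inherits(fit, "gtwr_fit")) stopf("'fit' must be a gtwr_fit")
  cf <- fit$coefficients[!fit$flagged, , drop = FALSE]
  vars <- c("(Intercept)", fit$predictors)
  if (group_by == "year") {
    out <- do.call(rbind, lapply(split(cf, cf$year), function(g) {
      do.call(rbind, lapply(vars, function(v) {
        q <- stats::quantile(g[[v]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
        data.frame(year = g$year[1L], factor = v, min = q[1L], q1 = q[2L],
                   median = q[3L], mean = mean(g[[v]]), q3 = q[4L], max = q[5L])
      }))
    }))
  } else {
    out <- do.call(rbind, lapply(split(cf, cf$unit_id), function(g) {
      means <- vapply(vars, function(v) mean(g[[v]]), numeric(1))
      cbind(data.frame(unit_id = g$unit_id[1L], x = mean(g$x), y = mean(g$y)),
            as.data.frame(as.list(means), check.names = FALSE))
    }))
  }
  rownames(out) <- NULL
  out
}
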