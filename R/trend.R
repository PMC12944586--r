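#' Fit a linear trend to an annual series
#'
#' Ordinary least-squares slope with a two-sided t-test on the slope
#' (n - 2 df), the convention behind "significant increase (p < 0.05)"
#' statements in vegetation-trend studies. The slope equals the closed form
#' \eqn{\sum(t-\bar t)(y-\bar y) / \sum(t-\bar t)^2}. A Theil-Sen slope with
#' a Mann-Kendall (Kendall tau) test is available as an alternative
#' estimator for series with outliers.
#'
#' @param times integer calendar years, strictly increasing.
#' @param values numeric series in native units; `NA`s are dropped pairwise.
#' @param method `"ols"` (default) or `"theil_sen"`.
#' @return object of class `trend_fit`: list with `slope` (units/year),
#'   `intercept`, `p_value`, `n`, `method`.
#' @examples
#' fit_linear_trend(1:5, c(1, 2, 2, 3, 5))$slope  # 0.9
#' @export
fit_linear_trend <- function(times, values, method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  if (length(times) != length(values)) stopf("fit error: 'times' and 'values' differ in length")
  ok <- is.finite(times) & is.finite(values)
  t <- as.numeric(times[ok]); y <- as.numeric(values[ok])
  n <- length(t)
  if (n < 3L) stopf("fit error: fewer than 3 finite points (%d)", n)
  if (any(diff(t) <= 0)) stopf("fit error: 'times' must be strictly increasing")
  Stt <- sum((t - mean(t))^2)
  if (Stt == 0) stopf("fit error: zero time variance")

  if (method == "ols") {
    slope <- sum((t - mean(t)) * (y - mean(y))) / Stt
    intercept <- mean(y) - slope * mean(t)
    resid <- y - intercept - slope * t
    sse <- sum(resid^2)
    se <- sqrt(sse / (n - 2) / Stt)
    p <- if (se == 0) {
      if (slope == 0) 1 else 0
    } else {
      2 * stats::pt(-abs(slope / se), df = n - 2)
    }
  } else {
    ij <- utils::combn(n, 2L)
    slopes <- (y[ij[2L, ]] - y[ij[1L, ]]) / (t[ij[2L, ]] - t[ij[1L, ]])
    slope <- stats::median(slopes)
    intercept <- stats::median(y - slope * t)
    p <- if (stats::var(y) == 0) 1 else
      suppressWarnings(stats::cor.test(t, y, method = "kendall"))$p.value
  }
  structure(list(slope = slope, intercept = intercept, p_value = p,
                 n = n, method = method), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit %s> slope = %.5g /year, p = %.3g, n = %d\n",
              x$method, x$slope, x$p_value, x$n))
  invisible(x)
}

#' Classify a fitted trend
#'
#' Total classification of (slope sign, p-value) into
#' `SIG_INC` / `NONSIG_INC` / `NONSIG_DEC` / `SIG_DEC` / `FLAT`.
#' An exactly-zero slope is its own `FLAT` class so the rule is total and
#' mutually exclusive.
#'
#' @param fit a `trend_fit`, or a numeric slope (then supply `p_value`).
#' @param p_value slope p-value when `fit` is numeric.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return one of [TREND_CLASSES].
#' @export
classify_trend <- function(fit, p_value = NULL, alpha = 0.05) {
  check_number(alpha, "alpha", lower = .Machine$double.xmin, upper = 1 - 1e-12)
  if (inherits(fit, "trend_fit")) {
    slope <- fit$slope; p <- fit$p_value
  } else {
    slope <- fit; p <- p_value
  }
  if (!is.finite(slope)) stopf("classification error: slope not finite")
  if (slope == 0) return("FLAT")
  sig <- is.finite(p) && p < alpha
  if (slope > 0) {
    if (sig) "SIG_INC" else "NONSIG_INC"
  } else {
    if (sig) "SIG_DEC" else "NONSIG_DEC"
  }
}

#' Piecewise trend rates around a split year
#'
#' Fits independent linear trends on `[start, split_year]` and
#' `[split_year, end]`; the split year belongs to both segments (the
#' "1980-2000" / "2000-2019" convention).
#'
#' @inheritParams fit_linear_trend
#' @param split_year breakpoint year, included in both segments.
#' @return list with `before` and `after`, each a `trend_fit`.
#' @export
segment_rates <- function(times, values, split_year, method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  pre <- times <= split_year
  post <- times >= split_year
  if (sum(pre & is.finite(values)) < 3L)
    stopf("fit error: pre-split segment has fewer than 3 points")
  if (sum(post & is.finite(values)) < 3L)
    stopf("fit error: post-split segment has fewer than 3 points")
  list(before = fit_linear_trend(times[pre], values[pre], method),
       after = fit_linear_trend(times[post], values[post], method))
}

#' Per-cell trend analysis of a raster series
#'
#' Vectorized OLS across all cells (NA-aware; a cell with fewer than 3
#' finite values is classified `NO_DATA`), returning slope, p-value and
#' trend-class grids.
#'
#' @param rs a [raster_series()].
#' @param alpha significance level for classification.
#' @param method `"ols"` (vectorized) or `"theil_sen"` (per-cell loop).
#' @return list of matrices `slope`, `p_value`, `class` (character;
#'   `"NO_DATA"` where unfittable) plus `alpha`.
#' @export
trend_raster <- function(rs, alpha = 0.05, method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  if (!inherits(rs, "raster_series")) stopf("'rs' must be a raster_series")
  d <- dim(rs$values)
  ncell <- d[1L] * d[2L]
  Y <- matrix(rs$values, ncell, d[3L])
  tt <- as.numeric(rs$years)

  if (method == "ols") {
    W <- is.finite(Y)
    n <- rowSums(W)
    Y0 <- ifelse(W, Y, 0)
    sum_t <- W %*% tt
    sum_t2 <- W %*% tt^2
    sum_y <- rowSums(Y0)
    sum_ty <- Y0 %*% tt
    sum_y2 <- rowSums(Y0^2)
    Sxx <- sum_t2 - sum_t^2 / n
    Sxy <- sum_ty - sum_t * sum_y / n
    Syy <- sum_y2 - sum_y^2 / n
    fit_ok <- n >= 3 & Sxx > 0
    slope <- ifelse(fit_ok, Sxy / Sxx, NA_real_)
    sse <- pmax(Syy - slope * Sxy, 0)
    se <- sqrt(sse / (n - 2) / Sxx)
    tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
    p <- ifelse(fit_ok, 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1)), NA_real_)
    p[fit_ok & se == 0 & slope == 0] <- 1
  } else {
    slope <- p <- rep(NA_real_, ncell)
    for (i in seq_len(ncell)) {
      yi <- Y[i, ]
      if (sum(is.finite(yi)) >= 3L) {
        f <- fit_linear_trend(tt, yi, method = "theil_sen")
        slope[i] <- f$slope; p[i] <- f$p_value
      }
    }
    fit_ok <- !is.na(slope)
  }

  cls <- rep("NO_DATA", ncell)
  ok <- which(fit_ok)
  if (length(ok)) {
    s <- slope[ok]; pv <- p[ok]
    cls[ok] <- ifelse(s == 0, "FLAT",
                      ifelse(s > 0,
                             ifelse(pv < alpha, "SIG_INC", "NONSIG_INC"),
                             ifelse(pv < alpha, "SIG_DEC", "NONSIG_DEC")))
  }
  list(slope = matrix(as.numeric(slope), d[1L], d[2L]),
       p_value = matrix(as.numeric(p), d[1L], d[2L]),
       class = matrix(cls, d[1L], d[2L]),
       alpha = alpha)
}

#' Area fractions per trend class
#'
#' Fractions of valid (masked, non-`NO_DATA`) cells in each trend class;
#' fractions sum to one over the classes present.
#'
#' @param class_grid character matrix of trend classes (e.g. from
#'   [trend_raster()]).
#' @param mask optional logical matrix; only `TRUE` cells are counted.
#' @param merge_flat if `TRUE`, `FLAT` cells are merged into `NONSIG_INC`
#'   for the summary.
#' @return named numeric vector of fractions over [TREND_CLASSES] (after
#'   optional merging), with an attribute `n_valid`.
#' @export
area_fractions <- function(class_grid, mask = NULL, merge_flat = FALSE) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(class_grid), ncol(class_grid))
  if (!identical(dim(mask), dim(class_grid)))
    stopf("mask shape %s != class grid shape %s",
          paste(dim(mask), collapse = "x"), paste(dim(class_grid), collapse = "x"))
  cls <- class_grid[mask & class_grid != "NO_DATA"]
  if (length(cls) == 0L) stopf("empty mask: no valid cells to summarize")
  if (merge_flat) cls[cls == "FLAT"] <- "NONSIG_INC"
  levels <- if (merge_flat) setdiff(TREND_CLASSES, "FLAT") else TREND_CLASSES
  fr <- table(factor(cls, levels = levels)) / length(cls)
  out <- stats::setNames(as.numeric(fr), levels)
  attr(out, "n_valid") <- length(cls)
  out
}
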