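#' Canonical factor-to-dimension mapping
#'
#' The four driver dimensions: natural (MT, MP, MD, MS), social (PD, EPR,
#' PI, FR, GY), economic (PG, PC, IS, IOR, IR), policy (GRGR).
#'
#' @return named character vector mapping factor name to dimension.
#' @export
dimension_map <- function() {
  c(MT = "natural", MP = "natural", MD = "natural", MS = "natural",
    PD = "social", EPR = "social", PI = "social", FR = "social", GY = "social",
    PG = "economic", PC = "economic", IS = "economic", IOR = "economic",
    IR = "economic",
    GRGR = "policy")
}

#' Dominant driver per unit
#'
#' For each unit, the factor with the largest absolute time-mean local
#' coefficient (GTWR fitted on standardized variables, so magnitudes are
#' comparable across factors); the sign comes from that mean. Exact ties
#' resolve to the lexicographically smallest factor name and are flagged.
#' Alternatives: the coefficient in the final year (`"final_year"`), or the
#' largest mean absolute contribution `|beta * x|` (`"contribution"`,
#' requires `panel`).
#'
#' @param fit a `gtwr_fit`.
#' @param method dominance rule.
#' @param panel the panel used for fitting (needed for `"contribution"`).
#' @return data.frame `unit_id`, `factor`, `sign` (`"+"`/`"-"`),
#'   `magnitude`, `label` (e.g. `"GRGR+"`), `tie` (logical).
#' @export
dominant_factors <- function(fit, method = c("mean_coef", "final_year", "contribution"),
                             panel = NULL) {
  method <- match.arg(method)
  if (!inherits(fit, "gtwr_fit")) stopf("'fit' must be a gtwr_fit")
  cf <- fit$coefficients[!fit$flagged, , drop = FALSE]
  facs <- fit$predictors
  if (method == "contribution") {
    if (is.null(panel)) stopf("'panel' is required for method = 'contribution'")
    key <- paste(cf$unit_id, cf$year)
    pkey <- paste(panel$unit_id, panel$year)
    idx <- match(key, pkey)
    if (anyNA(idx)) stopf("panel does not cover all fitted records")
    for (f in facs) cf[[f]] <- cf[[f]] * panel[[f]][idx]
  }
  out <- do.call(rbind, lapply(split(cf, cf$unit_id), function(g) {
    if (method == "final_year") g <- g[g$year == max(g$year), , drop = FALSE]
    m <- vapply(facs, function(f) mean(g[[f]]), numeric(1))
    a <- abs(m)
    best <- sort(facs[a == max(a)])
    f <- best[1L]
    data.frame(unit_id = g$unit_id[1L], factor = f,
               sign = if (m[[f]] >= 0) "+" else "-",
               magnitude = a[[f]],
               label = paste0(f, if (m[[f]] >= 0) "+" else "-"),
               tie = length(best) > 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Dominant driver of one unit
#'
#' @inheritParams dominant_factors
#' @param unit unit id.
#' @return one-row data.frame (see [dominant_factors()]).
#' @export
dominant_factor <- function(fit, unit, method = "mean_coef", panel = NULL) {
  all <- dominant_factors(fit, method = method, panel = panel)
  row <- all[all$unit_id == unit, , drop = FALSE]
  if (nrow(row) == 0L) stopf("unit '%s' not present in the fitted result", unit)
  row
}

#' Dimension-averaged explanatory power
#'
#' Unweighted arithmetic mean of the available q-values of the factors in
#' each dimension, per year. Missing q cells are excluded from the mean; a
#' dimension with no available factor in a year yields a missing cell.
#'
#' @param q_table data.frame with `factor`, `year`, `q` (e.g. from
#'   [factor_detector()]).
#' @param dims named character vector mapping every factor in `q_table` to
#'   a dimension; defaults to [dimension_map()].
#' @return data.frame `dimension`, `year`, `q_mean`, `n_factors`.
#' @export
dimension_average_q <- function(q_table, dims = dimension_map()) {
  if (nrow(q_table) == 0L) stopf("empty q table")
  unmapped <- setdiff(unique(q_table$factor), names(dims))
  if (length(unmapped))
    stopf("factor(s) not mapped to a dimension: %s", paste(unmapped, collapse = ", "))
  q_table$dimension <- unname(dims[q_table$factor])
  out <- expand.grid(dimension = unique(q_table$dimension),
                     year = sort(unique(q_table$year)),
                     stringsAsFactors = FALSE)
  out$q_mean <- NA_real_
  out$n_factors <- 0L
  for (i in seq_len(nrow(out))) {
    qs <- q_table$q[q_table$dimension == out$dimension[i] &
                      q_table$year == out$year[i]]
    qs <- qs[!is.na(qs)]
    out$n_factors[i] <- length(qs)
    if (length(qs)) out$q_mean[i] <- mean(qs)
  }
  out
}
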