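#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R_j^2), where R_j^2 is the coefficient of determination
#' from regressing predictor j on all other predictors (with intercept).
#' Exact collinearity is reported as `Inf`, not an error.
#'
#' @param design numeric matrix or data.frame of predictors (>= 2 columns,
#'   more rows than columns).
#' @return data.frame `variable`, `vif`.
#' @export
compute_vif <- function(design) {
  X <- as.matrix(design)
  if (!is.numeric(X)) stopf("design matrix must be numeric")
  p <- ncol(X)
  if (p < 2L) stopf("VIF needs at least 2 predictors")
  if (nrow(X) <= p) stopf("VIF needs more records than predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  vif <- numeric(p)
  for (j in seq_len(p)) {
    yj <- X[, j]
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) stopf("predictor '%s' has zero variance", colnames(X)[j])
    Zj <- cbind(`(Intercept)` = 1, X[, -j, drop = FALSE])
    qrz <- qr(Zj)
    sse <- sum(qr.resid(qrz, yj)^2)
    r2 <- 1 - sse / sst
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  data.frame(variable = colnames(X), vif = vif)
}

#' Collinearity screen at a VIF threshold
#'
#' Single-pass screen (the default): all predictors with VIF above the
#' threshold are excluded at once, and the rest retained. An iterative mode
#' removes the largest-VIF predictor one at a time until all remaining VIFs
#' are at or below the threshold.
#'
#' @param panel data.frame containing the candidate predictors.
#' @param predictors character vector of candidate predictor names.
#' @param threshold VIF cutoff (> 1), default 7.5.
#' @param iterative use stepwise removal instead of the single pass.
#' @return list with `retained`, `excluded` (character vectors) and
#'   `report` (data.frame `variable`, `vif`, `excluded`, `threshold`; in
#'   iterative mode `vif` is the value at the step a variable was removed,
#'   or the final value if retained).
#' @export
vif_screen <- function(panel, predictors = NULL, threshold = 7.5, iterative = FALSE) {
  check_number(threshold, "threshold", lower = 1 + 1e-12)
  check_flag(iterative, "iterative")
  if (is.null(predictors))
    predictors <- setdiff(names(panel)[vapply(panel, is.numeric, TRUE)],
                          c("unit_id", "x", "y", "year", "response"))
  X <- as.matrix(panel[, predictors, drop = FALSE])
  if (!iterative) {
    rep_df <- compute_vif(X)
    rep_df$excluded <- rep_df$vif > threshold
  } else {
    active <- predictors
    removed <- character(0)
    removed_vif <- numeric(0)
    repeat {
      if (length(active) < 2L) break
      v <- compute_vif(X[, active, drop = FALSE])
      if (max(v$vif) <= threshold) break
      worst <- v$variable[which.max(v$vif)]
      removed <- c(removed, worst)
      removed_vif <- c(removed_vif, max(v$vif))
      active <- setdiff(active, worst)
    }
    final <- if (length(active) >= 2L) compute_vif(X[, active, drop = FALSE])
             else data.frame(variable = active, vif = NA_real_)
    rep_df <- rbind(
      data.frame(variable = final$variable, vif = final$vif, excluded = FALSE),
      data.frame(variable = removed, vif = removed_vif,
                 excluded = rep(TRUE, length(removed)))
    )
    rep_df <- rep_df[match(predictors, rep_df$variable), ]
    rownames(rep_df) <- NULL
  }
  rep_df$threshold <- threshold
  excluded <- rep_df$variable[rep_df$excluded]
  retained <- setdiff(predictors, excluded)
  if (length(retained) == 0L)
    stopf("collinearity screen excluded every candidate predictor (threshold %.3g)", threshold)
  list(retained = retained, excluded = excluded, report = rep_df)
}
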