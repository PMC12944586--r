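#' Discretize a continuous driver into strata
#'
#' Stratification methods: `"quantile"` (breaks at k/L sample quantiles,
#' ties assigned to the lower stratum; the default), `"equal_interval"`
#' (evenly spaced breaks over the range), and `"jenks"` (exact
#' minimum-within-class-variance partition by dynamic programming, the
#' natural-breaks scheme common in geographical-detector practice). Empty
#' strata are collapsed and the effective stratum count reduced.
#'
#' @param values numeric driver values, one per unit.
#' @param L requested stratum count (>= 2).
#' @param method discretization method.
#' @return object of class `stratification`: list `labels` (integer in
#'   1..L_effective), `L`, `breaks`, `method`.
#' @export
discretize <- function(values, L = 5, method = c("quantile", "jenks", "equal_interval")) {
  method <- match.arg(method)
  if (!is.numeric(values) || anyNA(values)) stopf("'values' must be numeric without NA")
  check_number(L, "L", lower = 2)
  L <- as.integer(L)
  n <- length(values)
  if (length(unique(values)) == 1L) {
    warning("constant input: a single stratum (q will be 0)", call. = FALSE)
    return(structure(list(labels = rep(1L, n), L = 1L, breaks = numeric(0),
                          method = method), class = "stratification"))
  }
  if (method %in% c("quantile", "jenks") && length(unique(values)) < L)
    stopf("need at least L = %d distinct values for method '%s'", L, method)

  labels <- switch(method,
    quantile = {
      br <- stats::quantile(values, probs = seq_len(L - 1L) / L, names = FALSE, type = 7)
      # (-Inf, b1], (b1, b2], ... : ties fall in the lower stratum
      findInterval(values, unique(br), left.open = TRUE) + 1L
    },
    equal_interval = {
      br <- seq(min(values), max(values), length.out = L + 1L)[2:L]
      findInterval(values, br, left.open = TRUE) + 1L
    },
    jenks = jenks_labels(values, L)
  )
  # collapse empty strata to consecutive labels
  labels <- match(labels, sort(unique(labels)))
  Leff <- max(labels)
  br <- vapply(seq_len(Leff - 1L),
               function(h) max(values[labels == h]), numeric(1))
  structure(list(labels = as.integer(labels), L = Leff, breaks = br, method = method),
            class = "stratification")
}

# Exact Fisher natural-breaks partition by O(L n^2) dynamic programming on
# the sorted values (minimizes total within-class sum of squares).
jenks_labels <- function(values, L) {
  o <- order(values)
  x <- values[o]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) { # within-SS of x[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  cost <- matrix(Inf, L, n)
  back <- matrix(0L, L, n)
  for (j in seq_len(n)) cost[1L, j] <- ssq(1L, j)
  for (k in 2:L) {
    for (j in k:n) {
      for (i in k:j) {
        c_ <- cost[k - 1L, i - 1L] + ssq(i, j)
        if (c_ < cost[k, j]) { cost[k, j] <- c_; back[k, j] <- i }
      }
    }
  }
  lab_sorted <- integer(n)
  j <- n
  for (k in L:1) {
    i <- if (k > 1L) back[k, j] else 1L
    lab_sorted[i:j] <- k
    j <- i - 1L
  }
  labels <- integer(n)
  labels[o] <- lab_sorted
  labels
}

#' Factor-detector q-statistic
#'
#' The fraction of the response's variance explained by a stratification:
#' \deqn{q = 1 - \frac{\sum_h N_h \sigma_h^2}{N \sigma^2} = 1 - \frac{SSW}{SST},}
#' with population (biased) variances in both numerator and denominator so
#' that the decomposition SSW + SSB = SST holds exactly for unequal stratum
#' sizes.
#'
#' @param y numeric response per unit (N >= 2, nonconstant).
#' @param strata a [discretize()] result, or an integer/factor label vector.
#' @return object of class `q_result`: list `q`, `N`, `L`, `N_h`,
#'   `sigma2_h`, `sigma2`, `SSW`, `SST`.
#' @examples
#' q_statistic(c(1, 2, 3, 6), c(1, 1, 2, 2))$q  # 9/14
#' @export
q_statistic <- function(y, strata) {
  labels <- if (inherits(strata, "stratification")) strata$labels else as.integer(as.factor(strata))
  if (length(y) != length(labels)) stopf("'y' and strata labels differ in length")
  if (anyNA(y) || anyNA(labels)) stopf("NA in response or strata")
  N <- length(y)
  if (N < 2L) stopf("need at least 2 units")
  sigma2 <- mean((y - mean(y))^2)
  if (sigma2 == 0) stopf("response constant; q undefined")
  groups <- split(y, labels)
  N_h <- vapply(groups, length, 0L)
  sigma2_h <- vapply(groups, function(g) mean((g - mean(g))^2), numeric(1))
  SSW <- sum(N_h * sigma2_h)
  SST <- N * sigma2
  structure(list(q = 1 - SSW / SST, N = N, L = length(groups),
                 N_h = N_h, sigma2_h = sigma2_h, sigma2 = sigma2,
                 SSW = SSW, SST = SST),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> q = %.4f (N = %d, L = %d strata)\n", x$q, x$N, x$L))
  invisible(x)
}

# Fast q for permutation loops: labels as a factor-like integer vector.
q_value_fast <- function(y, labels, SST) {
  gs <- rowsum(y, labels)
  gn <- tabulate(labels)
  gs2 <- rowsum(y^2, labels)
  WSS <- sum(gs2 - gs^2 / gn)
  1 - WSS / SST
}

#' Significance of the q-statistic
#'
#' Default is a seeded permutation test: the stratum labels are randomly
#' reassigned B times and `p = (1 + #\{q_perm >= q_obs\}) / (B + 1)`.
#' Alternatively the canonical noncentral-F reference distribution:
#' `F = ((N - L) / (L - 1)) * q / (1 - q)` referred to
#' `F(L - 1, N - L; lambda)` with noncentrality
#' `lambda = (sum_h ybar_h^2 - (sum_h sqrt(N_h) ybar_h)^2 / N) / sigma^2`.
#'
#' @inheritParams q_statistic
#' @param method `"permutation"` (default) or `"noncentral_f"`.
#' @param B number of permutations (>= 99).
#' @param seed integer seed for the permutation draw.
#' @return the p-value.
#' @export
q_significance <- function(y, strata, method = c("permutation", "noncentral_f"),
                           B = 999, seed = 1L) {
  method <- match.arg(method)
  labels <- if (inherits(strata, "stratification")) strata$labels else as.integer(as.factor(strata))
  if (length(unique(labels)) == 1L) return(1)
  qr_ <- q_statistic(y, labels)
  if (method == "permutation") {
    if (B < 99) stopf("B must be at least 99 for a stable permutation p-value")
    set.seed(derive_seed(seed, "q_perm"))
    SST <- qr_$SST
    qperm <- vapply(seq_len(B),
                    function(b) q_value_fast(sample(y), labels, SST),
                    numeric(1))
    (1 + sum(qperm >= qr_$q - 1e-12)) / (B + 1)
  } else {
    N <- qr_$N; L <- qr_$L
    if (N - L < 1L) stopf("too few units for the noncentral-F test")
    Fv <- (N - L) / (L - 1) * qr_$q / (1 - qr_$q)
    ybar_h <- vapply(split(y, labels), mean, numeric(1))
    lambda <- (sum(ybar_h^2) -
                 sum(sqrt(qr_$N_h) * ybar_h)^2 / N) / qr_$sigma2
    stats::pf(Fv, L - 1, N - L, ncp = lambda, lower.tail = FALSE)
  }
}

#' Factor-detector table over factors and years
#'
#' One q-statistic (with significance stars) per factor and year: the
#' factor is discretized within each year, and the q of the response's
#' cross-sectional values computed. Factor-years where the factor is
#' entirely missing are emitted as missing cells, never as zero.
#'
#' @param panel data.frame with `unit_id`, `year`, the response column and
#'   factor columns.
#' @param response response column name.
#' @param factors character vector of factor columns.
#' @param years years at which to evaluate (default: all in the panel).
#' @param L stratum count for discretization.
#' @param method discretization method.
#' @param sig_method significance method (see [q_significance()]).
#' @param B permutations for the permutation test.
#' @param seed seed for permutation draws.
#' @return data.frame `factor`, `year`, `q`, `p_value`, `stars`
#'   (`"**"` p < 0.01, `"*"` p < 0.05, else `""`), `L` (effective), with
#'   class `q_table`. Missing cells carry `NA` q and empty stars.
#' @export
factor_detector <- function(panel, response, factors, years = NULL,
                            L = 5, method = "quantile",
                            sig_method = "permutation", B = 999, seed = 1L) {
  if (is.null(years)) years <- sort(unique(panel$year))
  out <- expand.grid(factor = factors, year = as.integer(years),
                     stringsAsFactors = FALSE)
  out$q <- NA_real_; out$p_value <- NA_real_; out$stars <- ""; out$L <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sub <- panel[panel$year == out$year[i], , drop = FALSE]
    yv <- sub[[response]]
    fv <- sub[[out$factor[i]]]
    if (is.null(fv) || all(is.na(fv))) next        # missing factor-year: "-"
    if (any(is.na(fv)) || any(is.na(yv)))
      stopf("misaligned units for factor '%s' in year %d", out$factor[i], out$year[i])
    st <- suppressWarnings(discretize(fv, L = L, method = method))
    qr_ <- q_statistic(yv, st)
    out$q[i] <- qr_$q
    out$L[i] <- st$L
    out$p_value[i] <- if (st$L == 1L) 1 else
      q_significance(yv, st, method = sig_method, B = B,
                     seed = derive_seed(seed, paste(out$factor[i], out$year[i])))
    out$stars[i] <- if (is.na(out$p_value[i])) "" else
      if (out$p_value[i] < 0.01) "**" else if (out$p_value[i] < 0.05) "*" else ""
  }
  class(out) <- c("q_table", class(out))
  out
}

#' Widen a q-table for display
#'
#' @param q_table result of [factor_detector()].
#' @param digits rounding for display.
#' @return data.frame with one row per year, one column per factor holding
#'   `"q stars"` strings (`"-"` for missing cells).
#' @export
q_table_wide <- function(q_table, digits = 3) {
  years <- sort(unique(q_table$year))
  facs <- unique(q_table$factor)
  wide <- data.frame(year = years)
  for (f in facs) {
    col <- vapply(years, function(yr) {
      r <- q_table[q_table$factor == f & q_table$year == yr, ]
      if (nrow(r) == 0L || is.na(r$q[1L])) "-"
      else trimws(paste(round(r$q[1L], digits), r$stars[1L]))
    }, character(1))
    wide[[f]] <- col
  }
  wide
}
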