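# Shared fixture builders (all generated in code, seeded).

# Small panel for fast GTWR tests.
small_panel <- function(n_units = 20, years = 2000:2011, noise_sd = 0.05, seed = 11) {
  generate_panel(panel_config(n_units = n_units, years = years, noise_sd = noise_sd),
                 seed = seed)
}

# Panel whose true coefficients are constant in space and time.
constant_coef_panel <- function(n_units = 15, years = 2000:2009, noise_sd = 0,
                                seed = 5) {
  cfg <- panel_config(
    n_units = n_units, years = years,
    intercept = c(a = 1, b = 0, c = 0, d = 0),
    predictors = list(x1 = c(a = 2, b = 0, c = 0, d = 0),
                      x2 = c(a = -1, b = 0, c = 0, d = 0)),
    noise_sd = noise_sd
  )
  generate_panel(cfg, seed = seed)
}

# Tiny land-use series built by hand: nr x nc grid, explicit per-year grids.
manual_landuse <- function(grids, years, codes = c(cropland = 1L, forest = 2L,
                                                   shrubland = 3L, grassland = 4L,
                                                   other = 5L)) {
  arr <- array(NA_integer_, dim = c(nrow(grids[[1]]), ncol(grids[[1]]), length(grids)))
  for (k in seq_along(grids)) arr[, , k] <- grids[[k]]
  landuse_series(arr, years, codes)
}

# Spatiotemporal distance diameter of a panel.
panel_diameter <- function(panel, tau = 1) {
  max(vegdrivers:::st_distance_matrix(panel$x, panel$y, as.numeric(panel$year), tau))
}

# Independent brute-force q: explicit group-variance decomposition.
brute_force_q <- function(y, labels) {
  N <- length(y)
  SST <- sum((y - mean(y))^2)
  SSW <- 0
  for (h in unique(labels)) {
    g <- y[labels == h]
    SSW <- SSW + sum((g - mean(g))^2)
  }
  1 - SSW / SST
}

# Independent brute-force VIF: auxiliary regressions by normal equations.
brute_force_vif <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    beta <- solve(t(Z) %*% Z, t(Z) %*% yj)
    r2 <- 1 - sum((yj - Z %*% beta)^2) / sum((yj - mean(yj))^2)
    1 / (1 - r2)
  }, numeric(1))
}
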