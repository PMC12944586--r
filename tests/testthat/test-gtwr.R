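test_that("spatiotemporal distance has the stated metric and symmetry", {
  expect_equal(st_distance(c(0, 0, 2000), c(3, 4, 2000)), 5)
  expect_equal(st_distance(c(0, 0, 2000), c(0, 0, 2002), tau = 4), 4)
  expect_equal(st_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(2, -1, 1995); b <- c(-3, 4, 2010)
  expect_equal(st_distance(a, b, tau = 0.25), st_distance(b, a, tau = 0.25))
  # tau = 0 ignores time entirely
  expect_equal(st_distance(c(0, 0, 1980), c(0, 0, 2020), tau = 0), 0)
})

test_that("kernel weights are 1 at zero, decay, and bisquare has compact support", {
  expect_equal(kernel_weight(0, 2, "gaussian"), 1)
  expect_equal(kernel_weight(0, 2, "bisquare"), 1)
  expect_equal(kernel_weight(2, 2, "gaussian"), exp(-1))
  expect_equal(kernel_weight(c(2, 3, 10), 2, "bisquare"), c(0, 0, 0))
  d <- seq(0, 5, by = 0.1)
  for (k in c("gaussian", "bisquare")) {
    w <- kernel_weight(d, 2, k)
    expect_true(all(diff(w) <= 1e-15))
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(kernel_weight(1, 0, "gaussian"), "positive")
  expect_error(kernel_weight(-1, 1, "gaussian"), "nonnegative")
})

test_that("local WLS solves exactly and zero weights exclude points", {
  X <- cbind(1, c(0, 1, 2))
  y <- c(1, 3, 5)
  f <- fit_local_wls(X, y, rep(1, 3))
  expect_equal(f$coef, c(1, 2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(f$flagged)
  # gross outlier with zero weight: line recovered exactly
  X2 <- cbind(1, c(0, 1, 2, 3))
  y2 <- c(1, 3, 5, 100)
  f2 <- fit_local_wls(X2, y2, c(1, 1, 1, 0))
  expect_equal(f2$coef, c(1, 2), tolerance = 1e-12, ignore_attr = TRUE)
  # duplicated predictor column triggers the ridge fallback flag
  X3 <- cbind(1, c(0, 1, 2, 3), c(0, 1, 2, 3))
  f3 <- fit_local_wls(X3, y2, rep(1, 4))
  expect_true(f3$flagged)
  expect_error(fit_local_wls(X, y, rep(0, 3)), "weights")
})

test_that("LOOCV equals brute-force delete-one refitting", {
  g <- small_panel(n_units = 10, years = 2005:2008, seed = 19)  # n = 40
  panel <- g$panel
  cfg <- gtwr_config(tau = 1)
  bw <- 0.4 * panel_diameter(panel)
  score <- gtwr_loocv(panel, "response", c("x1", "x2", "x3"), cfg, bw)
  # oracle: literally drop record i, fit at its location, predict it
  X <- cbind(1, as.matrix(panel[, c("x1", "x2", "x3")]))
  D <- vegdrivers:::st_distance_matrix(panel$x, panel$y, as.numeric(panel$year), 1)
  brute <- 0
  for (i in seq_len(nrow(panel))) {
    w <- kernel_weight(D[-i, i], bw, "gaussian")
    Xi <- X[-i, , drop = FALSE]
    beta <- solve(t(Xi * w) %*% Xi, t(Xi * w) %*% panel$response[-i])
    brute <- brute + (panel$response[i] - drop(X[i, ] %*% beta))^2
  }
  expect_equal(score, brute, tolerance = 1e-10)
})

test_that("a single-candidate grid is returned unchanged", {
  g <- small_panel(n_units = 8, years = 2000:2004, seed = 23)
  cfg <- gtwr_config(bandwidth_grid = 150, adaptive = TRUE)
  # adaptive flag suppresses golden refinement; grid of one must come back as-is
  sel <- select_bandwidth(g$panel, "response", c("x1", "x2", "x3"), cfg)
  expect_equal(sel$bandwidth, 150)
})

test_that("zero-noise global-linear data is fitted exactly at any bandwidth", {
  g <- constant_coef_panel(noise_sd = 0)
  diam <- panel_diameter(g$panel)
  for (mult in c(0.1, 1, 10)) {
    fit <- fit_gtwr(g$panel, "response", c("x1", "x2"),
                    gtwr_config(bandwidth = mult * diam))
    M <- as.matrix(fit$coefficients[, c("(Intercept)", "x1", "x2")])
    expect_lt(max(abs(sweep(M, 2, c(1, 2, -1)))), 1e-6)
    expect_equal(fit$residuals, rep(0, nrow(g$panel)), tolerance = 1e-8)
  }
})

test_that("an enormous bandwidth reproduces global OLS at every record", {
  g <- small_panel(n_units = 12, years = 2000:2009, noise_sd = 0.2, seed = 29)
  diam <- panel_diameter(g$panel)
  fit <- fit_gtwr(g$panel, "response", c("x1", "x2", "x3"),
                  gtwr_config(bandwidth = 1e6 * diam))
  ols <- lm(response ~ x1 + x2 + x3, data = g$panel)
  M <- as.matrix(fit$coefficients[, c("(Intercept)", "x1", "x2", "x3")])
  expect_lt(max(abs(sweep(M, 2, coef(ols)))), 1e-8)
})

test_that("tau = 0 with one shared year reproduces an independent GWR oracle", {
  set.seed(37)
  n <- 30
  panel <- data.frame(unit_id = 1:n, x = runif(n, 0, 100), y = runif(n, 0, 100),
                      year = 2000,
                      x1 = rnorm(n), x2 = rnorm(n))
  panel$response <- 1 + 0.02 * panel$x * panel$x1 - 0.5 * panel$x2 + rnorm(n, sd = 0.1)
  bw <- 40
  fit <- fit_gtwr(panel, "response", c("x1", "x2"),
                  gtwr_config(tau = 0, bandwidth = bw))
  # oracle: explicit per-point weighted normal equations, spatial only
  X <- cbind(1, panel$x1, panel$x2)
  for (i in seq_len(n)) {
    d2 <- (panel$x - panel$x[i])^2 + (panel$y - panel$y[i])^2
    W <- diag(exp(-d2 / bw^2))
    beta <- solve(t(X) %*% W %*% X) %*% (t(X) %*% W %*% panel$response)
    expect_equal(as.numeric(fit$coefficients[i, c("(Intercept)", "x1", "x2")]),
                 as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("bandwidth selection oversmooths constant-coefficient data and not varying data", {
  g <- constant_coef_panel(n_units = 12, years = 2000:2007, noise_sd = 0.05, seed = 13)
  diam <- panel_diameter(g$panel)
  grid <- seq(0.1, 1, by = 0.1) * diam
  sel <- select_bandwidth(g$panel, "response", c("x1", "x2"),
                          gtwr_config(bandwidth_grid = grid))
  expect_gte(sel$bandwidth, grid[9])   # at or beyond the penultimate candidate
  gv <- small_panel(n_units = 25, years = 2000:2011, noise_sd = 0.05, seed = 17)
  selv <- select_bandwidth(gv$panel, "response", c("x1", "x2", "x3"),
                           gtwr_config(bandwidth_grid = grid))
  expect_lt(selv$bandwidth, grid[10])
})

test_that("coefficient estimates track varying true surfaces and improve with less noise", {
  maes <- numeric(0)
  for (ns in c(0.5, 0.1)) {
    g <- generate_panel(panel_config(n_units = 30, years = 2000:2014, noise_sd = ns),
                        seed = 47)
    fit <- fit_gtwr(g$panel, "response", c("x1", "x2", "x3"),
                    gtwr_config(bandwidth = 0.08 * panel_diameter(g$panel)))
    err <- 0
    for (k in 1:3) {
      est <- fit$coefficients[[paste0("x", k)]]
      tru <- g$truth[[paste0("beta_x", k)]]
      err <- err + mean(abs(est - tru))
      if (ns == 0.1) expect_gt(cor(est, tru), 0.9)
    }
    maes <- c(maes, err / 3)
  }
  expect_lt(maes[2], maes[1])
})

test_that("GTWR is deterministic and its result bookkeeping is consistent", {
  g <- small_panel(n_units = 10, years = 2000:2005, seed = 53)
  cfg <- gtwr_config(bandwidth = 100)
  f1 <- fit_gtwr(g$panel, "response", c("x1", "x2", "x3"), cfg)
  f2 <- fit_gtwr(g$panel, "response", c("x1", "x2", "x3"), cfg)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  # residual = y - fitted exactly
  expect_equal(f1$residuals, g$panel$response - f1$fitted, tolerance = 0)
  expect_true(all(is.finite(as.matrix(
    f1$coefficients[, c("(Intercept)", "x1", "x2", "x3")]))))
})

test_that("lon/lat coordinates are accepted via planar conversion", {
  g <- small_panel(n_units = 10, years = 2000:2005, seed = 59)
  panel_ll <- g$panel
  # map the km coordinates into a plausible lon/lat window
  panel_ll$x <- 100 + panel_ll$x / 111.32 / cos(36 * pi / 180) * 0.1
  panel_ll$y <- 34 + panel_ll$y / 111.19 * 0.1
  fit <- fit_gtwr(panel_ll, "response", c("x1", "x2", "x3"),
                  gtwr_config(bandwidth = 50, coords = "lonlat"))
  expect_true(all(is.finite(fit$fitted)))
  expect_gt(fit$r_squared, 0.5)
})

test_that("coefficient summaries give order statistics and double-average identity", {
  g <- small_panel(n_units = 5, years = 2000:2004, seed = 61)
  fit <- fit_gtwr(g$panel, "response", c("x1", "x2", "x3"),
                  gtwr_config(bandwidth = 300))
  by_year <- coefficient_summary(fit, "year")
  expect_setequal(unique(by_year$factor), c("(Intercept)", "x1", "x2", "x3"))
  # medians are true medians across the 5 units
  y0 <- fit$coefficients[fit$coefficients$year == 2000, ]
  expect_equal(by_year$median[by_year$year == 2000 & by_year$factor == "x1"],
               median(y0$x1))
  by_unit <- coefficient_summary(fit, "unit")
  expect_equal(mean(by_unit$x1), mean(fit$coefficients$x1), tolerance = 1e-12)
  # all-identical coefficients collapse the quartiles
  fitc <- fit_gtwr(constant_coef_panel()$panel, "response", c("x1", "x2"),
                   gtwr_config(bandwidth = 1e5))
  s <- coefficient_summary(fitc, "year")
  expect_equal(s$q1, s$q3, tolerance = 1e-6)
})
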