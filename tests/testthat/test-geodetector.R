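test_that("quantile discretization splits at sample quantiles with ties downward", {
  st <- discretize(c(1, 2, 3, 4), L = 2)
  expect_equal(st$labels, c(1L, 1L, 2L, 2L))
  # ties at the break fall in the lower stratum
  st2 <- discretize(c(1, 1, 1, 2, 3, 4), L = 2, method = "quantile")
  expect_equal(max(st2$labels), 2L)
  expect_true(all(st2$labels[c(1, 2, 3)] == 1L))
  # saturation: L = N gives every unit its own stratum
  st3 <- discretize(c(5, 1, 9, 3), L = 4)
  expect_equal(sort(unique(st3$labels)), 1:4)
  expect_warning(st4 <- discretize(rep(2, 6), L = 3), "single stratum")
  expect_equal(st4$L, 1L)
  expect_error(discretize(c(1, 2, 2, 2), L = 3), "distinct")
})

test_that("jenks and equal-interval stratifications behave sensibly", {
  x <- c(1, 1.1, 1.2, 10, 10.1, 10.2, 20, 20.1, 20.2)
  stj <- discretize(x, L = 3, method = "jenks")
  expect_equal(stj$labels, rep(1:3, each = 3))
  # jenks minimizes within-class SS: compare against all contiguous 2-splits
  x2 <- c(0, 1, 2, 10, 11, 12)
  stj2 <- discretize(x2, L = 2, method = "jenks")
  wss <- function(lab) sum(unlist(lapply(split(x2, lab), function(g) sum((g - mean(g))^2))))
  best <- min(vapply(1:5, function(k) wss(rep(1:2, c(k, 6 - k))), numeric(1)))
  expect_equal(wss(stj2$labels), best)
  ste <- discretize(c(0, 0.4, 0.6, 1), L = 2, method = "equal_interval")
  expect_equal(ste$labels, c(1L, 1L, 2L, 2L))
})

test_that("q-statistic matches hand-computed variance decompositions", {
  expect_equal(q_statistic(c(1, 2, 3, 6), c(1, 1, 2, 2))$q, 9 / 14, tolerance = 1e-12)
  # single stratum: q = 0
  expect_equal(q_statistic(c(1, 2, 3, 4), rep(1, 4))$q, 0, tolerance = 1e-12)
  # zero within-stratum variance: q = 1
  expect_equal(q_statistic(c(1, 1, 2, 2), c(1, 1, 2, 2))$q, 1, tolerance = 1e-12)
  r <- q_statistic(c(1, 2, 3, 6), c(1, 1, 2, 2))
  expect_equal(r$SSW, 0.5 + 4.5, tolerance = 1e-12)
  expect_equal(r$SST, 14, tolerance = 1e-12)
  expect_equal(sum(r$N_h), r$N)
  expect_error(q_statistic(rep(5, 4), c(1, 1, 2, 2)), "constant")
})

test_that("q equals the brute-force decomposition, stays in [0,1], is affine-invariant", {
  set.seed(71)
  for (i in 1:200) {
    N <- sample(7:50, 1)
    L <- sample(2:6, 1)
    y <- rnorm(N)
    labels <- sample(seq_len(L), N, replace = TRUE)
    labels[seq_len(L)] <- seq_len(L)  # every stratum nonempty
    q <- q_statistic(y, labels)$q
    expect_lt(abs(q - brute_force_q(y, labels)), 1e-12)
    expect_gte(q, 0); expect_lte(q, 1)
    a <- runif(1, 0.5, 3) * sample(c(-1, 1), 1)
    expect_lt(abs(q_statistic(a * y + 5, labels)$q - q), 1e-12)
    # additivity: SSW + between-stratum mass = SST exactly
    r <- q_statistic(y, labels)
    ybar_h <- vapply(split(y, labels), mean, numeric(1))
    ssb <- sum(r$N_h * (ybar_h - mean(y))^2)
    expect_equal(r$SSW + ssb, r$SST, tolerance = 1e-10)
  }
})

test_that("refining a stratification never decreases q", {
  set.seed(73)
  for (i in 1:30) {
    N <- 40
    y <- rnorm(N)
    labels <- sample(1:3, N, replace = TRUE)
    q0 <- q_statistic(y, labels)$q
    # split stratum 1 arbitrarily in two
    refined <- labels
    in1 <- which(labels == 1)
    if (length(in1) >= 2) {
      refined[in1[seq_len(floor(length(in1) / 2))]] <- 4L
      expect_gte(q_statistic(y, refined)$q, q0 - 1e-12)
    }
  }
})

test_that("permutation significance is seeded, stable, and detects separation", {
  y <- c(1, 1.1, 0.9, 1.05, 5, 5.1, 4.9, 5.05)
  labels <- rep(1:2, each = 4)
  p1 <- q_significance(y, labels, B = 999, seed = 2)
  p2 <- q_significance(y, labels, B = 999, seed = 2)
  expect_identical(p1, p2)
  expect_lte(p1, 0.05)
  # no stratification, no effect
  expect_equal(q_significance(y, rep(1, 8)), 1)
  expect_error(q_significance(y, labels, B = 50), "at least 99")
})

test_that("noncentral-F significance agrees qualitatively with permutation", {
  set.seed(79)
  N <- 60
  y <- rnorm(N) + rep(c(0, 2), each = N / 2)
  labels <- rep(1:2, each = N / 2)
  pf_ <- q_significance(y, labels, method = "noncentral_f")
  pp <- q_significance(y, labels, method = "permutation", B = 999, seed = 3)
  expect_lt(pf_, 0.05)
  expect_lt(pp, 0.05)
  ynull <- rnorm(N)
  expect_gt(q_significance(ynull, labels, method = "noncentral_f"), 0.01)
})

test_that("the factor-detector table composes q, stars, and missing cells", {
  set.seed(83)
  n <- 40
  panel <- rbind(
    data.frame(unit_id = 1:n, year = 2000, f1 = rnorm(n), f2 = NA_real_),
    data.frame(unit_id = 1:n, year = 2010, f1 = rnorm(n), f2 = rnorm(n))
  )
  panel$response <- ifelse(is.na(panel$f2), panel$f1, panel$f2) + rnorm(2 * n, sd = 0.2)
  qt <- factor_detector(panel, "response", c("f1", "f2"), years = c(2000, 2010),
                        L = 4, B = 199, seed = 5)
  expect_equal(nrow(qt), 4)
  expect_true(is.na(qt$q[qt$factor == "f2" & qt$year == 2000]))  # "-" cell
  expect_false(anyNA(qt$q[qt$factor == "f1"]))
  # single factor, single year equals a direct q computation
  sub <- panel[panel$year == 2010, ]
  st <- discretize(sub$f2, L = 4)
  expect_equal(qt$q[qt$factor == "f2" & qt$year == 2010],
               q_statistic(sub$response, st)$q, tolerance = 1e-12)
  # wide view renders missing cells as "-"
  w <- q_table_wide(qt)
  expect_equal(w$f2[w$year == 2000], "-")
  # partial missingness is a unit-alignment error
  panel_bad <- panel
  panel_bad$f1[3] <- NA
  expect_error(factor_detector(panel_bad, "response", "f1", years = 2000, B = 199),
               "misaligned")
})

test_that("a factor explaining the response has q increasing in stratum count", {
  set.seed(89)
  n <- 100
  f <- rnorm(n)
  panel <- data.frame(unit_id = 1:n, year = 2000, f = f, response = f)
  qs <- vapply(c(2, 5, 10), function(L) {
    qt <- factor_detector(panel, "response", "f", years = 2000, L = L, B = 99, seed = 7)
    qt$q
  }, numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_gt(qs[2], 0.9)  # L = 5 quantile strata on a self-explaining factor
})
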