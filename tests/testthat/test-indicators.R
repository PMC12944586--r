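make_raw <- function(n = 4) {
  data.frame(
    unit_id = seq_len(n), year = 2000,
    area_km2 = 100, pop_total = 100, pop_urban = 60, pop_rural = 40,
    pop_employed = 40, gdp = 110, gdp_primary = 20, gdp_secondary = 60,
    gdp_tertiary = 30, grain_output_kg = 5e6, grain_sown_area_ha = 1000,
    income_urban = 20000, income_rural = 5000,
    fiscal_revenue = 50, fiscal_expenditure = 75,
    retail_sales = 40, fixed_asset_investment = 200
  )
}

test_that("indicators reproduce their defining ratios exactly", {
  ind <- compute_indicators(make_raw())
  expect_equal(ind$EPR[1], 0.4)          # 40 employed / 100 people
  expect_equal(ind$IR[1], 4.0)           # 20000 / 5000
  expect_equal(ind$IOR[1], 0.55)         # 110 / 200
  expect_equal(ind$IS[1], 0.5)           # 30 / 60
  expect_equal(ind$FR[1], 1.5)           # 75 / 50
  expect_equal(ind$PD[1], 1)             # 100 / 100 km2
  expect_equal(ind$GY[1], 5000)          # 5e6 kg / 1000 ha
  expect_equal(ind$PG[1], 1.1)
  expect_equal(ind$PC[1], 0.4)
  expect_equal(ind$PI[1], 2)
  expect_true(all(ind$EPR >= 0 & ind$EPR <= 1))
})

test_that("zero denominators exclude the record with a reason, not an error", {
  raw <- make_raw(3)
  raw$fiscal_revenue[2] <- 0
  expect_message(ind <- compute_indicators(raw), "excluded 1")
  expect_equal(nrow(ind), 2)
  exc <- attr(ind, "excluded")
  expect_equal(exc$unit_id, 2)
  expect_match(exc$reason, "fiscal revenue")
  raw$pop_total <- -1
  expect_error(compute_indicators(raw), "negative")
  expect_error(compute_indicators(raw[, -3]), "missing raw fields")
})

test_that("permanent cropland is the strict every-year conjunction", {
  g_all <- matrix(c(1, 1, 1, 5), 2, 2)          # 3 cropland cells
  g_one_off <- matrix(c(1, 4, 1, 5), 2, 2)      # cell 2 lapses one year
  lu <- manual_landuse(list(g_all, g_one_off, g_all), 1998:2000)
  m <- permanent_cropland_mask(lu, 1998:2000)
  expect_equal(sum(m), 2)
  expect_false(m[2, 1])
  # unchanging cropland: mask equals the year-one cropland map
  lu2 <- manual_landuse(list(g_all, g_all, g_all), 1998:2000)
  expect_equal(permanent_cropland_mask(lu2, 1998:2000), g_all == 1)
  expect_error(permanent_cropland_mask(lu, 1997:2000), "1997")
})

test_that("GRGR counts ever-converted permanent cropland over the zone base", {
  # 10 permanent cropland cells; 2 converted to forest by 2010
  base <- matrix(1L, 5, 2)
  conv <- base; conv[1, 1] <- 2L; conv[2, 1] <- 2L
  lu <- manual_landuse(list(base, base, conv, conv), c(1999, 2000, 2010, 2015))
  zones <- matrix(1L, 5, 2)
  g <- compute_grgr(lu, zones, years = c(2010, 2015),
                    baseline_years = c(1999, 2000), window = 2001:2020)
  expect_equal(g$grgr[g$year == 2010], 0.2)
  expect_equal(g$grgr[g$year == 2015], 0.2)
  # no conversions -> 0; all converted -> 1
  lu0 <- manual_landuse(list(base, base, base), c(1999, 2000, 2010))
  g0 <- compute_grgr(lu0, zones, years = 2010, baseline_years = c(1999, 2000),
                     window = 2001:2020)
  expect_equal(g0$grgr, 0)
  all_conv <- matrix(4L, 5, 2)
  lu1 <- manual_landuse(list(base, base, all_conv), c(1999, 2000, 2010))
  g1 <- compute_grgr(lu1, zones, years = 2010, baseline_years = c(1999, 2000),
                     window = 2001:2020)
  expect_equal(g1$grgr, 1)
})

test_that("GRGR is cumulative: reversion never decrements and it is monotone", {
  base <- matrix(1L, 4, 2)
  conv <- base; conv[1, 1] <- 2L
  revert <- base                     # converted cell reverts to cropland
  lu <- manual_landuse(list(base, conv, revert, revert), c(2000, 2005, 2010, 2015))
  zones <- matrix(1L, 4, 2)
  g <- compute_grgr(lu, zones, years = c(2005, 2010, 2015),
                    baseline_years = 2000, window = 2001:2020)
  expect_equal(g$grgr, rep(1 / 8, 3))   # ever-converted stays counted
  # monotonicity on a generated series, per unit
  lu2 <- generate_landuse_series(landuse_config(nrow = 12, ncol = 12,
                                                years = 1995:2020,
                                                baseline_years = 1995:2000),
                                 seed = 6)
  zones2 <- make_zone_grid(12, 12, 4)
  g2 <- compute_grgr(lu2, zones2, years = 2001:2020, baseline_years = 1995:2000,
                     window = 2001:2020)
  for (u in unique(g2$unit_id)) {
    gu <- g2$grgr[g2$unit_id == u][order(g2$year[g2$unit_id == u])]
    expect_true(all(diff(gu[!is.na(gu)]) >= 0))
  }
})

test_that("zones with an empty cropland base give NA with a message", {
  base <- matrix(c(1L, 1L, 5L, 5L), 2, 2)  # cropland only in zone 1 (column 1)
  zones <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  lu <- manual_landuse(list(base, base), c(2000, 2010))
  expect_message(
    g <- compute_grgr(lu, zones, years = 2010, baseline_years = 2000,
                      window = 2001:2020),
    "empty cropland base")
  expect_true(is.na(g$grgr[g$unit_id == 2]))
  expect_false(is.na(g$grgr[g$unit_id == 1]))
})

test_that("standardization is an invertible z-score and idempotent on z-scores", {
  g <- small_panel(n_units = 8, years = 2000:2005)
  std <- standardize_panel(g$panel, vars = c("response", "x1", "x2", "x3"))
  for (v in c("response", "x1", "x2", "x3")) {
    expect_equal(mean(std[[v]]), 0, tolerance = 1e-12)
    expect_equal(sd(std[[v]]), 1, tolerance = 1e-12)
  }
  # z of 7 under mean 5 sd 2 is 1
  std2 <- standardize_panel(data.frame(v = c(3, 5, 7)), "v")
  expect_equal(std2$v[3], 1)
  # round trip
  back <- unstandardize_panel(std)
  for (v in c("response", "x1", "x2", "x3"))
    expect_equal(back[[v]], g$panel[[v]], tolerance = 1e-10)
  # idempotence: standardizing a standardized panel changes nothing
  std3 <- standardize_panel(std, vars = c("response", "x1", "x2", "x3"))
  expect_equal(std3$response, std$response, tolerance = 1e-12)
  expect_error(standardize_panel(data.frame(v = rep(1, 5)), "v"), "'v'")
})
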