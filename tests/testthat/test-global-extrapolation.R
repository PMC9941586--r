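# production-vs-PIC regression, spherical integration, low-PIC minimum and
# unit conversions

R_EARTH <- 6371e3

test_that("noise-free station sets recover the regression coefficients exactly", {
  x <- c(0, 10, 50, 100, 300)
  fit <- fit_pic_regression(0.65 + 0.03 * x, x)
  expect_equal(fit$intercept, 0.65, tolerance = 1e-12)
  expect_equal(fit$slope, 0.03, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$std_error, 0, tolerance = 1e-9)
  expect_equal(unname(coef(fit)), c(0.65, 0.03))
})

test_that("degenerate regressions are rejected or flagged", {
  expect_error(fit_pic_regression(c(1, 2), c(1, 2)), "3 stations")
  expect_error(fit_pic_regression(c(1, 2, 3), c(5, 5, 5)), "variance")
  expect_warning(fit <- fit_pic_regression(c(2, 2, 2, 2), c(1, 2, 3, 4)),
                 "constant")
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
})

test_that("noisy synthetic stations recover coefficients at nominal CI coverage", {
  # five stations leave 3 residual df, so calibration uses exact t-intervals
  # (2-SE bands undercover badly at this sample size)
  x <- c(2, 5, 8, 20, 80)
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    y <- 0.65 + 0.03 * x + rnorm(5, 0, 0.3)
    fit <- fit_pic_regression(y, x)
    ci <- confint(fit$lm)
    if (0.65 >= ci[1, 1] && 0.65 <= ci[1, 2] &&
        0.03 >= ci[2, 1] && 0.03 <= ci[2, 2]) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
})

test_that("spherical cell areas sum to the area of the sphere", {
  for (step in c(1, 2, 5)) {
    lat <- seq(-90 + step / 2, 90 - step / 2, by = step)
    lon <- seq(-180 + step / 2, 180 - step / 2, by = step)
    g <- pic_grid(lat, lon, matrix(1, length(lat), length(lon)))
    expect_equal(sum(cell_areas(g)), 4 * pi * R_EARTH^2,
                 tolerance = 1e-6)
  }
})

test_that("uniform-field global integration equals the closed form", {
  lat <- seq(-89, 89, by = 2); lon <- seq(-179, 179, by = 2)
  p <- 7
  g <- pic_grid(lat, lon, matrix(p, length(lat), length(lon)))
  fit <- list(intercept = 0.65, slope = 0.03)
  res <- integrate_global(g, fit)
  expect_equal(res$total_mol_yr, (0.65 + 0.03 * p) * 4 * pi * R_EARTH^2,
               tolerance = 1e-9)
  expect_equal(res$total_pg_c_yr, res$total_mol_yr * 12.011 / 1e15)
  # linear in the regression coefficients
  res2 <- integrate_global(g, list(intercept = 1.3, slope = 0.06))
  expect_equal(res2$total_mol_yr, 2 * res$total_mol_yr, tolerance = 1e-9)
})

test_that("two-band grids integrate to the hand-computed sum and masks work", {
  lat <- seq(-89, 89, by = 2); lon <- seq(-179, 179, by = 2)
  vals <- matrix(5, length(lat), length(lon))
  vals[abs(lat) > 60, ] <- 80
  g <- pic_grid(lat, lon, vals)
  area <- cell_areas(g)
  a1 <- sum(area[abs(lat) <= 60, ]); a2 <- sum(area[abs(lat) > 60, ])
  fit <- list(intercept = 0.65, slope = 0.03)
  expect_equal(integrate_global(g, fit)$total_mol_yr,
               (0.65 + 0.03 * 5) * a1 + (0.65 + 0.03 * 80) * a2,
               tolerance = 1e-9)
  g_land <- pic_grid(lat, lon, vals, mask = matrix(FALSE, length(lat), length(lon)))
  expect_warning(res <- integrate_global(g_land, fit), "empty")
  expect_equal(res$total_mol_yr, 0)
})

test_that("negative predictions are floored at zero before integration", {
  lat <- seq(-89, 89, by = 2); lon <- seq(-179, 179, by = 2)
  g <- pic_grid(lat, lon, matrix(1, length(lat), length(lon)))
  res <- integrate_global(g, list(intercept = -5, slope = 0.03))
  expect_equal(res$total_mol_yr, 0)
})

test_that("low-PIC fraction and minimum estimate follow the area accounting", {
  lat <- seq(-89, 89, by = 2); lon <- seq(-179, 179, by = 2)
  g_all <- pic_grid(lat, lon, matrix(2, length(lat), length(lon)))
  expect_equal(low_pic_minimum(g_all)$fraction, 1)
  expect_equal(low_pic_minimum(g_all, threshold_mg_m3 = Inf)$fraction, 1)
  vals <- matrix(5, length(lat), length(lon))
  vals[abs(lat) > 60, ] <- 80
  g <- pic_grid(lat, lon, vals)
  res <- low_pic_minimum(g, 10, station_rates_mol_m2_yr = c(0.2, 1.0))
  area <- cell_areas(g)
  frac_oracle <- sum(area[abs(lat) <= 60, ]) / sum(area)
  expect_equal(res$fraction, frac_oracle, tolerance = 1e-12)
  expect_equal(res$estimates_mol_yr,
               frac_oracle * sum(area) * c(0.2, 1.0), tolerance = 1e-9)
  expect_equal(res$mean_estimate_mol_yr, mean(res$estimates_mol_yr))
})

test_that("unit conversions match molar masses and round-trip", {
  expect_equal(convert_units(3.1e14, "mol_to_PgC"), 3.72, tolerance = 0.002)
  expect_equal(convert_units(0.8, "mmolCaCO3_to_mg"), 80.07, tolerance = 1e-3)
  expect_equal(convert_units(0, "mol_to_PgC"), 0)
  x <- 123.4
  expect_equal(convert_units(convert_units(x, "mgCaCO3_to_mol") * 1e3,
                             "mmolCaCO3_to_mg"), x, tolerance = 1e-12)
  expect_error(convert_units(1, "furlongs"), "arg")
})
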