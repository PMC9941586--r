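# synthetic-data generators: reproducibility and ground-truth calibration

small_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_stations = 3,
               latitudes = c(25, 38, 50),
               total_stock_mg_m2 = c(700, 1700, 4500), ...)
}

test_that("generators are bit-reproducible given (seed, config)", {
  a <- gen_station_survey(small_cfg(5))
  b <- gen_station_survey(small_cfg(5))
  expect_identical(a, b)
  expect_identical(gen_maredat_like(small_cfg(5)),
                   gen_maredat_like(small_cfg(5)))
  expect_identical(gen_pic_climatology(small_cfg(5)),
                   gen_pic_climatology(small_cfg(5)))
  expect_identical(gen_trap_fluxes(small_cfg(5), c(0.4, 0.7, 1.0)),
                   gen_trap_fluxes(small_cfg(5), c(0.4, 0.7, 1.0)))
  # different seed, different draws
  expect_false(identical(a, gen_station_survey(small_cfg(6))))
})

test_that("realized survey stocks match the configured truth closely", {
  sv <- gen_station_survey(small_cfg(2))
  for (tr in sv$truth) {
    # heteropods are excluded: their stock is a handful of individuals, so
    # single-shell granularity dominates (the truth record carries the
    # realized value either way)
    for (tx in c("coccolithophore", "pteropod", "foraminifera")) {
      expect_equal(tr$realized[[tx]], tr$configured[[tx]], tolerance = 0.1,
                   label = sprintf("station %d %s", tr$station, tx))
    }
    expect_gte(tr$realized$heteropod, 0)
  }
})

test_that("probabilistic shell rounding hits the configured stock in expectation", {
  # heteropod stocks are a few shells per tow; over many seeds the mean
  # realized stock should approach the configured target
  vals <- vapply(1:40, function(s) {
    cfg <- synth_config(seed = s, n_stations = 1, latitudes = 30,
                        total_stock_mg_m2 = 700)
    tr <- gen_station_survey(cfg)$truth[[1]]
    c(tr$realized$heteropod, tr$configured$heteropod)
  }, c(0, 0))
  expect_equal(mean(vals[1, ]) / mean(vals[2, ]), 1, tolerance = 0.35)
})

test_that("zero stocks produce empty tows", {
  cfg <- synth_config(seed = 3, n_stations = 1, latitudes = 30,
                      total_stock_mg_m2 = 0)
  sv <- gen_station_survey(cfg)
  expect_equal(nrow(sv$stations[[1]]$shells), 0)
  expect_equal(sum(sv$stations[[1]]$filters$coccosphere_count), 0)
  expect_equal(sv$truth[[1]]$realized$pteropod, 0)
})

test_that("biomass compilations carry the configured zero fraction and skew", {
  cfg <- synth_config(seed = 4, maredat_n = 5000)
  mar <- gen_maredat_like(cfg)
  z <- mean(mar$records$mg_C_m3 == 0)
  # binomial check on ~7% zero inflation
  expect_equal(z, 0.067, tolerance = 0.2)
  expect_gt(mar$truth$skewness_in_layer, 1)  # heavily skewed by construction
})

test_that("planted outliers are removed by the preprocess stage", {
  cfg <- synth_config(seed = 9, maredat_n = 2000, n_outliers = 3)
  mar <- gen_maredat_like(cfg)
  pre <- maredat_preprocess(mar$records$mg_C_m3, mar$records$depth_m)
  expect_gte(pre$n_outliers_removed, 3)
  expect_lt(max(pre$values), max(mar$truth$outlier_values))
})

test_that("the climatology encodes its low-PIC fraction and seasonality truth", {
  cfg <- small_cfg(7)
  clim <- gen_pic_climatology(cfg)
  # realized fraction matches configuration to within one grid cell
  expect_equal(clim$truth$low_fraction_realized, 0.87, tolerance = 0.001)
  res <- low_pic_minimum(clim$grid, 10)
  expect_equal(res$fraction, clim$truth$low_fraction_realized, tolerance = 1e-12)
  # August/annual ratio at a mid-latitude full-retrieval cell equals the
  # configured seasonal cycle
  i <- which.min(abs(clim$grid$lat - 50))
  amp <- cfg$seasonal_amp_high * (50 - 20) / 70
  expect_equal(clim$grid$values[i, 1, 8] / clim$grid$annual[i, 1], 1 + amp,
               tolerance = 0.01)
  # uniform grid: bias factor 1 everywhere
  flat <- pic_grid(seq(-89, 89, 2), seq(-179, 179, 2),
                   array(5, c(90, 180, 12)))
  expect_true(all(abs(flat$values[, , 8] / flat$annual - 1) < 1e-12))
})

test_that("trap fluxes recover the configured export efficiency", {
  cfg <- small_cfg(8)  # zero trap noise by default
  prod <- c(0.4, 0.7, 1.0)
  tr <- gen_trap_fluxes(cfg, prod)
  eff <- export_efficiency(prod[1], tr$flux_mol_m2_yr[1])
  expect_equal(eff$exported_pct, 20, tolerance = 1e-12)
  # efficiency 1: flux equals production
  cfg1 <- small_cfg(8, export_efficiency_true = 1)
  expect_equal(gen_trap_fluxes(cfg1, prod)$flux_mol_m2_yr, prod)
  # aragonite fraction decreases northwards
  expect_true(all(diff(tr$aragonite_fraction) < 0))
})
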