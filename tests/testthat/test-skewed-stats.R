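# compilation statistics: filtering, uncertain-fPIC conversion, truncated
# KDE, skewness and the bootstrap/Monte-Carlo pipeline

test_that("preprocess keeps zeros, filters depth inclusively and removes outliers once", {
  # brute-force oracle: outliers are |x - mean| > 3 sd on the filtered sample
  v <- c(rep(0.2, 50), rep(0.4, 45), 0, 0, 0, 250)
  keep_oracle <- abs(v - mean(v)) <= 3 * sd(v)
  pre <- maredat_preprocess(v)
  expect_equal(pre$n_outliers_removed, sum(!keep_oracle))
  expect_gt(pre$n_outliers_removed, 0)
  expect_equal(sort(pre$values), sort(v[keep_oracle]))
  expect_equal(pre$n_zeros, 3)
  # all-zero sample: sd = 0, nothing removed
  pre0 <- maredat_preprocess(rep(0, 10))
  expect_equal(pre0$n_outliers_removed, 0)
  expect_equal(pre0$n_used, 10)
  # depth boundary is inclusive at 250 m
  pre_d <- maredat_preprocess(c(1, 2, 3), depth_m = c(100, 250, 251))
  expect_equal(pre_d$values, c(1, 2))
  expect_equal(pre_d$n_depth_excluded, 1)
  expect_error(maredat_preprocess(c(1, 2), depth_m = c(300, 400)), "depth")
})

test_that("small samples cannot trip the 3-sigma rule (bounded z-scores)", {
  # for n = 5 the max |z| is (n-1)/sqrt(n) < 3, so nothing is ever removed
  pre <- maredat_preprocess(c(0, 1, 2, 3, 10000))
  expect_equal(pre$n_outliers_removed, 0)
})

test_that("carbon to CaCO3 uses fPIC = r/(1+r) and the 8.33 mass ratio", {
  r0 <- 0.27 / 0.73
  cc <- carbon_to_caco3_mc(1, c(r0, r0), n = 3, seed = 1)
  expect_equal(unname(cc$fpic), rep(0.27, 3), tolerance = 1e-12)
  expect_equal(as.vector(cc$caco3), rep(0.27 * 8.33, 3), tolerance = 1e-12)
  expect_true(all(carbon_to_caco3_mc(0, c(0.2, 0.56), 10, 1)$caco3 == 0))
  # endpoint transform of the pteropod ratio range
  cc2 <- carbon_to_caco3_mc(1, c(0.20, 0.56), n = 5e4, seed = 2)
  expect_gte(min(cc2$fpic), 0.20 / 1.20)
  expect_lte(max(cc2$fpic), 0.56 / 1.56)
  expect_equal(range(cc2$fpic), c(0.1667, 0.3590), tolerance = 1e-3)
})

test_that("layer integration is plain thickness scaling", {
  expect_equal(layer_integrate(0.5), 125)
  expect_equal(layer_integrate(0), 0)
  expect_equal(layer_integrate(0.5, 1000), 4 * layer_integrate(0.5, 250))
})

test_that("truncated KDE integrates to 1, handles point masses and recovers a lognormal median", {
  set.seed(5)
  for (v in list(rlnorm(200, 0, 1), c(rep(0, 30), rexp(100)), runif(50, 0, 4))) {
    k <- truncated_kde(v)
    expect_true(all(k$density >= 0))
    integral <- pracma::trapz(k$x, k$density)
    expect_equal(integral, 1, tolerance = 1e-6)
  }
  k7 <- truncated_kde(rep(7, 100))
  expect_equal(unname(k7$percentiles), c(7, 7, 7))
  expect_equal(k7$mode, 7)
  set.seed(11)
  kl <- truncated_kde(rlnorm(1e4, 0, 1))
  expect_equal(unname(kl$percentiles[["p50"]]), 1, tolerance = 0.05)
  expect_error(truncated_kde(c(-1, 1, 2, 3, 4)), ">= 0")
})

test_that("sample skewness matches moment oracles", {
  expect_equal(sample_skewness(c(0, 1, 2)), 0)
  expect_equal(sample_skewness(c(0, 0, 0, 1)), 2 * sqrt(3) / 3, tolerance = 1e-9)
  set.seed(3)
  expect_equal(sample_skewness(rexp(1e6)), 2, tolerance = 0.025)
  expect_true(is.na(sample_skewness(rep(2, 5))))
  # bias-corrected variant
  v <- c(0, 0, 0, 1)
  expect_equal(sample_skewness(v, corrected = TRUE),
               sample_skewness(v) * sqrt(4 * 3) / 2, tolerance = 1e-12)
})

test_that("pipeline with degenerate priors equals the closed form exactly", {
  set.seed(8)
  v <- runif(60, 0.1, 2)  # no 3-sigma outliers, so preprocess is the identity
  params <- list(pic_poc_range = c(0.27 / 0.73, 0.27 / 0.73),
                 turnover_range = c(8, 8))
  res <- maredat_pipeline(v, params = params, n_boot = 1, seed = 4)
  expect_equal(res$first_pass$caco3, v * 0.27 * 8.33, tolerance = 1e-12)
  expect_equal(res$first_pass$production, v * 250 * 0.27 * 8.33 / 8,
               tolerance = 1e-12)
  # stock/production KDE percentiles are exact rescalings of the biomass ones
  p <- res$statistics
  expect_equal(p$stock_mg_m2$point, p$biomass_caco3_mg_m3$point * 250,
               tolerance = 1e-12)
  expect_equal(p$production_mg_m2_d$point, p$stock_mg_m2$point / 8,
               tolerance = 1e-12)
})

test_that("pipeline percentiles are equivariant under unit rescaling", {
  set.seed(9)
  v <- c(rep(0, 5), rlnorm(80, -1, 1))
  params <- list(pic_poc_range = c(0.2, 0.56), turnover_range = c(5, 16))
  a <- maredat_pipeline(v, params = params, n_boot = 5, seed = 6)
  b <- maredat_pipeline(v * 10, params = params, n_boot = 5, seed = 6)
  expect_equal(b$statistics$biomass_caco3_mg_m3$point,
               a$statistics$biomass_caco3_mg_m3$point * 10, tolerance = 1e-8)
})

test_that("bootstrap intervals cover generator truth at roughly nominal rate", {
  # calibration over repeated synthetic datasets: the 95% bootstrap interval
  # on the KDE median should contain the zero-inflated lognormal median
  covered <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    set.seed(1000 + i)
    v <- rlnorm(150, 0, 0.8)
    v[runif(150) < 0.05] <- 0
    params <- list(pic_poc_range = c(0.27 / 0.73, 0.27 / 0.73),
                   turnover_range = c(8, 8))
    res <- maredat_pipeline(v, params = params, n_boot = 60, seed = i)
    truth <- qlnorm((0.5 - 0.05) / 0.95, 0, 0.8) * 0.27 * 8.33
    ci <- res$statistics$biomass_caco3_mg_m3$boot[c(1, 3)]
    if (truth >= ci[1] && truth <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.8)
})
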