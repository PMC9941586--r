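# shell-length allometry, carbon chain, filter-count and picked-weight
# conversions

pteropod_ratio <- 0.27 / 0.73

test_that("carbon chain reproduces hand-computed per-individual masses", {
  # Cavoliniidae wet-weight power law through the full chain
  ww <- 0.2152 * 1^2.293
  expect_equal(shell_caco3("Cavoliniidae", 1),
               ww * 0.28 * 0.25 * pteropod_ratio * 8.33, tolerance = 1e-12)
  # Limacinidae enters the chain at dry weight
  dw <- 0.1365 * 2^1.501
  expect_equal(shell_caco3("Limacinidae", 2),
               dw * 0.25 * pteropod_ratio * 8.33, tolerance = 1e-12)
  expect_equal(signif(shell_caco3("Limacinidae", 2), 4), 0.2976)
  # Carinidae uses the heteropod PIC:POC midpoint
  expect_equal(shell_caco3("Carinidae", 2),
               0.0888 * 2^2.161 * 0.28 * 0.25 * 0.365 * 8.33, tolerance = 1e-12)
  # Atlantidae exponential ash-weight fit bypasses the chain
  expect_equal(shell_caco3("Atlantidae", 1000), 0.769 * exp(0.0023 * 1000),
               tolerance = 1e-12)
  expect_equal(shell_caco3("Atlantidae", 1000, atlantidae_length_scale = 1e-3),
               0.769 * exp(0.0023), tolerance = 1e-12)
})

test_that("tiny Cymbuliidae juveniles are clamped to zero with a warning", {
  expect_warning(out <- shell_caco3("Cymbuliidae", 0.05), "clamped")
  expect_identical(out, 0)
  # above the fit support the linear chain applies unclamped
  expect_equal(shell_caco3("Cymbuliidae", 2),
               (0.0392 * 2 - 0.003) * 0.25 * pteropod_ratio * 8.33,
               tolerance = 1e-12)
})

test_that("invalid shell inputs are rejected", {
  expect_error(shell_caco3("Cavoliniidae", 0), "length")
  expect_error(shell_caco3("Cavoliniidae", -1), "length")
  expect_error(shell_caco3("Nautilidae", 1), "unknown family")
})

test_that("per-individual CaCO3 is increasing, finite and non-negative over (0, 50] mm", {
  L <- seq(0.01, 50, length.out = 400)
  for (fam in c("Cavoliniidae", "Carinidae", "Limacinidae", "Atlantidae")) {
    m <- shell_caco3(fam, L)
    expect_true(all(is.finite(m)) && all(m >= 0), label = fam)
    expect_true(all(diff(m) > 0), label = paste(fam, "monotone"))
  }
  m <- suppressWarnings(shell_caco3("Cymbuliidae", L))
  expect_true(all(is.finite(m)) && all(m >= 0))
  expect_true(all(diff(m) >= 0))
})

test_that("chain factorization: CaCO3/WW is a single constant for wet-weight families", {
  const <- 0.28 * 0.25 * pteropod_ratio * 8.33
  L <- c(0.3, 1, 3, 10)
  ww <- 0.2152 * L^2.293
  expect_equal(shell_caco3("Cavoliniidae", L) / ww, rep(const, 4),
               tolerance = 1e-12)
})

test_that("filter-count concentration follows F*C/(A*V) and its homogeneity", {
  expect_equal(cocco_concentration(50, 1000, 0.35, 2.1), 1000 * 50 / (0.35 * 2.1))
  expect_equal(cocco_concentration(0, 1000, 0.35, 2.1), 0)
  expect_equal(cocco_concentration(7, 500, 500, 1), 7)  # A = F identity
  base <- cocco_concentration(40, 800, 1.2, 3)
  expect_equal(cocco_concentration(80, 800, 1.2, 6), base)   # 2C, 2V
  expect_equal(cocco_concentration(40, 1600, 1.2, 3) / base, 2)  # 2F doubles
  expect_error(cocco_concentration(5, 1000, 0, 2), "A")
  expect_error(cocco_concentration(5, 1000, 0.4, 0), "V")
  expect_error(cocco_concentration(5, 100, 200, 2), "exceeds")
})

test_that("coccolithophore calcite conversion handles both count modes and units", {
  tb <- coccolith_mass_table("sp", 20, 2.5)
  expect_equal(cocco_caco3(1000, "sp", tb, "coccosphere"), 0.05)
  expect_equal(cocco_caco3(0, "sp", tb, "coccosphere"), 0)
  expect_equal(cocco_caco3(1e6, "sp", tb, "loose_coccolith"), 2.5)
  expect_error(cocco_caco3(1, "missing_species", tb), "missing_species")
})

test_that("foraminiferal picked weights scale by split fraction", {
  expect_equal(foram_caco3(5, 0.5), 10)
  expect_equal(foram_caco3(numeric(0), numeric(0)), 0)
  expect_equal(foram_caco3(c(3, 1), c(0.25, 0.25)), 16)
  expect_error(foram_caco3(1, 0), "split_fraction")
  expect_error(foram_caco3(1, 1.2), "split_fraction")
})

test_that("a coccolith mass table round-trips through its YAML config", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("Emiliania huxleyi:",
               "  coccoliths_per_sphere: 20",
               "  coccolith_mass_pg: 2.5",
               "Coccolithus pelagicus:",
               "  coccoliths_per_sphere: 12",
               "  coccolith_mass_pg: 70"), path)
  tb <- read_coccolith_table(path)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$coccolith_mass_pg[tb$species == "Coccolithus pelagicus"], 70)
  # the shipped synthetic example table parses too
  shipped <- read_coccolith_table(
    system.file("extdata", "coccolith_masses_synthetic.yml",
                package = "pelagicarb"))
  expect_gte(nrow(shipped), 3)
  expect_true(all(shipped$coccolith_mass_pg > 0))
})
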