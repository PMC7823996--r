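# Generator ground truth: planted trend counts, zero-noise determinism,
# isotope chemistry and the compound/pathway fixtures.

test_that("formula parsing reproduces monoisotopic masses", {
  # frozen oracle values: sums of IUPAC monoisotopic atomic masses
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("C3H6O3"), 90.03169, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("C6H12O6"), 180.06339, tolerance = 1e-5)
  expect_identical(parse_formula("C3H6O3"),
                   c(C = 3L, H = 6L, O = 3L))
  expect_error(parse_formula("C3X2"), "unknown element")
  expect_error(parse_formula("c3h6"), "malformed|unknown")
})

test_that("isotope ratio follows the binomial 13C model", {
  expect_equal(isotope_ratio(20, 1), 20 * 0.0107 / (1 - 0.0107))
  expect_equal(isotope_ratio(20, 1), 0.216, tolerance = 2e-3)
  # monotone in n_carbons; below 1 up to 92 carbons
  ratios <- isotope_ratio(1:92, 1)
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios < 1))
})

test_that("planted trend counts follow frac_trend exactly", {
  g0 <- generate_feature_table(n_features = 100, frac_trend = 0,
                               noise_cv = 0.1, seed = 1)
  expect_identical(sum(g0$truth$features$trend_class != "flat"), 0L)

  g <- generate_feature_table(n_features = 200, frac_trend = 0.5,
                              noise_cv = 0.1, seed = 7)
  expect_identical(sum(g$truth$features$trend_class != "flat"), 100L)
  expect_identical(dim(g$table), c(200L, 9L * 3L + 3L))
})

test_that("zero-noise tables respect the planted trend shapes", {
  g <- generate_feature_table(n_features = 50, frac_trend = 0.5,
                              noise_cv = 0, seed = 3)
  tr <- g$truth$features
  tab <- ft_drop_blanks(g$table)
  tp <- sort(unique(tab$samples$time_h))
  means_at <- function(i) {
    vapply(tp, function(t) {
      mean(tab$intensity[i, tab$samples$time_h == t])
    }, numeric(1))
  }
  up <- which(tr$trend_class == "monotone_up")
  for (i in up) expect_true(all(diff(means_at(i)) > 0))
  down <- which(tr$trend_class == "monotone_down")
  for (i in down) expect_true(all(diff(means_at(i)) < 0))
  flat <- which(tr$trend_class == "flat")
  for (i in flat[1:5]) {
    expect_equal(diff(range(tab$intensity[i, ])), 0, tolerance = 1e-9)
  }
})

test_that("same seed regenerates identical tables and spectra", {
  a <- generate_feature_table(n_features = 40, seed = 5)
  b <- generate_feature_table(n_features = 40, seed = 5)
  expect_identical(a$table$intensity, b$table$intensity)
  expect_identical(a$truth$features, b$truth$features)
  sa <- generate_fia_spectra(a$truth, seed = 5)
  sb <- generate_fia_spectra(b$truth, seed = 5)
  expect_identical(sa[[1]]$mz, sb[[1]]$mz)
  expect_identical(sa[[10]]$intensity, sb[[10]]$intensity)
})

test_that("spectra carry drift, tune mix and isotope peaks as planted", {
  g <- generate_feature_table(n_features = 20, frac_trend = 0,
                              noise_cv = 0, seed = 2)
  # zero drift: observed equals true for the tune mix
  sp0 <- generate_fia_spectra(g$truth, drift = c(0, 0, 0), noise_cv = 0,
                              seed = 2)[[1]]
  for (r in default_tune_mix()) {
    expect_true(min(abs(sp0$mz - r)) < 1e-9)
  }
  # constant offset drift: tune-mix peak displaced by exactly the offset
  sp1 <- generate_fia_spectra(g$truth, drift = c(0.001, 0, 0), noise_cv = 0,
                              seed = 2)[[1]]
  expect_true(min(abs(sp1$mz - 322.04912)) < 1e-8)
  # isotope intensity ratio matches the binomial model at zero noise
  f <- g$truth$features[1, ]
  i_mono <- which.min(abs(sp0$mz - f$true_mz))
  i_plus1 <- which.min(abs(sp0$mz - (f$true_mz + 1.00335)))
  expect_equal(sp0$intensity[i_plus1] / sp0$intensity[i_mono],
               isotope_ratio(f$n_carbons, 1), tolerance = 1e-9)
  expect_true(length(sp0$mz) >= 1000)
})

test_that("spectra generation validates its preconditions", {
  g <- generate_feature_table(n_features = 10, seed = 1)
  expect_error(generate_fia_spectra(g$truth, tune_mix = c(100, 200)),
               "at least 3")
  expect_error(generate_fia_spectra(g$truth, drift = c(0, NA, 0)), "finite")
})

test_that("compound db and pathways carry the planted structure", {
  db <- generate_compound_db(40, seed = 1)
  expect_identical(nrow(db), 40L)
  expect_equal(db$monoisotopic_mass, monoisotopic_mass(db$formula))
  pw <- generate_pathways(db, n_sets = 5, set_size = 6,
                          planted_members = db$compound_id[1:6], seed = 1)
  expect_identical(length(pw$pathways), 5L)
  expect_identical(pw$pathways[[pw$planted]], db$compound_id[1:6])
  expect_identical(sum(names(pw$pathways) == pw$planted), 1L)
  expect_error(
    generate_pathways(db, planted_members = "NOPE", seed = 1),
    "present in the compound database"
  )
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_feature_table(n_features = 0), "n_features")
  expect_error(generate_feature_table(frac_trend = 1.2), "frac_trend")
  expect_error(generate_feature_table(noise_cv = -0.1), "noise_cv")
})
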