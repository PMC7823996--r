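# FIA MS1 processing stages, each against constructed spectra with known
# answers.

drifted_spec <- function(true_mz, intensity, drift) {
  spec1(true_mz + drift[1] + drift[2] * true_mz + drift[3] * true_mz^2,
        intensity)
}

test_that("recalibration recovers planted quadratic drift exactly", {
  refs <- default_tune_mix()
  drift <- c(2e-3, 5e-6, 1e-9)
  sp <- drifted_spec(c(refs, 500.123), c(rep(1e6, 5), 1e4), drift)
  cal <- fit_mass_recalibration(sp, refs)
  expect_lt(max(abs(cal$coefficients - drift)), 1e-9)
  expect_lt(max(abs(cal$residuals)), 1e-9)
  cor <- apply_recalibration(sp, cal)
  expect_lt(max(abs(cor$mz - sort(c(refs, 500.123)))), 1e-9)
})

test_that("zero drift yields the identity calibration", {
  refs <- default_tune_mix()
  sp <- spec1(c(refs, 300.5), c(rep(1e6, 5), 1e4))
  cal <- fit_mass_recalibration(sp, refs)
  expect_lt(max(abs(cal$coefficients)), 1e-12)
  cor <- apply_recalibration(sp, cal)
  expect_equal(cor$mz, sp$mz, tolerance = 1e-12)
})

test_that("recalibration is idempotent on noise-free drift", {
  refs <- default_tune_mix()
  sp <- drifted_spec(c(refs, 150.1, 700.7), c(rep(1e6, 5), 1e4, 1e4),
                     c(1e-3, 2e-6, 5e-10))
  cor1 <- apply_recalibration(sp, fit_mass_recalibration(sp, refs))
  cor2 <- apply_recalibration(cor1, fit_mass_recalibration(cor1, refs))
  expect_lt(max(abs(cor2$mz - cor1$mz)), 1e-9)
})

test_that("recalibration fails loudly with fewer than 3 matched references", {
  sp <- spec1(c(112.98559, 322.04812, 500), c(1e6, 1e6, 1e4))
  expect_error(fit_mass_recalibration(sp, default_tune_mix()),
               ">= 3 matched references")
  # the unmatched references are named in the message
  expect_error(fit_mass_recalibration(sp, default_tune_mix()), "622.029")
})

test_that("reference normalization divides by the summed reference signal", {
  refs <- c(100, 200)
  sp <- spec1(c(100, 200, 300), c(400, 600, 500))
  norm <- normalize_by_reference(sp, refs)
  expect_equal(norm$intensity, c(0.4, 0.6, 0.5))
  # scale invariance: a globally x2 spectrum normalizes identically
  sp2 <- spec1(sp$mz, sp$intensity * 2)
  expect_equal(normalize_by_reference(sp2, refs)$intensity, norm$intensity)
  expect_error(normalize_by_reference(spec1(300, 1), refs),
               "no reference peak")
})

test_that("top-peak detection keeps the n most intense, lower m/z on ties", {
  sp <- spec1(c(10, 20, 30, 40, 50), c(5, 3, 9, 1, 7))
  top <- detect_top_peaks(sp, 3)
  expect_equal(top$mz, c(10, 30, 50))
  # tie at rank n: the lower m/z wins
  tie <- spec1(c(10, 20, 30), c(5, 1, 1))
  expect_equal(detect_top_peaks(tie, 2)$mz, c(10, 20))
  # degenerate inputs
  expect_equal(detect_top_peaks(sp, 100)$mz, sp$mz)
  empty <- spec1(numeric(0), numeric(0))
  expect_identical(length(detect_top_peaks(empty, 3)$mz), 0L)
})

test_that("consensus clustering merges within tolerance only", {
  mk <- function(id, mz, i) spec1(mz, i, id = id)
  same <- build_consensus_features(
    list(mk("a", 200.0000, 10), mk("b", 200.0000, 20), mk("c", 200.0000, 30)),
    tol_ppm = 5)
  expect_identical(nrow(same), 1L)
  expect_identical(same$n_samples, 3L)

  apart <- build_consensus_features(
    list(mk("a", c(200.0000, 200.0100), c(10, 10))), tol_ppm = 5)
  expect_identical(nrow(apart), 2L)

  close <- build_consensus_features(
    list(mk("a", 200.0000, 100), mk("b", 200.0005, 300)), tol_ppm = 5)
  expect_identical(nrow(close), 1L)
  # intensity-weighted mean, computed independently
  expect_equal(close$mz, (200.0000 * 100 + 200.0005 * 300) / 400,
               tolerance = 1e-12)
})

test_that("gap filling recovers sub-threshold raw signal and fills zeros", {
  sm <- data.frame(sample_id = c("a", "b"), time_h = c(0, 0),
                   replicate = 1:2, is_blank = FALSE)
  # sample b's peak at 400 is below its top-2 detection threshold
  raw <- list(spec1(c(300, 400), c(100, 50), id = "a"),
              spec1(c(300, 400, 500), c(80, 10, 60), id = "b"))
  peaks <- lapply(raw, detect_top_peaks, n = 2)
  cons <- build_consensus_features(peaks, tol_ppm = 5)
  tab <- fill_gaps(raw, cons, sm, tol_ppm = 5)
  i400 <- which.min(abs(tab$features$mz - 400))
  expect_equal(unname(tab$intensity[i400, "b"]), 10)   # recovered from raw
  i500 <- which.min(abs(tab$features$mz - 500))
  expect_equal(unname(tab$intensity[i500, "a"]), 0)    # truly absent
  expect_false(anyNA(tab$intensity))
})

test_that("isotope collapsing respects spacing and plausible ratios", {
  mk_tab <- function(mz, X) tiny_table(X, time_h = c(0, 0, 0), mz = mz)
  # exact spacing, carbon-plausible ratio: collapsed, intensities summed
  t1 <- mk_tab(c(200.00000, 201.00335),
               rbind(c(100, 110, 90), c(11, 12, 10)))
  c1 <- collapse_isotopes(t1)
  expect_identical(nrow(c1$intensity), 1L)
  expect_equal(unname(c1$intensity[1, ]), c(111, 122, 100))
  expect_identical(c1$features$n_collapsed, 1L)
  # implausible ratio 3.0: not collapsed
  t2 <- mk_tab(c(200.00000, 201.00335),
               rbind(c(100, 100, 100), c(300, 300, 300)))
  expect_identical(nrow(collapse_isotopes(t2)$intensity), 2L)
  # three-member chain with a 30-carbon ratio structure: head keeps count 2
  r1 <- isotope_ratio(30, 1); r21 <- isotope_ratio(30, 2) / r1
  t3 <- mk_tab(c(300, 300 + 1.00335, 300 + 2 * 1.00335),
               rbind(c(1000, 1000, 1000), c(1000, 1000, 1000) * r1,
                     c(1000, 1000, 1000) * r1 * r21))
  c3 <- collapse_isotopes(t3)
  expect_identical(nrow(c3$intensity), 1L)
  expect_identical(c3$features$n_collapsed, 2L)
})

test_that("collapse conserves per-sample total intensity", {
  g <- generate_feature_table(n_features = 60, seed = 9)
  sp <- generate_fia_spectra(g$truth, seed = 9)
  tab <- fia_process(sp, g$truth$design$samples, collapse = FALSE)
  col <- collapse_isotopes(tab)
  rel <- abs(colSums(col$intensity) - colSums(tab$intensity)) /
    colSums(tab$intensity)
  expect_lt(max(rel), 1e-9)
})

test_that("sample order does not change consensus m/z or collapse chains", {
  g <- generate_feature_table(n_features = 40, seed = 4)
  sp <- generate_fia_spectra(g$truth, seed = 4)
  sm <- g$truth$design$samples
  t1 <- fia_process(sp, sm)
  perm <- rev(seq_along(sp))
  t2 <- fia_process(sp[perm], sm[perm, ])
  expect_equal(t1$features$mz, t2$features$mz, tolerance = 1e-12)
  expect_identical(t1$features$n_collapsed, t2$features$n_collapsed)
})

test_that("exact-mass annotation handles adducts, multiplicity and tolerance", {
  db <- data.frame(
    compound_id = c("c1", "c2", "c3"),
    name = c("lactic acid", "twin-a", "twin-b"),
    monoisotopic_mass = c(90.03169, 200.0000, 200.0005)
  )
  # negative mode: lactic acid [M-H]- at 89.024414
  tab <- tiny_table(matrix(1, 1, 1), time_h = 0, mz = 89.02442)
  ann <- annotate_features(tab, db, polarity = "-", tol_mDa = 3)
  expect_identical(ann$name, "lactic acid")
  expect_identical(ann$adduct, "[M-H]-")
  expect_lt(abs(ann$mass_error_mDa), 0.01)
  # two compounds 0.5 mDa apart: both annotated at 1 mDa tolerance
  tab2 <- tiny_table(matrix(1, 1, 1), time_h = 0,
                     mz = 200.0000 - 1.007276)
  ann2 <- annotate_features(tab2, db, polarity = "-", tol_mDa = 1)
  expect_setequal(ann2$compound_id, c("c2", "c3"))
  # 5 mDa away at 3 mDa tolerance: unannotated
  tab3 <- tiny_table(matrix(1, 1, 1), time_h = 0,
                     mz = 200.0050 - 1.007276)
  ann3 <- annotate_features(tab3, db[db$compound_id == "c2", ],
                            polarity = "-", tol_mDa = 3)
  expect_identical(nrow(ann3), 0L)
})
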