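# PCA, PLS-on-time, loading-based ranking and the spline trend LRT.

test_that("PCA: rank-1 table loads everything on component 1", {
  base <- c(1, 4, 9, 16)
  X <- outer(base, c(1, 2, 3, 4, 5, 6))  # all samples proportional
  tab <- tiny_table(X, time_h = rep(c(0, 12, 24), each = 2))
  res <- pca_table(tab)
  expect_gt(res$explained_variance[1], 0.999)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-12)
})

test_that("PCA rejects blanks and negative intensities", {
  g <- generate_feature_table(n_features = 30, seed = 2)
  expect_error(pca_table(g$table), "blank")
  tab <- ft_drop_blanks(g$table)
  tab$intensity[1, 1] <- -5
  expect_error(pca_table(tab), "negative")
})

test_that("a duplicated sample leaves PCA loading directions unchanged", {
  g <- generate_feature_table(n_features = 40, frac_trend = 0.5, seed = 12)
  tab <- ft_drop_blanks(quantile_normalize(g$table))
  res1 <- pca_table(tab)
  dup <- tab
  dup$intensity <- cbind(dup$intensity, dup$intensity[, 1])
  dup$samples <- rbind(dup$samples, transform(dup$samples[1, ],
                                              sample_id = "dup"))
  res2 <- feature_table(dup$intensity, dup$features, dup$samples) |>
    pca_table()
  cos <- abs(sum(res1$loadings[, 1] * res2$loadings[, 1])) /
    sqrt(sum(res1$loadings[, 1]^2) * sum(res2$loadings[, 1]^2))
  expect_gt(cos, 0.99)
})

test_that("PLS concentrates loading on the one time-linear feature", {
  tp <- rep(seq(0, 96, 12), each = 3)
  lin <- exp(0.02 * tp)                  # log-linear in time
  flat <- matrix(rep(c(50, 55, 60, 52, 57, 62), length.out = 4 * length(tp)),
                 4, length(tp), byrow = TRUE)  # structured but time-unrelated
  X <- rbind(lin, flat)
  tab <- tiny_table(X, time_h = tp)
  res <- pls_time(tab, n_components = 1)
  expect_identical(unname(which.max(abs(res$loadings[, 1]))), 1L)
  # cross-check component-1 direction against the closed form X'y
  Xl <- scale(t(log(X)), scale = FALSE)
  y0 <- tp - mean(tp)
  w_ref <- drop(crossprod(Xl, y0)); w_ref <- w_ref / sqrt(sum(w_ref^2))
  cos <- abs(sum(res$weights[, 1] * w_ref))
  expect_gt(cos, 1 - 1e-10)
})

test_that("PLS validates its inputs and is deterministic", {
  X <- matrix(runif(40, 1, 2), 4, 10)
  expect_error(pls_time(tiny_table(X, time_h = rep(24, 10))), "constant")
  tab <- tiny_table(X, time_h = rep(c(0, 12, 24, 36, 48), 2))
  r1 <- pls_time(tab); r2 <- pls_time(tab)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$loadings, r2$loadings)
  tab$intensity[1, 1] <- 0  # offset advice on zeros
  r3 <- pls_time(tab)       # auto offset +1, no error
  expect_true(all(is.finite(r3$loadings)))
})

test_that("loading-based ranking sums absolute loadings with id tie-break", {
  ord <- structure(list(
    loadings = matrix(c(0.9, 0.2, -0.1, 0.2), 2, 2,
                      dimnames = list(c("A", "B"), NULL)),
    method = "pls"), class = "ordination")
  rk <- rank_features_by_loading(ord)
  expect_equal(rk$importance, c(1.0, 0.4))
  expect_equal(rk$feature_id, c("A", "B"))
  zero <- structure(list(
    loadings = matrix(0, 3, 2, dimnames = list(c("c", "a", "b"), NULL)),
    method = "pls"), class = "ordination")
  rk0 <- rank_features_by_loading(zero)
  expect_equal(rk0$importance, c(0, 0, 0))
  expect_equal(rk0$feature_id, c("a", "b", "c"))  # id order on ties
})

test_that("trend LRT agrees with lm/lmtest on a single feature", {
  skip_if_not_installed("lmtest")
  tp <- rep(seq(0, 96, 12), each = 3)
  set.seed(31)
  y <- 100 + 0.5 * tp + rnorm(length(tp), 0, 5)
  tab <- tiny_table(matrix(y, 1), time_h = tp)
  res_chisq <- time_trend_lrt(tab, reference = "chisq")
  m1 <- stats::lm(y ~ splines::ns(tp, df = 4))
  m0 <- stats::lm(y ~ 1)
  lr <- lmtest::lrtest(m0, m1)
  expect_equal(res_chisq$lrt_stat, lr$Chisq[2], tolerance = 1e-8)
  expect_equal(res_chisq$p, lr$`Pr(>Chisq)`[2], tolerance = 1e-8)
  # F reference agrees with the exact nested-model F test
  res_f <- time_trend_lrt(tab, reference = "F")
  expect_equal(res_f$p, stats::anova(m0, m1)$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("trend LRT statistics are non-negative and nulls stay quiet", {
  g <- generate_feature_table(n_features = 100, frac_trend = 0.3, seed = 13)
  tab <- ft_drop_blanks(quantile_normalize(g$table))
  res <- time_trend_lrt(tab)
  expect_true(all(res$lrt_stat >= 0))
  # a constant feature at zero noise: statistic ~ 0, not significant
  const <- tiny_table(matrix(100, 1, 27), time_h = rep(seq(0, 96, 12), 3))
  r0 <- time_trend_lrt(const)
  expect_lt(r0$lrt_stat, 1e-6)
  expect_false(r0$significant)
})

test_that("trend LRT guards its design requirements", {
  tp <- rep(c(0, 12, 24), each = 2)
  tab <- tiny_table(matrix(runif(6), 1), time_h = tp)
  expect_error(time_trend_lrt(tab, spline_df = 4), "spline_df")
  single_rep <- tiny_table(matrix(runif(3), 1), time_h = c(0, 12, 24))
  expect_error(time_trend_lrt(single_rep, spline_df = 2), "replicates")
  g <- generate_feature_table(n_features = 10, seed = 1)
  expect_error(time_trend_lrt(g$table), "blank")
})
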