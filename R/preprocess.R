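# Quantile normalization and the above-blank filter.

#' Quantile-normalize a feature table
#'
#' Forces every sample column onto the common distribution given by the
#' across-column mean of order statistics, compensating for global intensity
#' shifts such as the change in cell size over the activation time course.
#' Ties within a column receive the mean of the quantile values they span.
#' Blank columns participate like ordinary samples (they are excluded later,
#' downstream of the blank filter); gap-filled zeros participate as ordinary
#' values.
#'
#' @param table A `feature_table` with no missing entries.
#' @return The normalized `feature_table`.
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$intensity) == 1) return(table)
  norm <- limma::normalizeQuantiles(table$intensity, ties = TRUE)
  dimnames(norm) <- dimnames(table$intensity)
  feature_table(norm, table$features, table$samples)
}

#' Flag features above the sterile-well blank
#'
#' For every feature and every time point, a one-tailed equal-variance
#' two-sample t-test compares the cell replicates at that time point against
#' the blank replicates (alternative: cells greater than blank). A feature is
#' above blank if at least one time point gives p below `alpha`. Applied to
#' quantile-normalized intensities.
#'
#' The pooled-variance t statistics are computed by matrix algebra across all
#' features and time points at once (algebraically identical to
#' `t.test(var.equal = TRUE, alternative = "greater")` per feature).
#'
#' @param table A quantile-normalized `feature_table` with >= 2 blank columns
#'   and >= 2 cell replicates per time point.
#' @param alpha Per-test significance level (default 0.05, uncorrected, as in
#'   the original filter).
#' @return A `blank_filter_result`: list with `p` (features x time points
#'   p-value matrix), `min_p`, and logical `above_blank`.
#' @export
above_blank_filter <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  sm <- table$samples
  blank_cols <- which(sm$is_blank)
  if (length(blank_cols) < 2) {
    stop("above_blank_filter needs >= 2 blank columns; ",
         "the default study_design() provides 3", call. = FALSE)
  }
  time_points <- sort(unique(sm$time_h[!sm$is_blank]))
  X <- table$intensity
  nb <- length(blank_cols)
  mb <- rowMeans(X[, blank_cols, drop = FALSE])
  vb <- apply(X[, blank_cols, drop = FALSE], 1, stats::var)

  p <- matrix(NA_real_, nrow(X), length(time_points),
              dimnames = list(rownames(X), paste0("t", time_points)))
  for (k in seq_along(time_points)) {
    cols <- which(!sm$is_blank & sm$time_h == time_points[k])
    if (length(cols) < 2) {
      stop("need >= 2 cell replicates per time point", call. = FALSE)
    }
    nc <- length(cols)
    mc <- rowMeans(X[, cols, drop = FALSE])
    vc <- apply(X[, cols, drop = FALSE], 1, stats::var)
    df <- nc + nb - 2
    sp2 <- ((nc - 1) * vc + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / nc + 1 / nb))
    tstat <- ifelse(se > 0, (mc - mb) / se,
                    sign(mc - mb) * Inf)  # degenerate: zero pooled variance
    tstat[se == 0 & mc == mb] <- 0
    p[, k] <- stats::pt(tstat, df = df, lower.tail = FALSE)
  }
  min_p <- apply(p, 1, min)
  structure(
    list(p = p, min_p = min_p, above_blank = min_p < alpha, alpha = alpha),
    class = "blank_filter_result"
  )
}

#' @export
print.blank_filter_result <- function(x, ...) {
  cat(sprintf("blank filter (alpha = %g): %d / %d features above blank\n",
              x$alpha, sum(x$above_blank), length(x$above_blank)))
  invisible(x)
}

#' Keep only features above the blank
#'
#' @param table A `feature_table`.
#' @param filter Result of [above_blank_filter()] on the same table (computed
#'   if omitted).
#' @param alpha Passed to [above_blank_filter()] when `filter` is missing.
#' @return The `feature_table` restricted to above-blank features.
#' @export
filter_above_blank <- function(table, filter = NULL, alpha = 0.05) {
  if (is.null(filter)) filter <- above_blank_filter(table, alpha = alpha)
  ft_subset(table, features = filter$above_blank)
}
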