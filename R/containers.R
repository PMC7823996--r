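#' Feature table container
#'
#' A feature-by-sample intensity matrix with feature metadata (m/z, optional
#' retention time, annotations) and sample metadata (time in hours, replicate,
#' blank flag). This is the common currency passed between pipeline stages.
#'
#' @param intensity Numeric matrix, features x samples; no missing values.
#' @param features data.frame with at least `feature_id` and `mz`; one row
#'   per row of `intensity`.
#' @param samples data.frame with at least `sample_id`, `time_h`, `replicate`,
#'   `is_blank`; one row per column of `intensity`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensity, features, samples) {
  intensity <- as.matrix(intensity)
  stopifnot(
    is.numeric(intensity),
    nrow(intensity) == nrow(features),
    ncol(intensity) == nrow(samples),
    all(c("feature_id", "mz") %in% names(features)),
    all(c("sample_id", "time_h", "replicate", "is_blank") %in% names(samples)),
    !anyNA(intensity)
  )
  if (anyDuplicated(features$feature_id)) {
    stop("duplicated feature_id", call. = FALSE)
  }
  rownames(intensity) <- features$feature_id
  colnames(intensity) <- samples$sample_id
  structure(
    list(intensity = intensity,
         features = as.data.frame(features),
         samples = as.data.frame(samples)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  ns <- sum(!x$samples$is_blank)
  nb <- sum(x$samples$is_blank)
  cat(sprintf(
    "feature_table: %d features x %d samples (%d cell, %d blank), %d time points\n",
    nrow(x$intensity), ncol(x$intensity), ns, nb,
    length(unique(x$samples$time_h[!x$samples$is_blank]))
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Subset a feature table by features and/or samples
#'
#' @param x A `feature_table`.
#' @param features Logical/integer/character index into the feature rows.
#' @param samples Logical/integer/character index into the sample columns.
#' @return A `feature_table` restricted to the selection.
#' @export
ft_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  fi <- if (is.null(features)) seq_len(nrow(x$intensity)) else features
  if (is.character(fi)) fi <- match(fi, x$features$feature_id)
  si <- if (is.null(samples)) seq_len(ncol(x$intensity)) else samples
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  feature_table(
    x$intensity[fi, si, drop = FALSE],
    x$features[fi, , drop = FALSE],
    x$samples[si, , drop = FALSE]
  )
}

#' Drop blank columns from a feature table
#'
#' Ordination (PCA/PLS) and trend testing operate on cell samples only; blanks
#' take part in quantile normalization and the blank filter but are excluded
#' downstream.
#'
#' @param x A `feature_table`.
#' @return The table without blank columns.
#' @export
ft_drop_blanks <- function(x) {
  ft_subset(x, samples = !x$samples$is_blank)
}

#' Single-sample centroided mass spectrum
#'
#' @param sample_id Sample identifier.
#' @param mz Numeric vector of m/z values in Da (will be sorted ascending).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param polarity `"+"` or `"-"`.
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(sample_id, mz, intensity, polarity = "-") {
  stopifnot(length(mz) == length(intensity),
            all(intensity >= 0), all(mz > 0), all(mz < 2000),
            polarity %in% c("+", "-"))
  o <- order(mz)
  structure(
    list(sample_id = sample_id, mz = as.numeric(mz[o]),
         intensity = as.numeric(intensity[o]), polarity = polarity),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("spectrum %s (%s mode): %d peaks, m/z %.4f-%.4f\n",
              x$sample_id, x$polarity, length(x$mz),
              if (length(x$mz)) min(x$mz) else NA,
              if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}
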