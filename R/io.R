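# Readers and writers for the pipeline's plain-text interchange formats:
# feature-table CSV with a sample-metadata sidecar, 3-column TSV peak lists,
# compound-database TSV, GMT pathway files, and JSON ground truth.

#' Write a feature table as CSV with a sample-metadata sidecar
#'
#' The main CSV holds one row per feature (feature_id, mz, then one column
#' per sample); the sidecar CSV (`<path base>_samples.csv` unless given) is
#' the single source of truth for time/replicate/blank labels.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @param samples_path Sidecar CSV path (default derived from `path`).
#' @return Invisibly, the two paths.
#' @export
write_feature_table <- function(table, path, samples_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(samples_path)) {
    samples_path <- sub("\\.csv$", "_samples.csv", path)
    if (identical(samples_path, path)) samples_path <- paste0(path, "_samples.csv")
  }
  df <- cbind(table$features, as.data.frame(table$intensity))
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(table$samples, samples_path, row.names = FALSE)
  invisible(c(table = path, samples = samples_path))
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Feature CSV path.
#' @param samples_path Sidecar CSV path (default derived from `path`).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, samples_path = NULL) {
  if (is.null(samples_path)) {
    samples_path <- sub("\\.csv$", "_samples.csv", path)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  sm <- utils::read.csv(samples_path)
  meta_cols <- setdiff(names(df), sm$sample_id)
  feature_table(as.matrix(df[, sm$sample_id, drop = FALSE]),
                df[, meta_cols, drop = FALSE], sm)
}

#' Write spectra as a 3-column TSV peak-list dialect
#'
#' Columns: sample_id, mz, intensity; all spectra concatenated.
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_spectra_tsv <- function(spectra, path) {
  df <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(sample_id = s$sample_id, mz = s$mz, intensity = s$intensity)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra from a 3-column TSV peak list
#'
#' @param path TSV with columns sample_id, mz, intensity.
#' @param polarity Polarity label applied to every spectrum.
#' @return List of `spectrum` objects in first-appearance order.
#' @export
read_spectra_tsv <- function(path, polarity = "-") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ids <- unique(df$sample_id)
  lapply(ids, function(id) {
    g <- df[df$sample_id == id, ]
    ms_spectrum(id, g$mz, g$intensity, polarity)
  })
}

#' Read a compound database TSV
#'
#' Expects columns `compound_id`, `name`, and either `monoisotopic_mass` or
#' `formula` (masses are then computed from the formulas).
#'
#' @param path TSV path.
#' @return data.frame with a `monoisotopic_mass` column.
#' @export
read_compound_db <- function(path) {
  db <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (is.null(db$monoisotopic_mass)) {
    if (is.null(db$formula)) {
      stop("compound database needs 'monoisotopic_mass' or 'formula'",
           call. = FALSE)
    }
    db$monoisotopic_mass <- monoisotopic_mass(db$formula)
  }
  db
}

#' Write pathway definitions in GMT format
#'
#' One pathway per line: id, description, then member compound ids,
#' tab-separated.
#'
#' @param pathways Named list of compound-id vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  lines <- vapply(names(pathways), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else "na"
    paste(c(id, desc, pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read pathway definitions from GMT format
#'
#' @param path GMT path.
#' @return Named list of member-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pw <- lapply(parts, function(p) p[-(1:2)])
  names(pw) <- vapply(parts, `[[`, "", 1)
  pw
}

#' Serialize synthetic ground truth as JSON
#'
#' @param truth A `synthetic_truth`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(features = truth$features, drift = as.list(truth$drift)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
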