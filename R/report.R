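# Feature accounting: per-method counts of features, above-blank fractions
# and time-trend fractions, plus the trend/above-blank ratio whose range
# across methods summarizes how pervasively the metabolome changes.

#' Published feature accounting of the T cell activation study
#'
#' Per-method feature accounting of the CD8+ T cell activation time course
#' (two FIA polarities and four LC-QTOF data sets): total detected features,
#' percent above the sterile-well blank, and percent above blank with a
#' significant time trend. Shipped as a plain-text fixture in
#' `inst/extdata/tcell_study_accounting.tsv`.
#'
#' @return data.frame: `method`, `polarity`, `n_features`,
#'   `pct_above_blank`, `pct_above_blank_with_trend`.
#' @export
study_accounting <- function() {
  path <- system.file("extdata", "tcell_study_accounting.tsv",
                      package = "metabodyn", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Accounting report across methods
#'
#' For each method/polarity data set, reports the feature counts and
#' percentages and derives the ratio of trend percentage to above-blank
#' percentage, i.e. the fraction of above-blank features that change over
#' time. Percentages are rounded to one decimal; the min/max of the ratio
#' across methods is reported as the headline range. A method with zero
#' above-blank features gets an undefined (NA) ratio, not 0.
#'
#' @param accounting data.frame with columns `method`, `polarity`,
#'   `n_features`, `pct_above_blank`, `pct_above_blank_with_trend` (default:
#'   the shipped study accounting).
#' @return An `accounting_report` list: `table` (with
#'   `pct_trend_among_above_blank` added), `total_features`,
#'   `min_trend_fraction`, `max_trend_fraction` (percent, rounded to the
#'   nearest integer for the headline range).
#' @export
run_accounting_report <- function(accounting = study_accounting()) {
  req <- c("method", "polarity", "n_features", "pct_above_blank",
           "pct_above_blank_with_trend")
  stopifnot(all(req %in% names(accounting)))
  ratio <- ifelse(
    accounting$pct_above_blank > 0,
    100 * accounting$pct_above_blank_with_trend / accounting$pct_above_blank,
    NA_real_
  )
  tab <- accounting
  tab$pct_trend_among_above_blank <- round(ratio, 1)
  structure(
    list(table = tab,
         total_features = sum(accounting$n_features),
         min_trend_fraction = round(min(ratio, na.rm = TRUE)),
         max_trend_fraction = round(max(ratio, na.rm = TRUE))),
    class = "accounting_report"
  )
}

#' @export
print.accounting_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf(
    "\n%d features in total; %d%% to %d%% of above-blank features show a time trend\n",
    x$total_features, x$min_trend_fraction, x$max_trend_fraction))
  invisible(x)
}

#' Accounting summary for a processed synthetic data set
#'
#' Computes the same accounting row the study reports per method, from a
#' feature table processed by this package: number of features, percent
#' above blank, and percent above blank with a Bonferroni-significant time
#' trend (both percentages on the full feature count).
#'
#' @param table A quantile-normalized `feature_table` (blanks included).
#' @param method,polarity Labels for the report row.
#' @param alpha Significance level for both the blank filter and the trend
#'   test family-wise level.
#' @param spline_df Spline degrees of freedom for the trend test.
#' @return One-row data.frame in the accounting format.
#' @export
accounting_row <- function(table, method = "FIA", polarity = "-",
                           alpha = 0.05, spline_df = 4) {
  bf <- above_blank_filter(table, alpha = alpha)
  ab <- filter_above_blank(table, bf)
  tt <- time_trend_lrt(ft_drop_blanks(ab), spline_df = spline_df,
                       alpha = alpha)
  n <- nrow(table$intensity)
  data.frame(
    method = method, polarity = polarity, n_features = n,
    pct_above_blank = round(100 * sum(bf$above_blank) / n, 1),
    pct_above_blank_with_trend = round(100 * sum(tt$significant) / n, 1),
    stringsAsFactors = FALSE
  )
}
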