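# Ordination (PCA on square-root scale, PLS on log scale with sampling time
# as the response) and spline-based time-trend likelihood-ratio testing.

# Orient each component so the mean score at the latest time point is >= the
# mean score at the earliest (reproducible sign convention for plots).
orient_components <- function(scores, loadings, time_h) {
  t0 <- time_h == min(time_h)
  t1 <- time_h == max(time_h)
  for (a in seq_len(ncol(scores))) {
    if (mean(scores[t1, a]) < mean(scores[t0, a])) {
      scores[, a] <- -scores[, a]
      loadings[, a] <- -loadings[, a]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of a feature table
#'
#' Square-root scales the (non-negative, quantile-normalized) intensities to
#' limit the influence of high-intensity features, centers each feature over
#' samples and performs PCA via singular value decomposition. Blanks must be
#' excluded beforehand (see [ft_drop_blanks()]).
#'
#' @param table A `feature_table` without blank columns.
#' @param scale `"sqrt"` (default) or `"none"`.
#' @param n_components Components to retain (default all).
#' @return An `ordination` object: `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance` (fractions
#'   summing to 1 over all components), `method = "pca"`.
#' @export
pca_table <- function(table, scale = c("sqrt", "none"), n_components = NULL) {
  stopifnot(inherits(table, "feature_table"))
  scale <- match.arg(scale)
  if (any(table$samples$is_blank)) {
    stop("exclude blank columns before ordination (ft_drop_blanks)",
         call. = FALSE)
  }
  X <- t(table$intensity)  # samples x features
  if (scale == "sqrt") {
    if (any(X < 0)) stop("negative intensities: cannot square-root scale",
                         call. = FALSE)
    X <- sqrt(X)
  }
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- if (is.null(n_components)) sum(sv$d > 1e-12 * sv$d[1]) else n_components
  k <- min(k, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- table$samples$sample_id
  rownames(loadings) <- table$features$feature_id
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  o <- orient_components(scores, loadings, table$samples$time_h)
  structure(list(scores = o$scores, loadings = o$loadings,
                 explained_variance = ev, method = "pca", scale = scale),
            class = "ordination")
}

#' PLS regression of sampling time on log intensities
#'
#' NIPALS PLS1 with sampling time (hours) as the predicted variable.
#' Intensities are log scaled (natural log; an offset of +1 is applied
#' automatically when zeros are present and `offset` is NA), columns are
#' mean-centered, and components are extracted deterministically starting
#' from the response vector. Features' absolute loadings measure how much
#' each contributes to time-dependent change.
#'
#' @param table A `feature_table` without blank columns.
#' @param n_components Number of PLS components (default 2).
#' @param scale `"log"` (default) or `"none"`.
#' @param offset Offset added before the log; `NA` (default) means 0 when all
#'   intensities are strictly positive, else 1.
#' @return An `ordination` object with `scores`, `loadings` (x-loadings),
#'   `weights`, and `explained_variance` = fraction of time variance
#'   explained per component; `method = "pls"`.
#' @export
pls_time <- function(table, n_components = 2, scale = c("log", "none"),
                     offset = NA) {
  stopifnot(inherits(table, "feature_table"), n_components >= 1)
  scale <- match.arg(scale)
  if (any(table$samples$is_blank)) {
    stop("exclude blank columns before ordination (ft_drop_blanks)",
         call. = FALSE)
  }
  y <- table$samples$time_h
  if (stats::var(y) == 0) {
    stop("sampling time is constant: nothing to predict", call. = FALSE)
  }
  X <- t(table$intensity)
  if (scale == "log") {
    if (is.na(offset)) offset <- if (any(X <= 0)) 1 else 0
    if (any(X + offset <= 0)) {
      stop("non-positive intensities: log scaling needs an offset ",
           "(e.g. offset = 1)", call. = FALSE)
    }
    X <- log(X + offset)
  }
  X <- sweep(X, 2, colMeans(X))
  y0 <- y - mean(y)
  n <- nrow(X); p <- ncol(X)
  k <- min(n_components, n - 1, p)
  Tm <- matrix(0, n, k); W <- matrix(0, p, k); P <- matrix(0, p, k)
  qv <- numeric(k)
  Xa <- X; ya <- y0
  ssy <- sum(y0^2)
  for (a in seq_len(k)) {
    w <- crossprod(Xa, ya)            # deterministic: from the response
    w <- w / sqrt(sum(w^2))
    tt <- Xa %*% w
    tnorm <- sum(tt^2)
    pv <- crossprod(Xa, tt) / tnorm
    qv[a] <- sum(ya * tt) / tnorm
    Xa <- Xa - tt %*% t(pv)
    ya <- ya - tt * qv[a]
    Tm[, a] <- tt; W[, a] <- w; P[, a] <- pv
  }
  expl <- vapply(seq_len(k), function(a) {
    sum((Tm[, a] * qv[a])^2) / ssy
  }, numeric(1))
  rownames(Tm) <- table$samples$sample_id
  rownames(P) <- rownames(W) <- table$features$feature_id
  colnames(Tm) <- colnames(P) <- colnames(W) <- paste0("comp", seq_len(k))
  o <- orient_components(Tm, P, y)
  # keep weights in sign-sync with loadings
  flip <- colSums(o$loadings * P) < 0
  W[, flip] <- -W[, flip]
  structure(list(scores = o$scores, loadings = o$loadings, weights = W,
                 explained_variance = expl, method = "pls", scale = scale),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination (%s scale): %d samples x %d components\n",
              toupper(x$method), x$scale, nrow(x$scores), ncol(x$scores)))
  ev <- x$explained_variance[seq_len(min(4, length(x$explained_variance)))]
  cat("explained variance:", paste(sprintf("%.1f%%", 100 * ev),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Rank features by summed absolute PLS loadings
#'
#' Importance of a feature is the sum over the retained components of its
#' absolute loading; with sampling time as the predicted variable this
#' measures how much the feature contributes to time-dependent change.
#' Descending sort; ties broken by feature id.
#'
#' @param ordination An `ordination` from [pls_time()] (or [pca_table()]).
#' @param n_components Components to sum over (default: all retained).
#' @return data.frame `feature_id`, `importance`, sorted descending.
#' @export
rank_features_by_loading <- function(ordination, n_components = NULL) {
  stopifnot(inherits(ordination, "ordination"))
  L <- ordination$loadings
  k <- if (is.null(n_components)) ncol(L) else min(n_components, ncol(L))
  imp <- rowSums(abs(L[, seq_len(k), drop = FALSE]))
  out <- data.frame(feature_id = rownames(L), importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spline-based time-trend likelihood-ratio test
#'
#' Per feature, fits intensity against a natural cubic spline basis of time
#' with `spline_df` degrees of freedom (unpenalized, so the test degrees of
#' freedom are exact) versus an intercept-only null, both by Gaussian maximum
#' likelihood. The statistic is 2 x the log-likelihood difference,
#' `n * log(RSS0 / RSS1)`. Default p-values come from the exact F reference
#' for nested Gaussian linear models, which is calibrated at the study's
#' sample size; the asymptotic chi-square reference (`reference = "chisq"`,
#' df = `spline_df`) is available and anti-conservative at small n.
#' Significance is Bonferroni-corrected for the number of features tested.
#'
#' @param table A `feature_table` without blank columns (above-blank features
#'   only, quantile-normalized).
#' @param spline_df Spline degrees of freedom (default 4); must be smaller
#'   than the number of distinct time points.
#' @param alpha Family-wise significance level before Bonferroni division.
#' @param reference `"F"` (default, exact) or `"chisq"` (asymptotic).
#' @return A `time_trend_result` data.frame: `feature_id`, `lrt_stat`, `df`,
#'   `p`, `significant` (Bonferroni), plus attributes `alpha`, `n_tested`.
#' @export
time_trend_lrt <- function(table, spline_df = 4, alpha = 0.05,
                           reference = c("F", "chisq")) {
  stopifnot(inherits(table, "feature_table"))
  reference <- match.arg(reference)
  sm <- table$samples
  if (any(sm$is_blank)) {
    stop("exclude blank columns before trend testing", call. = FALSE)
  }
  time_h <- sm$time_h
  n_tp <- length(unique(time_h))
  if (spline_df >= n_tp) {
    stop(sprintf("spline_df (%d) must be < number of distinct time points (%d)",
                 spline_df, n_tp), call. = FALSE)
  }
  reps <- tabulate(factor(time_h))
  if (any(reps < 2)) stop("need >= 2 replicates per time point", call. = FALSE)

  B <- cbind(1, splines::ns(time_h, df = spline_df))
  n <- length(time_h)
  Y <- t(table$intensity)                       # samples x features
  # residual sums of squares under both models, all features at once
  qr1 <- qr(B)
  rss1 <- colSums(qr.resid(qr1, Y)^2)
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  rss1 <- pmax(rss1, .Machine$double.eps)
  stat <- n * log(pmax(rss0 / rss1, 1))
  df_res <- n - spline_df - 1
  p <- if (reference == "F") {
    Fstat <- ((rss0 - rss1) / spline_df) / (rss1 / df_res)
    stats::pf(Fstat, spline_df, df_res, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = spline_df, lower.tail = FALSE)
  }
  n_tested <- nrow(table$intensity)
  out <- data.frame(feature_id = table$features$feature_id,
                    lrt_stat = stat, df = spline_df, p = p,
                    significant = p < alpha / n_tested,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("time_trend_result", "data.frame"),
            alpha = alpha, n_tested = n_tested, reference = reference)
}
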