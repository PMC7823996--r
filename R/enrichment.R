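# Metabolite set enrichment: expand feature importances to annotated
# metabolites (multi-annotation aware), then a weighted Kolmogorov-Smirnov
# running-sum enrichment with a member-label permutation null.

#' Expand a feature ranking to the metabolite level
#'
#' Every (feature, candidate compound) annotation pair propagates the
#' feature's importance to that compound: a feature annotated with several
#' metabolites contributes its importance to each of them, and a compound hit
#' by several features receives either the maximum (default) or the sum of
#' their importances. Unannotated features are dropped.
#'
#' @param ranking data.frame from [rank_features_by_loading()] (`feature_id`,
#'   `importance`).
#' @param annotations data.frame from [annotate_features()] (`feature_id`,
#'   `compound_id`).
#' @param collision `"max"` (default) or `"sum"`.
#' @return Named numeric vector of compound importances, sorted descending
#'   (ties broken by compound id).
#' @export
expand_to_metabolites <- function(ranking, annotations,
                                  collision = c("max", "sum")) {
  collision <- match.arg(collision)
  m <- merge(annotations[, c("feature_id", "compound_id")], ranking,
             by = "feature_id")
  if (nrow(m) == 0) return(stats::setNames(numeric(0), character(0)))
  agg <- tapply(m$importance, m$compound_id,
                if (collision == "max") max else sum)
  v <- as.numeric(agg)
  names(v) <- names(agg)
  v[order(-v, names(v))]
}

# Weighted KS running-sum enrichment score for one set of hit positions
# within a ranking of length N with weights |r|^weight_p.
running_sum_es <- function(rank_values, hit_idx, weight_p = 1) {
  N <- length(rank_values)
  k <- length(hit_idx)
  w <- abs(rank_values[hit_idx])^weight_p
  nr <- sum(w)
  if (nr == 0) w[] <- 1 / k else w <- w / nr
  steps <- rep(-1 / (N - k), N)
  steps[hit_idx] <- if (nr == 0) 1 / k else w
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Metabolite set enrichment over pathway definitions
#'
#' Ranks metabolites by importance (descending) and computes a weighted
#' Kolmogorov-Smirnov running-sum enrichment score per pathway: the running
#' sum climbs by the normalized importance weight at each member and falls by
#' 1/(N - k) elsewhere; the ES is its extreme deviation. The null
#' distribution comes from `n_perm` random member-label permutations (random
#' sets of the same size); `p = (b + 1) / (n_perm + 1)` where `b` counts null
#' scores at least as extreme with the same sign, and the normalized score
#' NES divides ES by the mean absolute null ES of the same sign.
#'
#' @param metabolite_ranking Named numeric vector of non-negative
#'   importances (from [expand_to_metabolites()]).
#' @param pathways Named list of compound-id vectors.
#' @param weight_p Running-sum weight exponent (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param min_size Minimum number of ranked members for a pathway to be
#'   tested (default 3).
#' @param seed Integer seed for the permutation null.
#' @return data.frame sorted by decreasing NES: `pathway`, `size`, `es`,
#'   `nes`, `p`, `leading_edge` (comma-separated compound ids).
#' @export
gsea_pathways <- function(metabolite_ranking, pathways, weight_p = 1,
                          n_perm = 1000, min_size = 3, seed = 1) {
  if (length(metabolite_ranking) == 0) {
    stop("empty metabolite ranking", call. = FALSE)
  }
  if (any(metabolite_ranking < 0)) {
    stop("importances must be non-negative (use absolute loadings)",
         call. = FALSE)
  }
  r <- sort(metabolite_ranking, decreasing = TRUE)
  N <- length(r)
  sizes <- vapply(pathways, function(p) sum(names(r) %in% p), integer(1))
  keep <- sizes >= min_size & sizes < N
  if (!any(keep)) {
    warning("no pathway has >= min_size ranked members")
    return(data.frame(pathway = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      leading_edge = character(0)))
  }
  pathways <- pathways[keep]
  sizes <- sizes[keep]

  with_seed(seed, {
    # shared null per set size
    null_by_size <- lapply(unique(sizes), function(k) {
      vapply(seq_len(n_perm), function(b) {
        running_sum_es(r, sort(sample.int(N, k)), weight_p)
      }, numeric(1))
    })
    names(null_by_size) <- as.character(unique(sizes))

    res <- lapply(seq_along(pathways), function(i) {
      hit_idx <- which(names(r) %in% pathways[[i]])
      es <- running_sum_es(r, hit_idx, weight_p)
      null_es <- null_by_size[[as.character(sizes[i])]]
      same_sign <- null_es[sign(null_es) == sign(es) | null_es == 0]
      b <- sum(abs(same_sign) >= abs(es))
      p <- (b + 1) / (n_perm + 1)
      denom <- mean(abs(same_sign))
      nes <- if (is.finite(denom) && denom > 0) es / denom else 0
      # leading edge: members at or before the running-sum extreme
      steps <- rep(-1 / (N - length(hit_idx)), N)
      w <- abs(r[hit_idx])^weight_p
      steps[hit_idx] <- if (sum(w) > 0) w / sum(w) else 1 / length(hit_idx)
      rs <- cumsum(steps)
      peak <- which.max(abs(rs))
      le <- if (es >= 0) names(r)[intersect(hit_idx, seq_len(peak))]
            else names(r)[hit_idx[hit_idx >= peak]]
      data.frame(pathway = names(pathways)[i], size = sizes[i],
                 es = es, nes = nes, p = p,
                 leading_edge = paste(le, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out <- out[order(-out$nes), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
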