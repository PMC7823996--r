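# FIA MS1 processing: quadratic lock-mass recalibration, reference
# normalization, top-N peak detection, cross-sample consensus features, gap
# filling, 13C isotopologue collapsing and exact-mass adduct annotation.

# Match each reference mass to the most intense observed peak within
# match_tol (the tune-mix signal dominates its neighborhood, so intensity,
# not proximity, disambiguates against chance background peaks). Returns a
# data.frame (ref, mz, intensity) of matched references only.
match_reference_peaks <- function(spec, reference_masses, match_tol) {
  hits <- lapply(reference_masses, function(r) {
    within <- which(abs(spec$mz - r) <= match_tol)
    if (length(within)) {
      i <- within[which.max(spec$intensity[within])]
      data.frame(ref = r, mz = spec$mz[i], intensity = spec$intensity[i])
    }
  })
  do.call(rbind, hits)
}

#' Fit a quadratic mass recalibration from tune-mix reference peaks
#'
#' Reference masses are matched to their nearest observed peaks within
#' `match_tol`; the mass error (observed - reference) is then fitted as a
#' quadratic polynomial of the reference mass by least squares. With at least
#' three matched references and noise-free quadratic drift the planted
#' coefficients are recovered exactly.
#'
#' @param spec A `spectrum`.
#' @param reference_masses Reference (true) m/z values, >= 3 must match.
#' @param match_tol Matching tolerance in Da (default 0.05, generous enough
#'   for typical drift of a few mDa).
#' @return A `calibration_model` with `coefficients` (c0, c1, c2) and
#'   `residuals` at the matched references.
#' @export
fit_mass_recalibration <- function(spec, reference_masses, match_tol = 0.05) {
  stopifnot(inherits(spec, "ms_spectrum"))
  matched <- match_reference_peaks(spec, reference_masses, match_tol)
  n_ok <- if (is.null(matched)) 0L else nrow(matched)
  if (n_ok < 3) {
    missing <- setdiff(reference_masses,
                       if (is.null(matched)) numeric(0) else matched$ref)
    stop(sprintf(
      "mass recalibration needs >= 3 matched references, got %d; unmatched: %s",
      n_ok, paste(format(missing), collapse = ", ")), call. = FALSE)
  }
  err <- matched$mz - matched$ref
  fit <- stats::lm.fit(cbind(1, matched$ref, matched$ref^2), err)
  co <- fit$coefficients
  names(co) <- c("c0", "c1", "c2")
  structure(list(coefficients = co, residuals = fit$residuals,
                 reference_masses = matched$ref),
            class = "calibration_model")
}

#' Apply a mass recalibration to a spectrum
#'
#' Corrects every m/z by subtracting the fitted drift polynomial. Because the
#' polynomial is expressed in the true mass, the correction
#' `m_true = m_obs - p(m_true)` is solved by fixed-point iteration (the drift
#' is a tiny perturbation, so three iterations converge far below 1e-9 Da).
#'
#' @param spec A `spectrum`.
#' @param model A `calibration_model`.
#' @return The spectrum with corrected m/z values.
#' @export
apply_recalibration <- function(spec, model) {
  stopifnot(inherits(spec, "ms_spectrum"), inherits(model, "calibration_model"))
  co <- model$coefficients
  p <- function(m) co[1] + co[2] * m + co[3] * m^2
  m <- spec$mz
  for (i in 1:3) m <- spec$mz - p(m)
  ms_spectrum(spec$sample_id, m, spec$intensity, spec$polarity)
}

#' Normalize spectrum intensities by the tune-mix reference signal
#'
#' All intensities are divided by the summed intensity of the matched
#' reference peaks, removing sample-to-sample variation in overall signal.
#'
#' @param spec A `spectrum`.
#' @param reference_masses Reference m/z values; at least one must match.
#' @param match_tol Matching tolerance in Da.
#' @return The normalized spectrum.
#' @export
normalize_by_reference <- function(spec, reference_masses, match_tol = 0.05) {
  stopifnot(inherits(spec, "ms_spectrum"))
  matched <- match_reference_peaks(spec, reference_masses, match_tol)
  if (is.null(matched) || nrow(matched) == 0) {
    stop("no reference peak matched; cannot normalize", call. = FALSE)
  }
  s <- sum(matched$intensity)
  ms_spectrum(spec$sample_id, spec$mz, spec$intensity / s, spec$polarity)
}

#' Detect the most intense peaks of a spectrum
#'
#' Returns the `n` highest-intensity peaks, m/z-sorted. A tie at rank `n` is
#' broken in favor of the lower m/z (deterministic).
#'
#' @param spec A `spectrum`.
#' @param n Number of peaks to keep (default 1000).
#' @return A `spectrum` restricted to the selected peaks.
#' @export
detect_top_peaks <- function(spec, n = 1000) {
  stopifnot(inherits(spec, "ms_spectrum"), n >= 1)
  if (length(spec$mz) <= n) return(spec)
  o <- order(-spec$intensity, spec$mz)[seq_len(n)]
  ms_spectrum(spec$sample_id, spec$mz[o], spec$intensity[o], spec$polarity)
}

#' Combine per-sample peak lists into consensus features
#'
#' Pools all detected peaks and clusters them in m/z by single linkage:
#' consecutive (sorted) peaks join the same cluster when their gap is within
#' `tol_ppm`. Each cluster becomes one consensus feature; if a sample
#' contributes several peaks to a cluster only its most intense is kept. The
#' representative m/z is the intensity-weighted mean of the member peaks.
#'
#' @param peaklists List of `spectrum` objects (one per sample).
#' @param tol_ppm Linkage tolerance in parts per million (default 5).
#' @return data.frame of consensus features (`feature_id`, `mz`,
#'   `n_samples`) with a `members` attribute mapping features to per-sample
#'   member peaks.
#' @export
build_consensus_features <- function(peaklists, tol_ppm = 5) {
  stopifnot(length(peaklists) >= 1)
  pool <- do.call(rbind, lapply(peaklists, function(s) {
    if (!length(s$mz)) return(NULL)
    data.frame(sample_id = s$sample_id, mz = s$mz, intensity = s$intensity,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || nrow(pool) == 0) {
    return(structure(data.frame(feature_id = character(0), mz = numeric(0),
                                n_samples = integer(0)),
                     members = list()))
  }
  pool <- pool[order(pool$mz), , drop = FALSE]
  gap_rel <- diff(pool$mz) / pool$mz[-nrow(pool)]
  cluster <- cumsum(c(1L, as.integer(gap_rel > tol_ppm * 1e-6)))

  members <- split(pool, cluster)
  members <- lapply(members, function(g) {
    # one peak per sample: keep the most intense
    g <- g[order(-g$intensity), , drop = FALSE]
    g[!duplicated(g$sample_id), , drop = FALSE]
  })
  rep_mz <- vapply(members, function(g) {
    sum(g$mz * g$intensity) / sum(g$intensity)
  }, numeric(1))
  o <- order(rep_mz)
  members <- members[o]
  rep_mz <- rep_mz[o]
  ids <- sprintf("CF%05d", seq_along(members))
  names(members) <- ids
  structure(
    data.frame(feature_id = ids, mz = rep_mz,
               n_samples = vapply(members, nrow, integer(1)),
               row.names = NULL, stringsAsFactors = FALSE),
    members = members
  )
}

#' Fill missing feature intensities from the raw spectra
#'
#' Builds the feature x sample intensity matrix from a consensus feature
#' list. Where a sample contributed a detected member peak, that intensity is
#' used; otherwise the raw (recalibrated, normalized) spectrum is re-queried
#' and all peaks within `tol_ppm` of the representative m/z are summed; a
#' truly absent feature gets 0. The result has no missing entries.
#'
#' @param spectra List of `spectrum` objects, same samples as the peak lists
#'   used to build the consensus.
#' @param consensus Result of [build_consensus_features()].
#' @param samples Sample metadata data.frame (sample_id, time_h, replicate,
#'   is_blank) in the order of `spectra`.
#' @param tol_ppm Extraction tolerance in ppm.
#' @return A `feature_table`.
#' @export
fill_gaps <- function(spectra, consensus, samples, tol_ppm = 5) {
  if (nrow(consensus) == 0) stop("empty consensus feature list", call. = FALSE)
  members <- attr(consensus, "members")
  sample_ids <- vapply(spectra, `[[`, "", "sample_id")
  stopifnot(identical(sample_ids, samples$sample_id))
  inten <- matrix(0, nrow(consensus), length(spectra))
  for (f in seq_len(nrow(consensus))) {
    g <- members[[consensus$feature_id[f]]]
    j <- match(g$sample_id, sample_ids)
    inten[f, j] <- g$intensity
  }
  tol_abs <- consensus$mz * tol_ppm * 1e-6
  for (j in seq_along(spectra)) {
    miss <- which(inten[, j] == 0)
    if (!length(miss)) next
    mz <- spectra[[j]]$mz
    it <- spectra[[j]]$intensity
    for (f in miss) {
      lo <- findInterval(consensus$mz[f] - tol_abs[f], mz)
      hi <- findInterval(consensus$mz[f] + tol_abs[f], mz)
      if (hi > lo) inten[f, j] <- sum(it[(lo + 1):hi])
    }
  }
  feature_table(inten,
                data.frame(feature_id = consensus$feature_id,
                           mz = consensus$mz),
                samples)
}

#' Plausible isotopologue intensity-ratio bound
#'
#' Default bound used by [collapse_isotopes()]: 1.5 times the expected M+1
#' ratio of an all-carbon molecule of mass `m` (a conservative upper bound on
#' the carbon count), i.e. `1.5 * 0.0107 * (m / 12)`.
#'
#' @param m Monoisotopic m/z of the chain head.
#' @return Maximum plausible I(M+1)/I(M) ratio.
#' @export
default_max_isotope_ratio <- function(m) {
  1.5 * ms_constants[["c13_abundance"]] * (m / 12)
}

#' Collapse 13C isotopologue chains into their monoisotopic feature
#'
#' Scans features in ascending m/z and greedily extends chains: a feature
#' joins the chain when its spacing from the chain tail is within `delta_tol`
#' of 1.00335 Da and the median across samples of its intensity ratio to the
#' tail is positive and below `max_ratio_fn(chain head m/z)`. Each chain is
#' replaced by a single feature at the monoisotopic m/z whose per-sample
#' intensity is the sum over chain members, so total intensity is conserved.
#'
#' @param table A `feature_table` (features m/z-sorted).
#' @param delta Isotopologue spacing in Da (default 1.00335).
#' @param delta_tol Spacing tolerance in Da (default 0.005).
#' @param max_ratio_fn Function of the chain-head m/z returning the maximum
#'   plausible consecutive intensity ratio.
#' @param keep Either `"sum"` (default: chain intensities summed) or
#'   `"monoisotopic"` (keep only the monoisotopic member's intensities).
#' @return The collapsed `feature_table`; its `features` gain an
#'   `n_collapsed` column (number of isotopologue members absorbed), and a
#'   `"chains"` attribute lists the member m/z values of every chain.
#' @export
collapse_isotopes <- function(table,
                              delta = ms_constants[["c13_delta"]],
                              delta_tol = 0.005,
                              max_ratio_fn = default_max_isotope_ratio,
                              keep = c("sum", "monoisotopic")) {
  stopifnot(inherits(table, "feature_table"))
  keep <- match.arg(keep)
  mz <- table$features$mz
  if (is.unsorted(mz)) stop("feature table must be m/z-sorted", call. = FALSE)
  n <- length(mz)
  X <- table$intensity
  chain_of <- integer(n)       # 0 = unassigned
  chain_head <- integer(0)
  chain_tail <- numeric(0)     # m/z of current tail per chain
  tail_row <- integer(0)
  n_chain <- 0L
  for (i in seq_len(n)) {
    if (chain_of[i] != 0L) next
    n_chain <- n_chain + 1L
    chain_of[i] <- n_chain
    chain_head[n_chain] <- i
    tail_mz <- mz[i]
    tail_i <- i
    repeat {
      target <- tail_mz + delta
      cand <- which(mz >= target - delta_tol & mz <= target + delta_tol &
                      chain_of == 0L)
      if (!length(cand)) break
      cand <- cand[which.min(abs(mz[cand] - target))]
      ratio <- stats::median(
        ifelse(X[tail_i, ] > 0, X[cand, ] / X[tail_i, ], NA_real_),
        na.rm = TRUE
      )
      if (!is.finite(ratio) || ratio <= 0 ||
          ratio > max_ratio_fn(mz[chain_head[n_chain]])) break
      chain_of[cand] <- n_chain
      tail_mz <- mz[cand]
      tail_i <- cand
    }
  }
  heads <- chain_head[seq_len(n_chain)]
  if (keep == "sum") {
    newX <- rowsum(X, group = chain_of, reorder = TRUE)
  } else {
    newX <- X[heads, , drop = FALSE]
  }
  feats <- table$features[heads, , drop = FALSE]
  feats$n_collapsed <- as.integer(tabulate(chain_of, n_chain) - 1L)
  rownames(newX) <- feats$feature_id
  out <- feature_table(newX, feats, table$samples)
  # member m/z per chain, for auditing which features were merged
  attr(out, "chains") <- split(mz, chain_of)
  out
}

#' Annotate features by exact mass against a compound database
#'
#' Each feature is matched to every compound whose \[M+H\]+ (positive mode)
#' or \[M-H\]- (negative mode) adduct m/z lies within `tol_mDa`; features can
#' carry zero, one or several candidates (several metabolites may share a sum
#' formula or near-identical mass). If both the features and the database
#' carry retention times, candidates are additionally required to match
#' within `rt_tol` minutes.
#'
#' @param table A `feature_table`.
#' @param compound_db data.frame with `compound_id`, `name`,
#'   `monoisotopic_mass` and optionally `rt`.
#' @param polarity `"+"` or `"-"`.
#' @param tol_mDa Mass tolerance in mDa (default 3, the wide annotation
#'   setting).
#' @param rt_tol Optional retention-time tolerance in minutes.
#' @return data.frame of annotations: `feature_id`, `compound_id`, `name`,
#'   `adduct`, `mass_error_mDa`.
#' @export
annotate_features <- function(table, compound_db, polarity = c("-", "+"),
                              tol_mDa = 3, rt_tol = NULL) {
  stopifnot(inherits(table, "feature_table"), nrow(compound_db) > 0)
  polarity <- match.arg(polarity)
  adduct <- if (polarity == "+") "[M+H]+" else "[M-H]-"
  ion_mz <- adduct_mz(compound_db$monoisotopic_mass, adduct)
  out <- lapply(seq_len(nrow(table$features)), function(f) {
    err_mDa <- (table$features$mz[f] - ion_mz) * 1e3
    hit <- abs(err_mDa) <= tol_mDa
    if (!is.null(rt_tol) && !is.null(compound_db$rt) &&
        !is.null(table$features$rt)) {
      hit <- hit & abs(table$features$rt[f] - compound_db$rt) <= rt_tol
    }
    if (!any(hit)) return(NULL)
    data.frame(feature_id = table$features$feature_id[f],
               compound_id = compound_db$compound_id[hit],
               name = compound_db$name[hit],
               adduct = adduct,
               mass_error_mDa = err_mDa[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), compound_id = character(0),
                      name = character(0), adduct = character(0),
                      mass_error_mDa = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Run the full FIA processing pipeline on a set of spectra
#'
#' Per sample: quadratic recalibration against the tune mix, reference
#' normalization, top-`top_n` peak detection; then cross-sample consensus
#' feature building, gap filling from the processed spectra, and optional
#' isotopologue collapsing.
#'
#' @param spectra List of `spectrum` objects, one per sample.
#' @param samples Sample metadata in the order of `spectra`.
#' @param reference_masses Tune-mix reference masses.
#' @param top_n Peaks detected per sample (default 1000).
#' @param tol_ppm Consensus/gap-fill tolerance (default 5 ppm).
#' @param collapse Collapse isotopologue chains (default TRUE).
#' @param delta_tol Isotopologue spacing tolerance in Da.
#' @return A `feature_table` of consensus features.
#' @export
fia_process <- function(spectra, samples,
                        reference_masses = default_tune_mix(),
                        top_n = 1000, tol_ppm = 5,
                        collapse = TRUE, delta_tol = 0.005) {
  processed <- lapply(spectra, function(s) {
    cal <- fit_mass_recalibration(s, reference_masses)
    normalize_by_reference(apply_recalibration(s, cal), reference_masses)
  })
  peaklists <- lapply(processed, detect_top_peaks, n = top_n)
  consensus <- build_consensus_features(peaklists, tol_ppm = tol_ppm)
  tab <- fill_gaps(processed, consensus, samples, tol_ppm = tol_ppm)
  if (collapse) tab <- collapse_isotopes(tab, delta_tol = delta_tol)
  tab
}
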