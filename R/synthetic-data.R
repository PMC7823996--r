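# Synthetic-data generator: emulates the T cell activation time-course design
# (9 time points 0-96 h every 12 h, 3 biological replicates, sterile-well
# blank, tune-mix reference masses, planted time trends and isotope chains,
# quadratic mass drift, multiplicative log-normal noise) with full ground
# truth, so every downstream stage can be tested without raw data downloads.

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default tune-mix reference masses
#'
#' A small series of reference masses spanning the scan range, in the spirit
#' of an ESI low-concentration tuning mix, used for quadratic mass
#' recalibration and intensity normalization.
#'
#' @return Numeric vector of reference m/z values (Da), ascending.
#' @export
default_tune_mix <- function() {
  c(112.98559, 322.04812, 622.02896, 921.99798, 1033.98811)
}

#' Study design for the activation time course
#'
#' @param time_points Sampling times in hours; strictly increasing. Default:
#'   every 12 h from 0 to 96 h (9 time points).
#' @param n_replicates Biological replicates per time point (default 3).
#' @param blank_replicates Sterile-well blank replicates (default 3; at least
#'   2 are required by the two-sample blank t-test).
#' @return A `study_design` object with a `samples` metadata data.frame
#'   (sample_id, time_h, replicate, is_blank).
#' @export
study_design <- function(time_points = seq(0, 96, by = 12),
                         n_replicates = 3, blank_replicates = 3) {
  stopifnot(length(time_points) >= 2, all(diff(time_points) > 0),
            n_replicates >= 1, blank_replicates >= 1)
  cells <- expand.grid(replicate = seq_len(n_replicates),
                       time_h = time_points)
  samples <- data.frame(
    sample_id = c(sprintf("t%03d_r%d", cells$time_h, cells$replicate),
                  sprintf("blank_r%d", seq_len(blank_replicates))),
    time_h = c(cells$time_h, rep(NA_real_, blank_replicates)),
    replicate = c(cells$replicate, seq_len(blank_replicates)),
    is_blank = c(rep(FALSE, nrow(cells)), rep(TRUE, blank_replicates)),
    stringsAsFactors = FALSE
  )
  structure(list(time_points = time_points, n_replicates = n_replicates,
                 blank_replicates = blank_replicates, samples = samples),
            class = "study_design")
}

# Relative trend multiplier at time t for one planted feature.
# monotone trends are logistic in time (plateauing profiles such as
# spermidine); transients are Gaussian bumps (profiles such as MTA).
trend_value <- function(trend_class, t, amplitude, t_center, width = 8) {
  switch(trend_class,
    flat          = rep(1, length(t)),
    monotone_up   = 1 + amplitude * stats::plogis((t - t_center) / width),
    monotone_down = 1 + amplitude * stats::plogis(-(t - t_center) / width),
    transient     = 1 + amplitude * exp(-(t - t_center)^2 / (2 * 12^2)),
    stop("unknown trend class: ", trend_class, call. = FALSE)
  )
}

#' Generate a synthetic feature table with planted time trends
#'
#' Produces a feature x sample intensity matrix following the study design,
#' with a chosen fraction of features carrying planted monotone (logistic) or
#' transient (Gaussian bump) time trends and the rest flat. Intensities are
#' `base_intensity * trend(t) * exp(eps)` with `eps ~ N(0, log(1 + noise_cv))`.
#' Features flagged above-blank appear in blank columns at 5% of their base
#' intensity; medium-derived features (not above blank) are flat and equally
#' intense in blanks and cell samples.
#'
#' @param design A `study_design`.
#' @param n_features Number of features (>= 1).
#' @param frac_trend Fraction of features with a non-flat planted trend.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param frac_above_blank Fraction of features planted above the blank;
#'   raised to `frac_trend` if smaller (trends are only planted above blank).
#' @param amplitude_range Range from which relative trend amplitudes are
#'   drawn uniformly (amplitude 1 means the feature doubles).
#' @param seed Integer seed; same seed reproduces the table exactly.
#' @return List with `table` (a `feature_table`) and `truth` (a
#'   `synthetic_truth` list: per-feature truth data.frame, drift coefficients,
#'   isotope chain bookkeeping filled in by [generate_fia_spectra()]).
#' @export
generate_feature_table <- function(design = study_design(),
                                   n_features = 200,
                                   frac_trend = 0.5,
                                   noise_cv = 0.1,
                                   frac_above_blank = 0.5,
                                   amplitude_range = c(1, 3),
                                   seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  if (frac_trend < 0 || frac_trend > 1) {
    stop("frac_trend must be in [0, 1]", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)

  with_seed(seed, {
    n_trend <- round(frac_trend * n_features)
    n_ab <- max(round(frac_above_blank * n_features), n_trend)
    feats <- data.frame(
      feature_id = sprintf("F%04d", seq_len(n_features)),
      true_mz = sort(stats::runif(n_features, 70, 1000)),
      stringsAsFactors = FALSE
    )
    feats$n_carbons <- pmax(1L, round(feats$true_mz *
                                        stats::runif(n_features, 0.03, 0.07)))
    feats$base_intensity <- exp(stats::rnorm(n_features, log(1e5), 0.8))
    feats$above_blank <- seq_len(n_features) %in%
      sample.int(n_features, n_ab)
    feats$trend_class <- "flat"
    idx_ab <- which(feats$above_blank)
    idx_trend <- if (n_trend > 0) sample(idx_ab, n_trend) else integer(0)
    feats$trend_class[idx_trend] <- sample(
      c("monotone_up", "monotone_down", "transient"),
      n_trend, replace = TRUE
    )
    feats$amplitude <- ifelse(
      feats$trend_class == "flat", 0,
      stats::runif(n_features, amplitude_range[1], amplitude_range[2])
    )
    tp <- design$time_points
    feats$t_center <- ifelse(
      feats$trend_class == "transient",
      sample(tp[tp > min(tp) & tp < max(tp)], n_features, replace = TRUE),
      stats::runif(n_features, 18, 60)
    )

    sm <- design$samples
    sdlog <- log(1 + noise_cv)
    inten <- matrix(0, n_features, nrow(sm))
    for (j in seq_len(nrow(sm))) {
      eps <- if (sdlog > 0) stats::rnorm(n_features, 0, sdlog) else 0
      if (sm$is_blank[j]) {
        level <- ifelse(feats$above_blank,
                        0.05 * feats$base_intensity,
                        feats$base_intensity)
      } else {
        tr <- vapply(seq_len(n_features), function(i) {
          trend_value(feats$trend_class[i], sm$time_h[j],
                      feats$amplitude[i], feats$t_center[i])
        }, numeric(1))
        level <- feats$base_intensity * tr
      }
      inten[, j] <- level * exp(eps)
    }

    ft <- feature_table(
      inten,
      data.frame(feature_id = feats$feature_id, mz = feats$true_mz),
      sm
    )
    truth <- structure(
      list(features = feats,
           drift = c(a = 2e-3, b = 5e-6, c = 1e-9),
           design = design,
           isotope_k = 2L),
      class = "synthetic_truth"
    )
    list(table = ft, truth = truth)
  })
}

#' Generate FIA-like centroided spectra from planted truth
#'
#' One spectrum per sample (cell samples and blanks). Each spectrum carries
#' tune-mix reference peaks, planted monoisotopic peaks, 13C isotopologue
#' peaks at +k x 1.00335 Da with binomial intensity ratios determined by the
#' planted carbon count, and low-intensity noise peaks to reach at least
#' `min_peaks` peaks. All observed m/z are displaced by the quadratic drift
#' `a + b*m + c*m^2` evaluated at the true m/z.
#'
#' @param truth A `synthetic_truth` from [generate_feature_table()].
#' @param design A `study_design` (defaults to the one stored in `truth`).
#' @param tune_mix Reference masses (>= 3 required for the downstream
#'   quadratic recalibration).
#' @param drift Length-3 numeric `(a, b, c)`; defaults to the truth's drift.
#' @param noise_cv Multiplicative intensity noise.
#' @param min_peaks Minimum peak count per spectrum (default 1100).
#' @param isotope_k Isotopologues planted per feature (default 2: M+1, M+2).
#' @param seed Integer seed.
#' @return List of `spectrum` objects, one per sample.
#' @export
generate_fia_spectra <- function(truth,
                                 design = truth$design,
                                 tune_mix = default_tune_mix(),
                                 drift = truth$drift,
                                 noise_cv = 0.1,
                                 min_peaks = 1100,
                                 isotope_k = 2L,
                                 seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(tune_mix) < 3) {
    stop("at least 3 tune-mix reference masses are required", call. = FALSE)
  }
  if (!all(is.finite(drift)) || length(drift) != 3) {
    stop("drift coefficients must be 3 finite numbers", call. = FALSE)
  }
  apply_drift <- function(m) m + drift[1] + drift[2] * m + drift[3] * m^2
  feats <- truth$features
  sm <- design$samples
  sdlog <- log(1 + noise_cv)

  with_seed(seed, {
    lapply(seq_len(nrow(sm)), function(j) {
      t_h <- sm$time_h[j]
      if (sm$is_blank[j]) {
        level <- ifelse(feats$above_blank, 0.05, 1) * feats$base_intensity
      } else {
        tr <- vapply(seq_len(nrow(feats)), function(i) {
          trend_value(feats$trend_class[i], t_h,
                      feats$amplitude[i], feats$t_center[i])
        }, numeric(1))
        level <- feats$base_intensity * tr
      }
      eps <- if (sdlog > 0) stats::rnorm(nrow(feats), 0, sdlog) else 0
      mono_int <- level * exp(eps)

      mzs <- feats$true_mz
      ints <- mono_int
      for (k in seq_len(isotope_k)) {
        ratio <- isotope_ratio(feats$n_carbons, k)
        keep <- ratio * mono_int > 1  # drop vanishing isotopologues
        mzs <- c(mzs, feats$true_mz[keep] + k * ms_constants[["c13_delta"]])
        ints <- c(ints, (mono_int * ratio)[keep])
      }
      # tune-mix reference peaks: bright, stable across samples
      mzs <- c(mzs, tune_mix)
      ints <- c(ints, 5e6 * exp(stats::rnorm(length(tune_mix), 0, 0.02)))
      # unstructured noise peaks up to min_peaks
      n_noise <- max(0L, min_peaks - length(mzs))
      if (n_noise > 0) {
        mzs <- c(mzs, stats::runif(n_noise, 20, 1050))
        ints <- c(ints, exp(stats::rnorm(n_noise, log(300), 1)))
      }
      ms_spectrum(sm$sample_id[j], apply_drift(mzs), ints, polarity = "-")
    })
  })
}

# A compact catalogue of common polar metabolites (name, elemental formula)
# used to draw synthetic compound databases.
.METABOLITE_CATALOG <- data.frame(
  name = c("lactic acid", "pyruvic acid", "succinic acid", "fumaric acid",
           "malic acid", "citric acid", "alpha-ketoglutaric acid",
           "glucose", "fructose-6-phosphate", "glucose-6-phosphate",
           "glyceraldehyde-3-phosphate", "phosphoenolpyruvate",
           "ribose-5-phosphate", "glycine", "alanine", "serine", "proline",
           "valine", "threonine", "cysteine", "leucine", "isoleucine",
           "asparagine", "aspartic acid", "glutamine", "glutamic acid",
           "lysine", "methionine", "histidine", "phenylalanine", "arginine",
           "tyrosine", "tryptophan", "ornithine", "putrescine", "spermidine",
           "spermine", "S-adenosyl-methionine", "methylthioadenosine",
           "carnitine", "acetyl-carnitine", "choline", "betaine", "taurine",
           "creatine", "creatinine", "hypoxanthine", "xanthine", "uric acid",
           "adenine", "adenosine", "AMP", "ADP", "ATP", "guanine",
           "guanosine", "GMP", "uracil", "uridine", "UMP", "cytosine",
           "cytidine", "CMP", "NAD", "NADP", "glutathione",
           "glycerol-3-phosphate", "myo-inositol", "pantothenic acid",
           "nicotinamide"),
  formula = c("C3H6O3", "C3H4O3", "C4H6O4", "C4H4O4", "C4H6O5", "C6H8O7",
              "C5H6O5", "C6H12O6", "C6H13O9P", "C6H13O9P", "C3H7O6P",
              "C3H5O6P", "C5H11O8P", "C2H5NO2", "C3H7NO2", "C3H7NO3",
              "C5H9NO2", "C5H11NO2", "C4H9NO3", "C3H7NO2S", "C6H13NO2",
              "C6H13NO2", "C4H8N2O3", "C4H7NO4", "C5H10N2O3", "C5H9NO4",
              "C6H14N2O2", "C5H11NO2S", "C6H9N3O2", "C9H11NO2", "C6H14N4O2",
              "C9H11NO3", "C11H12N2O2", "C5H12N2O2", "C4H12N2", "C7H19N3",
              "C10H26N4", "C15H22N6O5S", "C11H15N5O3S", "C7H15NO3",
              "C9H17NO4", "C5H13NO", "C5H11NO2", "C2H7NO3S", "C4H9N3O2",
              "C4H7N3O", "C5H4N4O", "C5H4N4O2", "C5H4N4O3", "C5H5N5",
              "C10H13N5O4", "C10H14N5O7P", "C10H15N5O10P2", "C10H16N5O13P3",
              "C5H5N5O", "C10H13N5O5", "C10H14N5O8P", "C4H4N2O2",
              "C9H12N2O6", "C9H13N2O9P", "C4H5N3O", "C9H13N3O5",
              "C9H14N3O8P", "C21H27N7O14P2", "C21H28N7O17P3", "C10H17N3O6S",
              "C3H9O6P", "C6H12O6", "C9H17NO5", "C6H6N2O"),
  stringsAsFactors = FALSE
)

#' Generate a synthetic compound database
#'
#' Draws `n` compounds from a built-in catalogue of common polar metabolites
#' and computes their monoisotopic masses from the elemental formulas.
#'
#' @param n Number of compounds (capped at the catalogue size).
#' @param seed Integer seed.
#' @return data.frame with `compound_id`, `name`, `formula`,
#'   `monoisotopic_mass`.
#' @export
generate_compound_db <- function(n = 50, seed = 1) {
  stopifnot(n >= 1)
  n <- min(n, nrow(.METABOLITE_CATALOG))
  with_seed(seed, {
    idx <- sort(sample.int(nrow(.METABOLITE_CATALOG), n))
    db <- .METABOLITE_CATALOG[idx, , drop = FALSE]
    db$compound_id <- sprintf("CPD%04d", idx)
    db$monoisotopic_mass <- monoisotopic_mass(db$formula)
    rownames(db) <- NULL
    db[, c("compound_id", "name", "formula", "monoisotopic_mass")]
  })
}

#' Generate synthetic pathway definitions with one planted set
#'
#' Builds `n_sets` random pathways over the compound database; exactly one
#' pathway (`planted` in the result) consists of the supplied planted member
#' compounds, which downstream enrichment should recover.
#'
#' @param db Compound database from [generate_compound_db()].
#' @param n_sets Number of pathways.
#' @param set_size Members per random pathway.
#' @param planted_members Character vector of compound_ids forming the
#'   planted-enriched pathway; must all be present in `db`.
#' @param seed Integer seed.
#' @return List with `pathways` (named list of compound_id vectors) and
#'   `planted` (the planted pathway id).
#' @export
generate_pathways <- function(db, n_sets = 10, set_size = 8,
                              planted_members, seed = 1) {
  stopifnot(n_sets >= 1, set_size >= 1)
  if (!all(planted_members %in% db$compound_id)) {
    stop("planted_members must all be present in the compound database",
         call. = FALSE)
  }
  with_seed(seed, {
    pw <- lapply(seq_len(n_sets - 1), function(i) {
      sample(db$compound_id, min(set_size, nrow(db)))
    })
    names(pw) <- sprintf("PW%02d", seq_len(n_sets - 1))
    pw[["PW_planted"]] <- unique(planted_members)
    list(pathways = pw, planted = "PW_planted")
  })
}

#' Generate a synthetic lipidomics feature table
#'
#' Emulates the lipid fraction of the activation time course: per-class
#' trends (PC, TAG, HexCer rising; LPC/LPE/PE transient; SM slowly falling)
#' and a planted phosphatidylcholine saturation shift in which the
#' polyunsaturated (>= 4 double bonds) share of total PC intensity declines
#' linearly from `polyunsat_start` at 0 h to `polyunsat_end` at 48 h and
#' stays there.
#'
#' Besides the annotated species the table carries `n_filler` unannotated
#' flat features (real lipid tables hold on the order of a thousand features
#' beyond the annotated species); they give the quantile normalization a
#' realistic, dense intensity distribution, without which within-sample
#' ratios such as the saturation fractions would be distorted.
#'
#' @param design A `study_design`.
#' @param noise_cv Multiplicative intensity noise.
#' @param polyunsat_start,polyunsat_end Planted polyunsaturated PC fraction
#'   at 0 h and from 48 h on (defaults 0.60 and 0.25).
#' @param n_filler Unannotated background features (default 300).
#' @param seed Integer seed.
#' @return List with `table` (a `feature_table`), `annotations` (data.frame
#'   feature_id, lipid_name) and `truth` (planted per-time polyunsaturated
#'   fraction).
#' @export
generate_lipid_table <- function(design = study_design(),
                                 noise_cv = 0.1,
                                 polyunsat_start = 0.60,
                                 polyunsat_end = 0.25,
                                 n_filler = 300,
                                 seed = 1) {
  species <- data.frame(
    lipid_name = c("PC 32:0",
                   "PC 34:1", "PC 34:2", "PC 32:1", "PC 16:0_18:1",
                   "PC 36:3", "PC 34:3",
                   "PC 36:4", "PC 38:4", "PC 16:0_20:4", "PC 18:0_20:4",
                   "PC 38:6",
                   "LPC 16:0", "LPC 18:1", "LPE 18:0",
                   "PE 34:1", "PE 36:2",
                   "SM 34:1", "SM 42:2",
                   "TAG 52:2", "TAG 54:3",
                   "HexCer 42:1"),
    stringsAsFactors = FALSE
  )
  parsed <- lapply(species$lipid_name, parse_lipid_name)
  species$class <- vapply(parsed, `[[`, "", "lipid_class")
  species$db <- vapply(parsed, `[[`, 0L, "total_double_bonds")
  is_pc <- species$class == "PC"
  polyunsat <- is_pc & species$db >= 4
  # within-class intensity weights for the non-polyunsaturated PC pool
  pc_weight <- ifelse(species$db == 0, 0.10,
                      ifelse(species$db <= 2, 0.75 / 5, 0.15 / 2))

  class_trend <- function(cls, t) {
    switch(cls,
      PC     = 1 + t / 48,
      TAG    = 1 + 1.5 * t / 96,
      HexCer = 1 + t / 96,
      LPC    = ,
      LPE    = ,
      PE     = 1 + exp(-(t - 48)^2 / (2 * 16^2)),
      SM     = 1 - 0.3 * t / 96,
      1
    )
  }
  frac_poly <- function(t) {
    polyunsat_start - (polyunsat_start - polyunsat_end) * pmin(t, 48) / 48
  }

  sm <- design$samples
  sdlog <- log(1 + noise_cv)
  base_total <- c(PC = 1e6, LPC = 8e4, LPE = 5e4, PE = 2e5, SM = 3e5,
                  TAG = 6e5, HexCer = 1e5)

  with_seed(seed, {
    inten <- matrix(0, nrow(species), nrow(sm))
    for (j in seq_len(nrow(sm))) {
      t_h <- if (sm$is_blank[j]) 0 else sm$time_h[j]
      lev <- numeric(nrow(species))
      for (cls in unique(species$class)) {
        rows <- which(species$class == cls)
        total <- base_total[[cls]] * class_trend(cls, t_h)
        if (cls == "PC") {
          fp <- frac_poly(t_h)
          lev[rows[polyunsat[rows]]] <-
            total * fp / sum(polyunsat[rows])
          npoly <- rows[!polyunsat[rows]]
          w <- pc_weight[npoly] / sum(pc_weight[npoly])
          lev[npoly] <- total * (1 - fp) * w
        } else {
          lev[rows] <- total / length(rows)
        }
      }
      if (sm$is_blank[j]) lev <- lev * 0.02
      eps <- if (sdlog > 0) stats::rnorm(nrow(species), 0, sdlog) else 0
      inten[, j] <- lev * exp(eps)
    }
    if (n_filler > 0) {
      base <- exp(stats::rnorm(n_filler, log(2e5), 1.2))
      fill <- matrix(base, n_filler, nrow(sm)) *
        exp(matrix(stats::rnorm(n_filler * nrow(sm), 0, sdlog),
                   n_filler, nrow(sm)))
      inten <- rbind(inten, fill)
    }
    feats <- data.frame(
      feature_id = c(sprintf("L%04d", seq_len(nrow(species))),
                     if (n_filler > 0) sprintf("LB%04d", seq_len(n_filler))),
      mz = 400 + seq_len(nrow(species) + n_filler) * 1.73  # placeholder m/z
    )
    list(
      table = feature_table(inten, feats, sm),
      annotations = data.frame(
        feature_id = feats$feature_id[seq_len(nrow(species))],
        lipid_name = species$lipid_name,
        stringsAsFactors = FALSE),
      truth = list(time_points = design$time_points,
                   polyunsat_frac = frac_poly(design$time_points))
    )
  })
}

#' Plant compound annotations linking features to a pathway ground truth
#'
#' Connects the feature-level ground truth to the compound database for
#' enrichment testing: each compound of the planted pathway is annotated onto
#' a distinct trended feature (so its importance in a PLS-loading ranking is
#' high), and background compounds are annotated onto flat above-blank
#' features. Requires the truth to contain at least as many trended features
#' as planted members and as many flat above-blank features as background
#' compounds.
#'
#' @param truth A `synthetic_truth`.
#' @param db Compound database from [generate_compound_db()].
#' @param planted_members Compound ids forming the planted pathway.
#' @param n_background Number of background compounds annotated onto flat
#'   features (default: all remaining db compounds that fit).
#' @param seed Integer seed.
#' @return data.frame `feature_id`, `compound_id` usable wherever
#'   [annotate_features()] output is expected.
#' @export
plant_annotations <- function(truth, db, planted_members,
                              n_background = NULL, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            all(planted_members %in% db$compound_id))
  feats <- truth$features
  trended <- feats$feature_id[feats$trend_class != "flat"]
  flat_ab <- feats$feature_id[feats$trend_class == "flat" & feats$above_blank]
  if (length(trended) < length(planted_members)) {
    stop("fewer trended features than planted pathway members", call. = FALSE)
  }
  background <- setdiff(db$compound_id, planted_members)
  if (is.null(n_background)) {
    n_background <- min(length(background), length(flat_ab))
  }
  if (length(flat_ab) < n_background) {
    stop("fewer flat above-blank features than background compounds; ",
         "raise frac_above_blank above frac_trend", call. = FALSE)
  }
  with_seed(seed, {
    rbind(
      data.frame(feature_id = sample(trended, length(planted_members)),
                 compound_id = planted_members, stringsAsFactors = FALSE),
      data.frame(feature_id = sample(flat_ab, n_background),
                 compound_id = sample(background, n_background),
                 stringsAsFactors = FALSE)
    )
  })
}
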