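# Shared fixture builders: all synthetic, constructed in code at test time.

# Minimal feature table: X is features x samples; sample layout given by
# parallel vectors. Feature m/z default to an arbitrary ascending grid.
tiny_table <- function(X, time_h, replicate = NULL, is_blank = NULL,
                       mz = NULL) {
  X <- as.matrix(X)
  n_s <- ncol(X)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(n_s), time_h, FUN = seq_along)
  }
  if (is.null(is_blank)) is_blank <- rep(FALSE, n_s)
  if (is.null(mz)) mz <- 100 + seq_len(nrow(X)) * 10
  feature_table(
    X,
    data.frame(feature_id = sprintf("F%03d", seq_len(nrow(X))), mz = mz),
    data.frame(
      sample_id = sprintf("s%02d", seq_len(n_s)),
      time_h = ifelse(is_blank, NA_real_, time_h),
      replicate = replicate, is_blank = is_blank
    )
  )
}

# Feature table following the default 9 x 3 + 3-blank design, values supplied
# per feature as a function of (time_h, is_blank).
design_table <- function(value_fn_list) {
  d <- study_design()
  sm <- d$samples
  X <- t(vapply(value_fn_list, function(f) {
    vapply(seq_len(nrow(sm)), function(j) f(sm$time_h[j], sm$is_blank[j]),
           numeric(1))
  }, numeric(nrow(sm))))
  tiny_table(X, sm$time_h, sm$replicate, sm$is_blank)
}

spec1 <- function(mz, intensity, id = "s1", polarity = "-") {
  ms_spectrum(id, mz, intensity, polarity)
}

# 50 canonical lipid shorthand names covering all classes, both species-level
# and chain-resolved forms.
canonical_lipid_names <- function() {
  species <- c(
    sprintf("PC %d:%d", seq(30, 40, 2), c(0, 1, 2, 3, 4, 6)),
    sprintf("PE %d:%d", seq(32, 40, 2), c(0, 1, 2, 4, 5)),
    sprintf("SM %d:%d", seq(32, 42, 2), c(1, 1, 2, 2, 3, 1)),
    sprintf("TAG %d:%d", seq(48, 58, 2), c(1, 2, 3, 2, 4, 5)),
    sprintf("LPC %d:%d", seq(14, 22, 2), c(0, 0, 1, 1, 4)),
    sprintf("LPE %d:%d", seq(16, 22, 2), c(0, 1, 1, 4)),
    sprintf("HexCer %d:%d", seq(34, 42, 2), c(1, 1, 2, 1, 2))
  )
  chains <- c("PC 16:0_18:1", "PC 16:0_20:4", "PC 18:0_20:4", "PC 18:1_18:2",
              "PE 16:0_22:6", "PE 18:0_18:1", "TAG 16:0_18:1_18:2",
              "TAG 18:1_18:1_18:1", "LPC 20:4", "PC 18:2_18:2",
              "PE 18:2_20:4", "PC 14:0_16:0", "SM 18:1_24:1",
              "TAG 16:0_16:0_18:1")
  c(species, chains)[1:50]
}
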