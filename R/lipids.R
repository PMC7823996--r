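# Lipid shorthand parsing, class profiles over time, phosphatidylcholine
# saturation binning, and filtering by constituent fatty acyl chain.

.LIPID_CLASSES <- c("LPC", "LPE", "PC", "PE", "SM", "TAG", "HexCer")

#' Parse lipid shorthand nomenclature
#'
#' Accepts species-level names (`"PC 36:4"`) and chain-resolved names
#' (`"PC 16:0_20:4"`, up to three chains). For chain-resolved names the total
#' carbons and double bonds are the chain sums. Classes outside the known set
#' (LPC, LPE, PC, PE, SM, TAG, HexCer) are kept with `lipid_class = "other"`
#' and a warning; ether/oxidized modifiers are outside the grammar.
#'
#' @param name Lipid shorthand string.
#' @return A `lipid_species` list: `lipid_class`, `class_label`,
#'   `total_carbons`, `total_double_bonds`, `acyl_chains` (data.frame or
#'   NULL).
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regexec("^([A-Za-z]+) (\\d+:\\d+(?:_\\d+:\\d+){0,2})$", name)
  g <- regmatches(name, m)[[1]]
  if (length(g) == 0) {
    # locate first offending position for the error message
    ok <- regexpr("^[A-Za-z]+ \\d", name)
    pos <- if (ok == -1) 1L else attr(ok, "match.length") + 1L
    stop(sprintf("malformed lipid name '%s' (near position %d)", name, pos),
         call. = FALSE)
  }
  cls <- g[2]
  chains_txt <- strsplit(g[3], "_", fixed = TRUE)[[1]]
  cd <- do.call(rbind, lapply(chains_txt, function(s) {
    as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  }))
  chains <- data.frame(carbons = cd[, 1], double_bonds = cd[, 2])
  known <- cls %in% .LIPID_CLASSES
  if (!known) warning("unknown lipid class '", cls, "'; treated as 'other'")
  structure(
    list(lipid_class = if (known) cls else "other",
         class_label = cls,
         total_carbons = sum(chains$carbons),
         total_double_bonds = sum(chains$double_bonds),
         acyl_chains = if (nrow(chains) > 1) chains else NULL),
    class = "lipid_species"
  )
}

#' Format a lipid species back to canonical shorthand
#'
#' Inverse of [parse_lipid_name()] on canonical names.
#'
#' @param species A `lipid_species`.
#' @return Character shorthand.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (is.null(species$acyl_chains)) {
    sprintf("%s %d:%d", species$class_label,
            species$total_carbons, species$total_double_bonds)
  } else {
    sprintf("%s %s", species$class_label,
            paste(sprintf("%d:%d", species$acyl_chains$carbons,
                          species$acyl_chains$double_bonds),
                  collapse = "_"))
  }
}

# Parse annotations and return a per-feature data.frame of lipid attributes,
# restricted to features present in the table.
lipid_annotation_frame <- function(table, annotations) {
  stopifnot(all(c("feature_id", "lipid_name") %in% names(annotations)))
  ann <- annotations[annotations$feature_id %in% table$features$feature_id, ]
  parsed <- lapply(ann$lipid_name, parse_lipid_name)
  data.frame(
    feature_id = ann$feature_id,
    lipid_name = ann$lipid_name,
    lipid_class = vapply(parsed, `[[`, "", "lipid_class"),
    total_double_bonds = vapply(parsed, `[[`, 0L, "total_double_bonds"),
    chain_resolved = !vapply(parsed, function(p) is.null(p$acyl_chains),
                             logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Summed class intensity over the time course
#'
#' Per lipid class and time point: the mean over replicates of the per-sample
#' sum of member-species intensities. Intended for RAW (non-quantile-
#' normalized) intensities, since absolute class totals track cell size.
#' Classes with no annotated species are omitted with a warning (from the
#' parser) only if their names are malformed; blanks are excluded.
#'
#' @param table A `feature_table` with raw intensities.
#' @param annotations data.frame `feature_id`, `lipid_name`.
#' @return Tidy data.frame: `lipid_class`, `time_h`, `intensity`.
#' @export
sum_by_class <- function(table, annotations) {
  stopifnot(inherits(table, "feature_table"))
  ann <- lipid_annotation_frame(table, annotations)
  tab <- ft_drop_blanks(table)
  sm <- tab$samples
  out <- list()
  for (cls in unique(ann$lipid_class)) {
    rows <- match(ann$feature_id[ann$lipid_class == cls],
                  tab$features$feature_id)
    per_sample <- colSums(tab$intensity[rows, , drop = FALSE])
    agg <- tapply(per_sample, sm$time_h, mean)
    out[[cls]] <- data.frame(lipid_class = cls,
                             time_h = as.numeric(names(agg)),
                             intensity = as.numeric(agg))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phosphatidylcholine saturation profile over time
#'
#' Bins PC species by total double bonds into {0, 1-2, 3, >= 4} and reports,
#' per time point, each bin's fraction of total PC intensity (mean over
#' replicates of the per-sample fractions; fractions sum to 1 at every time
#' point). Intended for quantile-normalized intensities; the fraction is
#' scale-free. The polyunsaturated bin (">=4") declining over activation is
#' the hallmark of the membrane remodeling this profile is designed to show.
#'
#' @param table A `feature_table` (quantile-normalized).
#' @param annotations data.frame `feature_id`, `lipid_name`.
#' @return Tidy data.frame: `bin` (factor "0", "1-2", "3", ">=4"), `time_h`,
#'   `fraction`.
#' @export
pc_saturation_profile <- function(table, annotations) {
  stopifnot(inherits(table, "feature_table"))
  ann <- lipid_annotation_frame(table, annotations)
  ann <- ann[ann$lipid_class == "PC", , drop = FALSE]
  if (nrow(ann) == 0) stop("no PC-annotated features in table", call. = FALSE)
  bins <- c("0", "1-2", "3", ">=4")
  db <- ann$total_double_bonds
  bin <- ifelse(db == 0, "0", ifelse(db <= 2, "1-2",
                                     ifelse(db == 3, "3", ">=4")))
  tab <- ft_drop_blanks(table)
  rows <- match(ann$feature_id, tab$features$feature_id)
  X <- tab$intensity[rows, , drop = FALSE]
  bin_sum <- rowsum(X, group = factor(bin, levels = bins))
  # bins with no species contribute zero intensity
  missing_bins <- setdiff(bins, rownames(bin_sum))
  if (length(missing_bins)) {
    zero <- matrix(0, length(missing_bins), ncol(bin_sum),
                   dimnames = list(missing_bins, colnames(bin_sum)))
    bin_sum <- rbind(bin_sum, zero)[bins, , drop = FALSE]
  }
  frac <- sweep(bin_sum, 2, colSums(bin_sum), "/")   # per-sample fractions
  sm <- tab$samples
  out <- list()
  for (b in rownames(frac)) {
    agg <- tapply(frac[b, ], sm$time_h, mean)
    out[[b]] <- data.frame(bin = b, time_h = as.numeric(names(agg)),
                           fraction = as.numeric(agg))
  }
  res <- do.call(rbind, out)
  res$bin <- factor(res$bin, levels = bins)
  rownames(res) <- NULL
  res
}

#' Filter lipid species by a constituent fatty acyl chain
#'
#' Restricts the table to chain-resolved species whose acyl chains contain
#' the requested fatty acid (e.g. `c(20, 4)` for FA 20:4, arachidonic acid)
#' and returns their per-species time profiles (mean over replicates).
#' Chain-resolved annotations typically come from negative-mode formate
#' adducts of PCs (`[M+HCOO]-`, neutral mass + 44.998204 Da).
#'
#' @param table A `feature_table` (quantile-normalized).
#' @param annotations data.frame `feature_id`, `lipid_name`.
#' @param fa Length-2 integer vector `(carbons, double_bonds)`.
#' @return Tidy data.frame: `feature_id`, `lipid_name`, `time_h`,
#'   `intensity`. Zero rows if no species contains the chain.
#' @export
filter_by_fatty_acid <- function(table, annotations, fa) {
  stopifnot(inherits(table, "feature_table"), length(fa) == 2)
  ann <- lipid_annotation_frame(table, annotations)
  if (!any(ann$chain_resolved)) {
    stop("no chain-resolved lipid annotations (names like 'PC 16:0_20:4'); ",
         "species-level names cannot be filtered by fatty acid",
         call. = FALSE)
  }
  ann <- ann[ann$chain_resolved, , drop = FALSE]
  has_fa <- vapply(ann$lipid_name, function(nm) {
    ch <- parse_lipid_name(nm)$acyl_chains
    any(ch$carbons == fa[1] & ch$double_bonds == fa[2])
  }, logical(1))
  ann <- ann[has_fa, , drop = FALSE]
  tab <- ft_drop_blanks(table)
  sm <- tab$samples
  out <- list()
  for (i in seq_len(nrow(ann))) {
    row <- match(ann$feature_id[i], tab$features$feature_id)
    agg <- tapply(tab$intensity[row, ], sm$time_h, mean)
    out[[i]] <- data.frame(feature_id = ann$feature_id[i],
                           lipid_name = ann$lipid_name[i],
                           time_h = as.numeric(names(agg)),
                           intensity = as.numeric(agg))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(0), lipid_name = character(0),
               time_h = numeric(0), intensity = numeric(0))
  rownames(res) <- NULL
  res
}
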