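#' @keywords internal
"_PACKAGE"

# Monoisotopic atomic masses (IUPAC 2021), Da.
.MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069,
  Na = 22.98976928,
  K = 38.96370649,
  Cl = 34.96885268,
  F = 18.99840316
)

#' Physical constants used for adduct and isotopologue arithmetic
#'
#' `proton_mass` is the mass of a proton in Da (used for \[M+H\]+ / \[M-H\]-
#' adducts), `c13_delta` the mass difference between consecutive 13C
#' isotopologues, `c13_abundance` the natural abundance of 13C, and
#' `formate_delta` the neutral-mass offset of a formate adduct \[M+HCOO\]-.
#'
#' @format Named numeric vector.
#' @export
ms_constants <- c(
  proton_mass   = 1.007276,
  c13_delta     = 1.00335,
  c13_abundance = 0.0107,
  formate_delta = 44.998204  # HCOOH (46.005480) - proton
)

#' Parse an elemental formula into element counts
#'
#' Accepts Hill-style formulas such as `"C6H12O6"`. Element symbols are one
#' uppercase letter optionally followed by a lowercase letter; a missing count
#' means 1.
#'
#' @param formula Character scalar, e.g. `"C3H6O3"`.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C3H6O3")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  unknown <- setdiff(el, names(.MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " in formula ", formula, call. = FALSE)
  }
  counts <- tapply(cnt, el, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts[order(names(counts))]
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")    # 18.01056
#' monoisotopic_mass("C3H6O3") # 90.03169 (lactic acid)
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    cnt <- parse_formula(f)
    sum(.MONOISOTOPIC_MASS[names(cnt)] * cnt)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Expected 13C isotopologue intensity ratio
#'
#' For a molecule with `n_carbons` carbon atoms, the intensity of the M+k
#' isotopologue relative to the monoisotopic peak under a binomial model of
#' independent 13C substitutions is `choose(n, k) * (p/(1-p))^k` with
#' p the 13C natural abundance.
#'
#' @param n_carbons Number of carbon atoms.
#' @param k Isotopologue index (1 = M+1).
#' @param abundance 13C natural abundance (default 0.0107).
#' @return Expected I(M+k)/I(M) ratio.
#' @export
isotope_ratio <- function(n_carbons, k = 1L,
                          abundance = ms_constants[["c13_abundance"]]) {
  choose(n_carbons, k) * (abundance / (1 - abundance))^k
}

#' Adduct m/z for a neutral monoisotopic mass
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param adduct One of `"[M+H]+"`, `"[M-H]-"`, `"[M+HCOO]-"`.
#' @return Expected ion m/z.
#' @export
adduct_mz <- function(mass, adduct = c("[M+H]+", "[M-H]-", "[M+HCOO]-")) {
  adduct <- match.arg(adduct)
  switch(adduct,
    "[M+H]+"    = mass + ms_constants[["proton_mass"]],
    "[M-H]-"    = mass - ms_constants[["proton_mass"]],
    "[M+HCOO]-" = mass + ms_constants[["formate_delta"]]
  )
}
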