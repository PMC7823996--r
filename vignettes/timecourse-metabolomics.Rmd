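---
title: "Time-course metabolomics of T cell activation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-course metabolomics of T cell activation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodyn)
```

## The experimental setting this package models

`metabodyn` processes and analyses time-resolved untargeted metabolomics of
CD8+ T cell activation: naive T cells are activated in vitro and sampled
every 12 h for 96 h (9 time points, 3 biological replicates), together with
a sterile-well blank (medium without cells). Aliquots of the same extracts
are measured by flow injection analysis (FIA) MS1 — no chromatography, one
composite spectrum per sample — and by LC-MS; this package implements the
FIA MS1 processing chain and the statistics applied downstream of any
feature table.

Every stage is exercised on synthetic data with embedded ground truth, so
the pipeline is testable end to end without any instrument data.

## FIA MS1 processing

Each sample's centroided spectrum passes through:

1. **Quadratic mass recalibration.** The spectrum contains bright tune-mix
   peaks at known reference masses. Each reference is matched to the most
   intense peak within 0.05 Da (intensity, not proximity, disambiguates
   against chance background peaks near a lock mass). The mass error
   (observed − reference) is fitted as a quadratic polynomial of the
   reference mass by least squares; correcting an arbitrary peak requires
   the polynomial at its (unknown) true mass, which is obtained by
   fixed-point iteration — the drift is a few mDa, so three iterations
   converge far below 1e-9 Da. On noise-free quadratic drift the planted
   coefficients are recovered exactly, and the correction is idempotent.
2. **Reference normalization.** Intensities are divided by the summed
   tune-mix signal, removing global sensitivity differences between
   injections.
3. **Top-1000 peak detection**, with the tie at rank 1000 broken toward the
   lower m/z for determinism.
4. **Consensus features.** Detected peaks from all samples are pooled,
   sorted and clustered by single linkage: adjacent peaks join when their
   gap is below 5 ppm. The tolerance is a package default chosen for a
   QTOF at >50,000 resolution and is configurable; each sample contributes
   at most one (its most intense) peak per cluster, and the representative
   m/z is the intensity-weighted mean.
5. **Gap filling.** For each (feature, sample) without a detected member
   peak, the processed spectrum is re-queried and all raw peaks within
   5 ppm of the representative m/z are summed; truly absent signals become
   0, so the table has no missing entries.
6. **Isotopologue collapsing.** Chains are grown from the lowest m/z: a
   feature joins when its spacing from the chain tail is within 0.005 Da of
   1.00335 Da (one 13C substitution) and the median across samples of its
   intensity ratio to the tail is positive and "carbon-plausible". The
   plausibility bound is 1.5 × 0.0107 × (m/12): 1.5 times the expected M+1
   ratio of a molecule made entirely of carbon, a deliberately conservative
   upper bound (few metabolites have more carbons than m/12, and the safety
   factor absorbs intensity noise). A chain is replaced by one feature at
   the monoisotopic m/z whose per-sample intensity is the sum over members,
   so total signal is conserved exactly; keeping only the monoisotopic
   intensities is available behind the `keep` flag. Chance chains among
   background features do occur — the spacing criterion cannot forbid them
   — but the audit trail (`attr(, "chains")`) shows every merge, and the
   tests verify that no chain with implausible spacing is ever collapsed
   and that planted features survive unmerged.
7. **Exact-mass annotation** against a compound database, assuming [M+H]+
   in positive and [M−H]− in negative mode (proton mass 1.007276 Da),
   within a 3 mDa default tolerance (the wide annotation setting typical
   for QTOF work; 1 mDa is the narrow alternative). A feature may carry
   zero, one or several candidate compounds; multi-annotation is preserved
   deliberately because several metabolites can share a sum formula.

## Blank filtering and normalization

Feature tables are quantile normalized — every column is forced onto the
across-column mean of order statistics — to compensate for the large change
in cell size (and hence total metabolite content) over activation. Ties
receive the mean of the quantile values they span; gap-filled zeros
participate as ordinary values because they are informative. The
computation is delegated to `limma::normalizeQuantiles(ties = TRUE)`.
Blanks are normalized together with the samples and excluded downstream of
the filter.

The above-blank filter then runs, per feature and per time point, a
one-tailed equal-variance two-sample t-test of the cell replicates against
the blank replicates; a feature is kept if any time point has p < 0.05
(uncorrected — this is a permissive detection filter, not an inference).
When the pooled variance is exactly zero (possible after quantile
normalization) the statistic is ±Inf or 0 according to the mean difference.
The generator provides 3 blank replicates: a typical culture design has a
single sterile well, but a two-sample test needs at least two observations
per group, so the blank is modeled as replicated — a documented stand-in.

## Ordination

* **PCA** on square-root-scaled intensities (squashing the dominance of
  high-intensity features), feature-centered, via SVD.
* **PLS** with sampling time (hours) as the predicted variable, on
  log-scaled intensities. PLS1 is implemented as NIPALS with the weight
  vector started from the response, so the result is deterministic — no
  random initialization. When zeros are present the log uses an offset of
  +1 (natural log otherwise). The explained variance reported per component
  is the fraction of time variance captured.

Both orient each component so that the mean score at 96 h is at least the
mean score at 0 h, a sign convention that makes plots reproducible.
Feature importance for downstream enrichment is the sum over the first two
components (the two that are plotted) of absolute loadings; with time as
the response, a large absolute loading means a large contribution to
time-dependent change.

## Time-trend testing

Each feature is tested for any time trend: a Gaussian fit of intensity on a
natural cubic spline basis of time with 4 degrees of freedom against an
intercept-only null. The spline is unpenalized with fixed df — with 9 time
points at most 8 df are identifiable, and a fixed basis makes the test
degrees of freedom exact, unlike a penalized smoother whose effective df
are data-dependent. The statistic reported is the likelihood ratio
2ΔlogL = n·log(RSS0/RSS1).

P-values default to the exact F reference for nested Gaussian linear
models. The asymptotic chi-square reference (available via
`reference = "chisq"`) rejects about 9% of truly flat features at nominal
5% with n = 27 samples — the likelihood-ratio chi-square approximation is
anti-conservative at this sample size — whereas the F reference is exactly
calibrated under Gaussian errors, and empirically holds its level (within
Monte-Carlo error) under the generator's multiplicative log-normal noise.
Significance is Bonferroni-corrected for the number of features tested,
matching the "significant time trend" accounting convention: percentages
are quoted on the full feature count, and the ratio of the trend percentage
to the above-blank percentage summarizes how much of the detectable
metabolome changes.

The null model is intercept-only, giving the test its "any time trend"
semantics; testing against a linear-in-time null instead would ask a
different question (non-linearity) and is intentionally not the default.

## Metabolite set enrichment

Feature importances are expanded to metabolites through the annotations:
each (feature, candidate compound) pair propagates the feature's importance
to the compound, and a compound hit by several features keeps the maximum
(avoiding double counting while retaining the strongest evidence; `sum` is
available). The enrichment itself is the weighted Kolmogorov–Smirnov
running sum with weight exponent 1, a member-label permutation null
(n = 1000), the +1-corrected permutation p-value (so p is never 0 and never
below 1/(n_perm+1)), and NES = ES divided by the mean absolute same-sign
null ES. Pathways with fewer than 3 ranked members are dropped as
degenerate. All of these are configurable, since no single canonical
parameterization of rank-based set enrichment exists.

## Lipid analytics

The shorthand grammar covers `CLASS C:D` and chain-resolved
`CLASS C1:D1_C2:D2[_C3:D3]` over the classes LPC, LPE, PC, PE, SM, TAG and
HexCer; anything else (including ether/oxidized modifiers) parses as
`other` with a warning rather than an error. Class totals over time use raw
intensities (absolute class totals track cell size, which is the point of
that display); phosphatidylcholine saturation fractions use
quantile-normalized intensities and are intensity-weighted (per-sample bin
fraction, then the replicate mean; a species-count weighting would answer a
different question). The double-bond bins {0, 1–2, 3, ≥4} complete the
partition around the biologically salient categories (mono/di-unsaturated
accumulating, polyunsaturated ≥4 depleting). Chain-level filtering (e.g.
all species containing FA 20:4) requires chain-resolved names, which in
practice come from negative-mode formate adducts ([M+HCOO]−, +44.998204 Da
relative to the neutral mass).

## The synthetic-data generator

The generator emulates the study conditions: 9 time points every 12 h, 3
replicates, 3 blank replicates, a 5-mass tune-mix series, planted monotone
(logistic in time, matching plateauing profiles) and transient (Gaussian
bump) trends, isotope chains at +k × 1.00335 Da with binomial 13C intensity
ratios, quadratic mass drift (defaults a = 2e−3, b = 5e−6, c = 1e−9,
i.e. a few mDa across the scan range), and multiplicative log-normal noise
with CV 0.1. Half the features are above blank (above-blank features
appear in blanks at 5% of base intensity; the rest are "medium-derived",
equally intense in blanks and cells, and flat). Trend amplitudes are drawn
uniformly from 1–3 relative units (a doubling to a quadrupling), large
against the 10% noise so that detection power, not noise modeling, is what
the tests probe. The lipid generator plants the polyunsaturated PC fraction
declining linearly from 0.60 to 0.25 over the first 48 h and flat
thereafter, and surrounds the 22 annotated species with 300 unannotated
filler features so that quantile normalization operates on a realistically
dense intensity distribution (with only a couple dozen values per column
the mapping to shared order statistics visibly distorts within-sample
ratios).

What the generator does **not** emulate: chromatographic peak shapes and
retention time (FIA only), profile-mode spectra, MS2 fragmentation, charge
states above 1, adducts beyond M±H and formate, correlated noise between
features, batch effects, and missingness mechanisms other than
falling below the top-1000 detection threshold. Passing tests therefore
demonstrate the correctness of the computations under these idealized
conditions, not robustness to every artifact of real instrument data.

## Problem sizes and evaluation scenarios

The shipped tests and the acceptance script use 200-feature tables (the
real per-method tables have 1500–2500), 2000 features for the type-I
calibration, 100 repeated null data sets for the family-wise error
estimate, spectra of ~1100 peaks across 30 samples for the end-to-end run,
a 60-compound database with 10 pathways of size 8 for enrichment, and the
22-species (+300 filler) lipid table. For the ranking and enrichment
scenarios the generator is run with `frac_trend = 0.5` and
`frac_above_blank = 0.75`: with equal fractions every above-blank feature
would be trended and the "do planted trends dominate the ranking" question
would be vacuous; the 0.75 setting leaves 50 flat above-blank features to
serve as background for both the top-decile check and the background
pathway compounds.

## Known limitations

* The blank filter assumes equal variances between blank and cells on the
  quantile-normalized scale; heavy heteroscedasticity would call for
  Welch's test, which this permissive detection filter deliberately does
  not use.
* The LRT treats replicates as independent observations; a mixed-effects
  formulation with a replicate random effect is out of scope.
* Isotope collapsing is greedy and ascending; a globally optimal chain
  decomposition could differ on pathological inputs.
* FDR control is not offered for the trend test (Bonferroni only), matching
  the accounting convention it reproduces.
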