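# metabodyn

Time-course metabolomics processing and statistics for T cell activation
studies.

When naive CD8+ T cells are activated they remodel their metabolome within
days. Resolving those dynamics takes dense time sampling (here: every 12 h
for 96 h, 3 biological replicates, plus a sterile-well blank) and several
MS methods in parallel — flow injection analysis (FIA) for a fast,
chromatography-free overview, and LC-MS for higher-confidence annotation.
`metabodyn` implements the computational side of such a study as a tested,
reusable R pipeline:

* **FIA MS1 feature extraction** — quadratic lock-mass recalibration from
  tune-mix peaks, reference-signal normalization, top-1000 peak detection,
  cross-sample consensus features (5 ppm single linkage), gap filling from
  the raw spectra, collapsing of ¹³C isotopologue chains (spacing
  1.00335 Da, carbon-plausible intensity ratios), and exact-mass
  annotation as [M+H]⁺/[M−H]⁻ against a compound database.
* **Preprocessing** — quantile normalization (compensating the change in
  cell size over activation) and an above-blank filter: per feature and
  time point, a one-tailed equal-variance t-test of cell replicates
  against blank replicates, keeping features with p < 0.05 at any time
  point.
* **Time-course statistics** — PCA on square-root-scaled intensities; PLS
  with sampling time as the predicted variable (deterministic NIPALS on
  log intensities), whose summed absolute loadings rank features by their
  contribution to time-dependent change; and a per-feature likelihood
  ratio test of a natural cubic spline of time (df = 4) against an
  intercept-only null, Bonferroni-corrected.
* **Pathway enrichment** — feature importances expanded to annotated
  metabolites (multi-annotation aware) and a weighted Kolmogorov–Smirnov
  running-sum enrichment with a member-label permutation null.
* **Lipid analytics** — lipid shorthand parsing (`PC 36:4`,
  `PC 16:0_20:4`), summed class profiles over time, phosphatidylcholine
  saturation binning by double bonds {0, 1–2, 3, ≥4}, and filtering by
  constituent fatty acyl chain.
* **Synthetic data with ground truth** — a first-class generator that
  emulates the study design (planted monotone/transient trends, isotope
  chains, quadratic mass drift, log-normal noise, tune mix, blanks) so
  every stage above is testable without instrument data.

The statistical core in the field's notation: a feature is *above blank*
if min over time points t of P(T ≥ t_obs) < 0.05 for the pooled-variance
one-tailed t statistic; a feature has a *time trend* if the LRT statistic
2ΔlogL = n·log(RSS₀/RSS₁) for intensity ~ ns(time, df = 4) vs intensity ~ 1
is significant at α/n_features (p-values from the exact F reference for
nested Gaussian models); the enrichment score of pathway S is the extreme
of the running sum that climbs |r_j|/Σ_{S}|r| at members and falls
1/(N−|S|) elsewhere.

## Worked example

```r
library(metabodyn)

design <- study_design()                      # 9 x 12 h, 3 reps, 3 blanks
sim <- generate_feature_table(design, n_features = 200, frac_trend = 0.5,
                              frac_above_blank = 0.75, noise_cv = 0.1,
                              seed = 7)
spectra <- generate_fia_spectra(sim$truth, seed = 7)
spectra[[1]]
#> spectrum t000_r1 (- mode): 1100 peaks, m/z 21.5196-1048.8539

tab <- fia_process(spectra, design$samples)   # recalibrate .. collapse
tab
#> feature_table: 11866 features x 30 samples (27 cell, 3 blank), 9 time points

norm <- quantile_normalize(sim$table)
bf <- above_blank_filter(norm)
bf
#> blank filter (alpha = 0.05): 135 / 200 features above blank

above <- filter_above_blank(norm, bf)
trends <- time_trend_lrt(ft_drop_blanks(above))
sum(trends$significant)
#> [1] 100

pls <- pls_time(ft_drop_blanks(above))
pls
#> PLS ordination (log scale): 27 samples x 2 components
#> explained variance: 91.8%, 6.1%

head(rank_features_by_loading(pls), 3)
#>   feature_id importance
#> 1      F0127  0.3674699
#> 2      F0007  0.3439873
#> 3      F0010  0.3423883
```

The 200 simulated features contain 100 planted trends; the blank filter
keeps 135 of the 150 planted above-blank features, the spline LRT flags
exactly the 100 trended ones, and PLS component 1 (91.8% of time variance)
ranks trended features at the top.

The per-method accounting table of the underlying study ships with the
package:

```r
run_accounting_report()
#>            method polarity n_features pct_above_blank pct_above_blank_with_trend pct_trend_among_above_blank
#>               FIA        -       1887            44.4                       31.0                        69.8
#>               FIA        +       2416            52.7                       28.4                        53.9
#>     LC-QTOF HILIC        -       1671            31.2                       26.3                        84.3
#>  LC-QTOF Polar RP        +       1549            32.8                       25.8                        78.7
#>    LC-QTOF Lipids        -       1745            57.9                       53.4                        92.2
#>    LC-QTOF Lipids        +       1819            57.6                       56.6                        98.3
#>
#> 11087 features in total; 54% to 98% of above-blank features show a time trend
```

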