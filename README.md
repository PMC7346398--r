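# fcstrength

Voxel-wise functional connectivity strength (FCS) analysis for
resting-state fMRI, with genotype-group inference and brain–behavior
correlation — an imaging-genetics pipeline in plain R.

## What it does, and for whom

Imaging-genetics studies ask whether a genetic variant modulates brain
function. A common design compares a voxel-wise functional measure across
genotype groups (here `AA` / `AG` / `GG` of a biallelic SNP) in a healthy
cohort, then relates the affected region's signal to a behavioral trait
within each group. This package implements that full chain for the
functional connectivity strength statistic:

- **Preprocessing** of 4D BOLD runs: discarding initial volumes,
  nuisance regression with the Friston-24 motion expansion
  (`[R, R², R₋₁, R₋₁²]`) plus white-matter, CSF and global mean signals,
  and 0.01–0.1 Hz band-pass filtering.
- **FCS**: for voxel *i*, `FCS(i) = Σ_{j≠i} atanh(r_ij) · 1[r_ij > 0.1]` —
  the sum (or per-pair mean) of Fisher-z-transformed Pearson correlations
  with every other in-mask voxel exceeding the r = 0.1 threshold; a
  weighted degree-centrality map, smoothed with a 4 mm FWHM Gaussian.
- **Group inference** under additive (3-group ANOVA), dominant and
  recessive (two-sample t) genetic models, with sex/age covariate
  adjustment, residual-based smoothness (FWHM/RESEL) estimation, and
  Gaussian-random-field cluster-level correction
  (voxel p < 0.001, cluster p < 0.05).
- **Cohort statistics**: Hardy-Weinberg χ², contingency χ², one-way ANOVA
  from raw data *or* from printed group summaries (n / mean / SD), Fisher
  LSD post hoc tests, and genotype-stratified Spearman correlations
  between cluster FCS and SPQ schizotypy scores at p < 0.05/5.
- **A synthetic cohort generator** that seeds a connectivity hub whose
  hub-voxel-to-latent correlation is dosed per genotype, plus realistic
  nuisance structure (WM/CSF/global drifts, motion-coupled signal) and
  SPQ scores with an exactly controlled within-group coupling to hub
  strength — ground truth for end-to-end recovery testing.

## Worked example

Cohort-level statistics from a published-style summary table (genotype
counts 142/188/72; group means ± SD):

```r
library(fcstrength)

hwe_chi2(142, 188, 72)[c("chi2", "p")]
#> $chi2
#> [1] 0.5046204
#> $p
#> [1] 0.477477

anova_from_summary(n = c(142, 188, 72),
                   mean = c(0.379, 0.612, 0.755),   # occipital FCS
                   sd   = c(0.461, 0.531, 0.542))[c("F", "p")]
#> $F
#> [1] 15.19978
#> $p
#> [1] 4.347141e-07
```

End-to-end on a synthetic cohort (60 subjects, 16×16×10 grid, genotype
connectivity doses 0.2 / 0.45 / 0.7):

```r
cfg <- pipeline_config(
  cohort = list(group_sizes = c(20, 20, 20), grid_shape = c(16, 16, 10),
                n_volumes = 217, connectivity_dose = c(0.2, 0.45, 0.7)),
  seed = 1)
res <- run_pipeline(cfg)
res$surviving_models
#> [1] "additive"  "dominant"  "recessive"
tapply(res$cluster_values, res$phenotypes$genotype, mean)
#>     AA     AG     GG
#> 0.0295 0.0307 0.0331
```

The significant additive-model cluster overlaps the seeded hub (Dice
0.37 for this seed) and the extracted cluster means are ordered
AA < AG < GG, recovering the dosed effect. A shell entry point wrapping
the same functions is installed at
`system.file("cli", "fcstrength", package = "fcstrength")`
(`fcstrength simulate|run --config FILE --out DIR --seed N`).

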