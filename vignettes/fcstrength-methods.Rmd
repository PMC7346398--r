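---
title: "Methods: functional connectivity strength and imaging-genetics inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional connectivity strength and imaging-genetics inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcstrength)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limitations of the package — the information a reader
needs to judge what a passing test suite does and does not demonstrate.

## The measure: functional connectivity strength

For a preprocessed BOLD run with $V$ in-mask voxels, the package computes
for each voxel $i$

$$\mathrm{FCS}(i) \;=\; \sum_{j \ne i} \operatorname{atanh}(r_{ij})\,
  \mathbf{1}[r_{ij} > r_0],$$

the sum of Fisher-z-transformed Pearson correlations between voxel time
series, restricted to correlations strictly above the threshold
$r_0 = 0.1$ (weak correlations are treated as noise and excluded, as is
conventional for this weighted degree-centrality measure). Correlations
are clipped to $\pm(1 - 10^{-7})$ before the transform so that perfectly
correlated pairs stay finite. Two scales are provided:

- `sum` — the literal definition above;
- `mean` (default for reporting) — the sum divided by $V - 1$. Group
  FCS means in the 0.3–0.8 range, as published summary tables show,
  are only compatible with a per-pair normalization: a raw sum over
  tens of thousands of voxels is orders of magnitude larger. Because
  the normalization actually used upstream is not derivable from the
  statistic's verbal definition, both scales are exposed and the choice
  is recorded in every output. The normalization is a positive constant
  per run, so group contrasts and rank correlations are unaffected.

The correlation matrix is processed in column blocks (`block_size`,
default 1024) so the $V \times V$ matrix is never materialized; a unit
test verifies block-size invariance, and an $O(V^2)$ brute-force loop
serves as the oracle for correctness.

Maps are smoothed with a separable Gaussian kernel,
$\sigma_\text{axis} = \mathrm{FWHM} / (\text{voxel}_\text{axis}\sqrt{8\ln 2})$,
truncated at $4\sigma$. Smoothing is *mask-renormalized*: both
$\text{map}\times\text{mask}$ and $\text{mask}$ are convolved and their
ratio taken inside the mask, so zeros outside the mask never bleed in and
a constant map is left exactly unchanged. Default FWHM is 4 mm.

## Preprocessing

The stage order is fixed: discard initial volumes (default 5, trimming
the motion trace identically) → nuisance regression → band-pass. The
toolchains used for this kind of analysis do not document their internal
ordering of regression and filtering; regression-then-filter was chosen
and is stated here because simultaneous band-limited regression is a
known alternative with slightly different leakage properties.

- **Friston-24 expansion.** The canonical autoregressive form
  $[R, R^2, R_{-1}, R_{-1}^2]$: the six rigid-body parameters, their
  squares, their one-volume lags (first row zero-padded), and squared
  lags — not the temporal-derivative variant.
- **Tissue/global signals.** Spatial mean time courses over the WM mask,
  CSF mask, and the analysis mask (global), each mean-centered. Global
  signal regression is on by default (`gsr = FALSE` disables it).
- **Regression.** Ordinary least squares per voxel against the 28-column
  design (24 + 3 signals + intercept), in double precision. Exactly
  collinear columns (e.g. an all-zero motion block) are dropped with a
  warning, never silently. Residualization is idempotent, which is
  tested.
- **Band-pass.** An ideal DFT-domain mask on the linearly detrended
  series: bins with $f \in [0.01, 0.1]$ Hz pass with unit gain, all
  others (including DC) are zeroed. The transfer function is therefore
  exactly the stated indicator; ripple-free but with rectangular-window
  leakage for off-bin frequencies. Tests verify ≥ 0.9 power retention at
  0.05 Hz and ≤ 0.1 at 0.18 Hz for a 212-volume, TR 2.4 s series.

## Group inference

Under the **additive** model the three genotypes are compared by a
vectorized one-way ANOVA per voxel ($F$, df $2, N-3$); **dominant**
(A-carriers vs GG) and **recessive** (AA vs G-carriers) use
pooled-variance two-sample $t$. Covariates (sex, age by default) are
removed by residualizing the FCS values on an intercept + covariate
design first, with the error df reduced accordingly — the specific
adjustment mechanism is a package choice, since "controlling for
demographic factors" names no estimator.

**Smoothness** is estimated from the standardized model residuals (unit
voxel-wise variance): per axis,
$\mathrm{FWHM} = \sqrt{4\ln 2 / \operatorname{var}(\Delta e)}$ with
$\Delta e$ the first differences between in-mask neighbors, pooled over
subjects; the RESEL count is $\sum_\text{mask} \prod_\text{axis}
\mathrm{FWHM}_\text{axis}^{-1}$. For i.i.d. Gaussian residuals the
difference variance is exactly 2, so the estimator's white-noise floor is
$\sqrt{2\ln 2} \approx 1.177$ voxels — asserted in a test. This
first-difference estimator was adopted because the upstream toolchains do
not document theirs; it is the largest methodological gap the package had
to fill, and its bias properties are characterized below.

**Cluster correction** follows the three-dimensional Gaussian-field
forms: statistic maps are converted to equivalent $Z$ by p-value matching
under the statistic's null distribution ($F$ one-sided; $t$ two-sided as
two one-sided passes at half the forming level, signed), thresholded at
the cluster-forming level ($p < 0.001$), and labelled into connected
components (26-connectivity by default; 18 and 6 available). With

$$E[m] = R\,(4\ln 2)^{3/2} (2\pi)^{-2} (u^2 - 1)\, e^{-u^2/2}$$

the expected cluster count over $R$ resels at threshold $u$, and
$E[n] = S\,\Phi(-u)/E[m]$ the expected cluster size over $S$ voxels,
cluster extent is modelled as $P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)/E[n])^{2/3}$, giving the corrected
$p = 1 - e^{-E[m]\,P(n \ge k)}$. Converting $F$ to $Z$ rather than using
$F$-field Euler-characteristic densities is simpler, standard in several
packages, and is validated here by Monte-Carlo familywise-error
calibration rather than assumed.

**Post hoc** comparisons use Fisher's LSD: pairwise $t$ with the pooled
ANOVA mean square error and its df, unadjusted p-values.

## Cohort statistics

`anova_from_summary()` reconstructs the one-way ANOVA from printed group
moments ($SSB = \sum n_i(\bar x_i - \bar x)^2$,
$SSW = \sum (n_i - 1)s_i^2$) and is algebraically identical to
`oneway_anova()` on raw data — a tested identity, which is what makes
published summary tables re-checkable. Hardy-Weinberg and contingency
χ² use Pearson's statistic without continuity correction (the published
sex-table value is only reproduced without it). Stratified Spearman
correlations use average ranks and the $t$ approximation for p; the
Bonferroni divisor is 5, taken literally from the significance convention
it mirrors even though only four correlations (total + three subscales)
are tested — it is a parameter (`alpha_divisor`), and the discrepancy is
deliberate.

## The synthetic cohort generator

The generator emulates the study design the analysis assumes, with
defaults set to the study's conditions: group sizes 142/188/72, TR 2.4 s,
217 volumes, SPQ moments per the published table. What it simulates:

- **Hub connectivity.** A spherical hub (default radius 2.5 voxels,
  auto-placed off-center) whose voxels share a band-limited
  (0.01–0.08 Hz) latent signal: voxel series
  $x = d\,L + \sqrt{1-d^2}\,\varepsilon$, so the hub-latent correlation
  is exactly the dose $d$ and hub-pair correlations are $d_i d_j$. The
  band limit ensures the seeded effect survives the band-pass stage; the
  effect lives on the correlation scale because FCS is a
  correlation-domain statistic. Default doses (0.2, 0.45, 0.7) for
  (AA, AG, GG) mirror a rising-with-G-allele effect.
- **Subject variation.** Each subject's dose is the group dose plus
  Gaussian jitter (`dose_jitter_sd`, default 0.1, clamped to
  (0.01, 0.99)) — the within-group variance that makes a within-group
  brain-behavior coupling possible at all.
- **Nuisance.** WM, CSF and global drift time courses (standardized
  random walks) and a motion-coupled component are added *globally*
  with amplitudes 0.3/0.3/0.5/0.2, giving the regression stage real
  structure to remove; motion traces are Gaussian random walks
  (step SD `motion_sd`, default 0.05) with recorded maximum excursions
  so exclusion rules can be emulated.
- **Behavior.** SPQ totals are drawn per group from the published
  moments; within the designated group (default GG) the sample
  correlation between SPQ and hub strength is imposed *exactly* equal to
  `behavior_coupling` (default −0.4) by conditional construction, and
  exactly 0 in the other groups — "equal to" is read literally, in the
  spirit of `mvrnorm(empirical = TRUE)`. Integer rounding and [0, 74]
  clamping then perturb it by a few hundredths. Subscale scores are
  noisy fractions of the total with shared items allowed (totals do not
  bound subscore sums).
- **Determinism.** The cohort seed drives a phenotype stage that also
  draws one sub-seed per subject; BOLD runs can be stored or regenerated
  one at a time from those sub-seeds (`cohort_subject_bold()`), so the
  402-subject default streams through the pipeline in bounded memory
  with bit-identical results either way.

What it does **not** emulate: scanner physics, slice-timing or
realignment errors, susceptibility artifacts, anatomical images,
spatially structured (non-global) physiological noise, or
distance-dependent connectivity. Recovery tests therefore show that the
chain of estimators is correct and calibrated under its own assumptions —
not that those assumptions hold in any particular scanner's data.

## Numerical choices and degenerate inputs

- Default grid 16×16×10 at a nominal 2 mm voxel size: 2,296 in-mask
  voxels keep the all-pairs correlation desk-scale.
- Ties at exactly $r_0$ are excluded (strict inequality).
- Zero-variance voxels get FCS 0 and are counted, never NaN; an
  all-constant run is an error.
- $F$ at voxels with $SSB = SSW = 0$ is defined as 0 (flat data, no
  evidence); `atanh` clipping bounds every z at ~16.6.
- Out-of-mask voxels are zeroed at every stage, never propagated.
- 0-based voxel indices in all tables.

Problem sizes used by the validation suite (chosen as desk-scale
renditions of the study design): familywise-error calibration uses 200
null replicates of 30 subjects on a 20×20×14 grid at simulation
smoothness 3.5 voxels FWHM; effect recovery uses 10 seeds × 60 subjects
on the default grid; correlation recovery uses 50 phenotype-stage
replicates at the full 142/188/72 group sizes.

## Known limitations

- **GRF at low smoothness.** The cluster-extent model
  $P(n\ge k)=\exp(-\beta k^{2/3})$ is a continuous-field result. On a
  discrete lattice with expected cluster sizes of only 1–2 voxels
  (simulation smoothness ≲ 2.5 voxels FWHM), it over-predicts large null
  clusters and the correction becomes conservative (observed familywise
  error ~0.005 at nominal 0.05). At ≥ 3.5 voxels FWHM — the regime the
  pipeline's own smoothed FCS maps occupy, and the usual validity
  guidance for Gaussian-field theory — the observed rate is ~0.02–0.03,
  close to the nominal level. Users applying the correction to
  barely-smoothed maps should expect conservatism, not inflation.
- **Smoothness estimator bias.** The first-difference estimator has two
  opposing discrete-lattice biases (Taylor error of the difference
  approximation; Gaussian-ACF curvature) that nearly cancel around
  FWHM ≈ 3 voxels; at the white-noise end it floors at 1.177 voxels
  rather than 0.
- The per-pair `mean` FCS scale is one plausible normalization of the
  published group means, not a reverse-engineered match; only group
  contrasts, not absolute FCS levels, should be compared across
  implementations.
- Local vs long-range connectivity are not separated, and no
  permutation-based (TFCE-style) inference is provided — cluster-level
  GRF only.
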