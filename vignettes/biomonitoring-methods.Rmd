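---
title: "Methods: trace-metal biomonitoring analysis in metalmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trace-metal biomonitoring analysis in metalmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalmon)
```

## The measurement model

An active biomonitoring survey exposes a biomonitor (here: potted
strawberry plants, with co-located transplanted lichens) at sites across
a grid, plus one background site well away from the sources of interest.
After the exposure period, element mass fractions (mg·kg⁻¹ dry weight)
are measured for a 22-element panel. Concentrations of trace elements in
such data are strictly positive, right-skewed, and span several orders
of magnitude across elements, so the package treats them as lognormal
throughout; Cr and Pb are typically left-censored at the instrumental
detection limit (DL) in a substantial fraction of samples.

Working assumptions:

* one background site characterizes the regional baseline (a design
  constraint of this kind of survey, not a statistical choice);
* Al is purely geogenic and uncensored everywhere, so it can serve as
  the normalizing element for both accumulation and enrichment factors;
* below-DL values carry no usable magnitude information beyond "below
  DL"; they are substituted at DL/2 for ratio statistics and maps, and
  excluded from per-element location statistics (`summarize_survey()`
  reports `n_above_dl` and computes mean/sd/median/min/max over
  uncensored values only, so the substitution cannot distort medians).
  Results computed from an imputed cell are flagged (`from_imputed`).

## Ratio statistics

`accumulation_factor()` computes, per sample and element,
AF = (C_X/C_Al)site / (C_X/C_Al)background, with the conventional
classes none (≤1), minimal (1,2), moderate [2,5], significant (5,20],
very high (20,40], extremely high (>40). The interval labels in common
use overlap at the boundaries; the package assigns each boundary to the
lower class listed here, deterministically, with AF = 2 falling in
"moderate".

`enrichment_factor()` computes EF = (C_X/C_Al)sample / (C_X/C_Al)crust
against a packaged upper-continental-crust composition (Rudnick & Gao
2003 compilation; replaceable via `crustal_reference(path=)`, with the
provenance label carried into outputs). Mean EF is the mean of
per-sample EFs, not the EF of mean concentrations. Screens: mean
EF < 10 reads as predominantly crustal; an element is "enriched" when
mean EF > 3 and at least 30 % of samples exceed 3. Both AF and EF are
invariant to rescaling a site's whole element vector, and both are
identically 1 for the normalizing element. Mean EFs are computed over
exposure sites only; the background site never enters summaries.

The modified coefficient of variation (sd/median) complements the EF
screen: elements under physiological regulation show small values,
dispersed anthropogenic inputs large ones.

## Source apportionment

`apportion_sources()` chains the standard adequacy-screened PCA:

1. Spearman correlation screen (average ranks for ties; two-sided p by
   the t approximation for n ≥ 10, exact below);
2. iterative anti-image elimination: per-variable MSA is the diagonal
   of the anti-image correlation matrix, computed from partial
   correlations via the inverse correlation matrix; the lowest-MSA
   variable is removed and MSA recomputed until all retained variables
   reach the threshold (default 0.5). A `keep` list can exempt a
   variable a scientist decides to retain despite a low MSA;
3. Bartlett sphericity, χ² = −(n−1−(2p+5)/6)·ln|R| on p(p−1)/2 df, and
   KMO = Σr²/(Σr² + Σpartial²) over off-diagonal entries, on the
   retained set;
4. correlation-matrix PCA (elements span four orders of magnitude, so
   covariance PCA would be dominated by the macro elements); components
   with eigenvalue > 1 are retained; loadings are eigenvector·√eigenvalue;
5. varimax rotation with Kaiser row normalization, by pairwise planar
   rotations; iteration stops when the criterion gain drops below 1e−9
   or after 1000 sweeps, making results deterministic. Each rotated
   component is sign-flipped so its largest-magnitude loading is
   positive, and components are reordered by explained variance, which
   is recomputed after rotation as column sums of squared loadings over
   the number of variables;
6. elements are assigned to a source where |loading| > 0.5.

Communalities (row sums of squared loadings) are preserved by rotation
to 1e−9, and the eigenvalues sum to the number of variables — both are
enforced by tests, alongside a brute-force single-angle search that the
two-component rotation must match to 1e−6 and an independent cross-check
against `stats::varimax`.

A behaviour worth knowing: for a variable carrying *no* shared variance,
the MSA statistic concentrates near 0.5 — exactly the customary
threshold — because its raw and partial correlations with the rest are
equally pure noise. Elimination of such variables is therefore
borderline by construction, and one or two may survive the screen in any
given survey, occasionally carrying a small chance eigenvalue just above
1 behind them. This is a property of the method at n ≈ 50, not an
implementation artifact; the package reports dropped variables with
their MSA at drop time so the screen is auditable, and the structure
recovery tests evaluate the extraction/rotation machinery on the
variables the planted components actually span, while the full-panel
chain is required to separate the planted groups among however many
components pass the eigenvalue cut.

## Spatial analysis

`project_local()` maps WGS84 coordinates to a local plane by the
equirectangular approximation about the mean latitude (R = 6,371,000 m),
adequate below ~100 km extents (it warns beyond); all distances are then
Euclidean.

`idw_interpolate()` is global IDW: every cell averages *all* samples
with weights d⁻ᵏ (k = 2 by default), so the surface is a convex
combination of the samples — exact at sample locations (cells within
1e−6 m snap to the sample value) and bounded by the sample range. Class
maps cut at the 20/40/60/80th percentiles (linear-interpolation
quantile, right-closed intervals) of the *station* values, not the
interpolated grid, so the legend reflects measurements; pass
`sample_values` to `percentile_classes()` to switch. The default cell
size (65 m) is a tenth of the design's sampling cell; it only affects
raster resolution, not the estimator.

`crown_profile()` aggregates sites into annuli around a putative point
source (default outer radii 1–5 km, right-closed) and fits
ln(ring mean) on ring distance by OLS, reporting a = exp(intercept),
b = −slope and r² on the log scale — the "exponential trendline"
workflow. The abscissa is the geometric ring midpoint by default; with
`ring_distance = "mean"` it is the mean distance of the sites in the
ring, which is the better-calibrated choice when the survey extent
truncates the outer rings (sites then cluster at the inner edge and
midpoint fits flatten the decay). Empty rings are skipped with a
warning; with fewer than two usable rings the profile reports means but
no fit.

`quadrant_compare()` labels sites by compass bearing from the source
(NE = [0°, 90°), and so on clockwise) and applies the tie-corrected
Kruskal–Wallis test across quadrants, with unadjusted pairwise rank-sum
follow-ups (Bonferroni available by option).

## Biomonitor comparison

Per-site EFs of the two monitors are compared element-wise in two ways.

*Location*: Shapiro–Wilk on the paired differences routes to the paired
t-test or the Wilcoxon signed-rank test. The signed-rank branch uses
Pratt's treatment of zero differences (zeros are ranked, then dropped
from the sums) with a tie- and zero-corrected normal approximation; it
agrees with `stats::wilcox.test` when no zeros are present.

*Slope*: major-axis (Model II) regression is appropriate because neither
biomonitor is an error-free predictor. The slope is the direction of the
first principal axis of the 2×2 covariance matrix,
b = (s_yy − s_xx + √((s_yy−s_xx)² + 4s_xy²)) / (2s_xy), so regressing
(y, x) gives exactly 1/b. The 95 % CI is computed by the angular method:
a direction θ₀ belongs to the interval iff rotating the data by θ₀
leaves the two rotated coordinates uncorrelated at the 5 % level (F test
on 1 and n−2 df), inverted numerically.

Two permutation tests accompany the fit, both with p = (count+1)/(n_perm+1)
and an explicit seed, hence bit-reproducible:

* association — permute y against x; statistic |r|;
* slope ≠ 1 — under the null of a symmetric (slope-1) relation the
  *mean-centered* coordinates of a pair are exchangeable, so each
  centered pair is swapped with probability ½ and the major axis is
  re-estimated; the statistic is |ln slope|. Centering matters: the MA
  slope depends only on the covariance structure, while the raw
  coordinates are *not* exchangeable when the monitors differ in
  overall level — swapping uncentered pairs creates a two-cluster cloud
  along the anti-diagonal and destroys the test (in simulation the
  uncentered variant fails to reject even y = 3x). The centered variant
  measures type-I error 0.05 at α = 0.05 in the package's calibration
  suite (500 seeds, n_perm = 199).

One caveat for interpretation: with multiplicative noise on the ratio
scale, the raw-scale MA slope between two EF series is not exactly the
underlying accumulation-ratio quotient (noise variance on the larger
variable inflates it); the slope test is therefore read as evidence of
*unequal* accumulation, not as an estimator of the ratio itself.

## The synthetic survey generator

`synthetic_config()` encodes the study design the package emulates:
49 exposure sites in distinct, uniformly chosen cells of a 7 × 11 grid
of 650 m × 620 m cells (4.55 × 6.82 km), one background site ~9 km
outside the grid, and a 22-element panel. Log concentrations are the log
background profile plus four latent component contributions plus
Normal(0, σ = 0.15) noise:

* **geogenic dust** (Al, Si, K, Cl, Mg): an unstructured standard-normal
  site score — soil influence varies site to site without a single
  spatial gradient — with loadings 0.12–0.6 scaled to realistic
  concentration CVs;
* **steelworks** (Fe 1.0, Cr 1.4, Mn 0.5, Ti 0.3): score
  ln(10) − 0.5·d + N(0, 0.15²), d the distance in km from a source
  inside the grid. The affine log-space form makes the Fe expectation
  exactly a·e^(−b·d) with the planted b = 0.5 km⁻¹, which is what the
  crown profile estimates; the amplitude (10× at the source) puts the
  grid-average Fe at roughly three times background. The noise term is
  site-level exposure variability (shielding, micro-siting) — without
  it the steelworks and traffic scores would be deterministic functions
  of position and strongly anti-correlated, which no rotation could
  disentangle;
* **traffic** (Zn 1.2, Pb 1.4, Ti 0.8): score exp(−d_corridor/600 m)
  + N(0, 0.25²) along a southern corridor;
* **root-uptake nutrients** (P, S, Mg): unstructured site score.

The remaining nine panel elements carry background and noise only, which
is what makes the anti-image screen meaningful in tests. Detection
limits (Cr 8, Pb 5.5 mg·kg⁻¹) censor the lower tail of those elements at
rates comparable to the emulated survey; true values are kept in the
returned `truth` object for validation. The lichen survey is the leaf
survey times element-wise accumulation ratios (taken from published
paired mean concentrations of the two biomonitors; elements not
determined in lichens get ratio 1) with independent lognormal noise
(σ = 0.25), so lichen-vs-leaf EF slopes differ from 1 in the directions
observed in the field.

What the generator deliberately does *not* emulate: wind-driven plume
anisotropy, temporal exposure dynamics, rain wash-off, soil-to-leaf
translocation pathways, spatially correlated (kriging-style) noise
fields, and per-sample instrumental DL variation. Passing recovery tests
therefore demonstrates that the estimators recover the structure they
target under a realistic magnitude/censoring/noise regime — not that
field data will be as clean.

## Numerical and testing choices

* Simulation sizes: recovery suites run 20 seeds; permutation
  calibration 500 seeds at n_perm = 199, n = 30; power checks n = 40.
  These sizes give binomial standard errors comfortably inside the
  asserted margins while keeping the default suite under a minute.
* Degenerate inputs are first-class: constant vectors (p = 1 for
  background comparison, warning + NA for correlations), isotropic
  clouds (MA slope undefined → error), empty rings (skipped), fewer
  than five samples (no quintile classes), singular correlation
  matrices (sphericity p reported 0 with a warning; KMO errors).
* All randomness flows from explicit seeds; generator and permutation
  functions restore the caller's RNG state.
* α = 0.05 throughout, with no multiple-testing correction by default
  (Bonferroni available where follow-ups are reported) — matching the
  practice of the survey designs this package serves.

## Known limitations

* The one-background design means every AF inherits the (unknown)
  sampling error of a single site; AFs are best read jointly with EFs.
* The equirectangular projection is not a substitute for a proper CRS
  at larger extents.
* MA permutation tests assume exchangeability after centering; heavily
  heteroscedastic pairs (error variance growing with the mean) can make
  the slope test conservative.
* DL/2 substitution is simple and auditable but biased for heavily
  censored elements; summaries avoid it, ratio statistics flag it.
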