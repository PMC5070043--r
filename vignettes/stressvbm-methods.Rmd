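---
title: "Methods: CAR quantification, expression-weighted thresholds and the voxelwise GLM"
author: "stressvbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAR quantification, expression-weighted thresholds and the voxelwise GLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressvbm)
```

This vignette documents the statistical model behind `stressvbm`, the
choices made where the design was genuinely open, and what the
synthetic-data module does and does not emulate.

## The analysis in one paragraph

The pipeline relates the cortisol awakening response (CAR) — a
three-sample salivary index of HPA-axis reactivity — to voxelwise grey
matter volume (GMV) in a two-group (ultra-high-risk vs control) design.
Saliva series are quality-controlled and summarised as Pruessner
area-under-the-curve values; group differences are tested with pooled
two-sample t-tests including a standard-score outlier screen and a
transition-subgroup comparison. Images are smoothed, proportionally
scaled and fit per voxel by ordinary least squares with age, gender and
antidepressant covariates, testing the CAR slope and the group×CAR
interaction. Instead of a single map-wide correction, each atlas region
receives its own voxelwise p threshold according to its combined
glucocorticoid (GR) and mineralocorticoid (MR) receptor expression:
regions most exposed to cortisol signalling are tested leniently
(P<0.01 uncorrected), regions least exposed most strictly (P<0.05
Bonferroni-corrected over the in-mask voxels), with equal steps in
between.

## CAR quantification

With concentrations $c_0, c_{30}, c_{60}$ (nmol/l) at nominal times 0,
30, 60 minutes after waking, trapezoidal integration over nominal time
gives

$$\mathrm{AUCg} = 15\,(c_0 + 2c_{30} + c_{60}), \qquad
  \mathrm{AUCi} = \mathrm{AUCg} - 60\,c_0,$$

both in nmol·min/l. `computeCar()` returns both plus
$\Delta_{30} = c_{30} - c_0$, and the identity
$\mathrm{AUCi} + 60 c_0 = \mathrm{AUCg}$ is tested exactly.

**Which AUC is "the" CAR?** The two variants answer different questions
(total output vs response above waking baseline). Both are computed and
stored; the pipeline default (`auc_variant = "i"`) is AUCi because the
CAR is defined as a *response to awakening* and because group means in
the tens-to-hundreds of nmol·min/l are the magnitudes AUCi produces at
typical waking baselines. The choice is configurable and nothing
downstream depends on it structurally.

**Quality control.** A subject is excluded when any rule fires, and all
fired rules are reported: `missing_sample` (any of the three nominal
points absent), `low_volume` (saliva volume < 200 µl, below reliable
assay volume), `timing_deviation` (|actual − nominal| > 15 min; the
boundary value passes; timing is self-reported, so a missing actual time
is treated as on-time unless `strictTiming = TRUE`), and
`negative_delta30` ($\Delta_{30} < 0$, the signature of a delayed first
sample; zero passes). QC is idempotent and rule-order-independent,
which the tests assert by recovering every planted failure with its
exact reason code.

**Group statistics.** `pooledTTest()` implements the Student
pooled-variance test with $df = n_1 + n_2 - 2$ directly from summary
statistics, so published group means/SDs are usable as inputs; a Welch
option exists but the pooled form is the default (the reference group
comparisons in this design print pooled degrees of freedom). When both
SDs are zero the statistic is defined as 0 for equal means and is a
degenerate-variance error otherwise. Outliers are screened with
standard scores computed on the full sample including the candidate
(sample SD, $n-1$ denominator), flagging $|z| > 3$; exclusion then
re-runs the group test on $n-1$. `calibrateSampleStats()` affinely maps
an arbitrary base sample onto exact target summary statistics, which is
how the tests reconstruct an excluded value's standard score from
printed full- and reduced-sample means when raw data are unavailable —
the reconstructed sample is synthetic by construction.

## The receptor-expression threshold map

Aggregation is strictly hierarchical, and the order matters in
unbalanced designs:

1. multiple sampling sites of one donor within a region are averaged
   (`aggregateSamplesToRegions()`);
2. probes targeting a gene are averaged within (region, donor), then
   donors are averaged within (region, gene)
   (`averageProbesThenDonors()`) — probe-first, so each donor
   contributes one value regardless of probe count;
3. GR and MR are pooled by an unweighted mean (`combineGrMr()`): a
   substantial fraction of corticosteroid-regulated genes respond to
   both receptor types and no principled weighting is established, so
   none is invented;
4. regions are ranked by descending combined expression and rank $r$ of
   $R$ receives
   $p(r) = p_{\max}(1-w) + p_{\min} w$ with $w = (r-1)/(R-1)$,
   $p_{\max} = 0.01$ and $p_{\min} = 0.05/N_{\mathrm{mask}}$
   (`assignThresholds()`).

Numerical and convention choices:

* **Spacing is linear on the p scale** ("equally sized steps" of a
  probability range); a log-p option is provided for users who prefer
  near-geometric progression at the strict end, but it is not the
  default. The convex-combination form is used so both endpoints are
  exact in floating point, which the tests check for every $R$ in
  2..50.
* **Ties** in combined expression share the mean of their tied ranks
  and hence an identical threshold; any other convention would make the
  result depend on input row order.
* **The Bonferroni denominator** is the in-mask voxel count of the
  dataset being analysed, recomputed per run, not a fixed constant.
* **Uncovered regions** (no expression samples, or missing one of the
  two genes) are excluded from inference and listed in the threshold
  map rather than given a made-up threshold; `applyThresholds()` treats
  any *other* unthresholded atlas region as a configuration error
  (lenient mode downgrades it to a warning).
* A single-region map receives $p_{\max}$ by convention.

## Voxelwise GLM

`smoothGaussian()` is a separable Gaussian with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis (expressed in voxels
via the voxel size), kernel truncated at $4\sigma$ and normalised to
unit sum. The grid boundary is handled by **replicate extension**, so a
constant image is an exact fixed point; this deliberately differs from
SPM's implicit-zero padding, which darkens edges and would break the
fixed-point and linearity properties the tests rely on. FWHM 0 is the
identity.

`proportionalScale()` multiplies each subject by (grand mean of in-mask
means)/(subject's in-mask mean); after scaling all subjects share one
global mean. Normalising to the grand mean rather than an arbitrary
constant is inconsequential for t statistics — only relative scaling
matters — and the tests verify t-invariance to arbitrary per-subject
global factors.

`fitVoxelwiseGlm()` solves all voxels at once through one QR
decomposition of the shared design: $\hat\beta = (X^TX)^{-1}X^Ty$,
$t = c^T\hat\beta / \sqrt{s^2\, c^T(X^TX)^{-1}c}$,
$s^2 = \mathrm{RSS}/(n - \mathrm{rank}\,X)$, df recorded once per map.
Equivalence with an explicit per-voxel normal-equations solver is
asserted to 1e-10 relative tolerance. Degenerate cases:

* rank-deficient designs error **naming the collinear columns**;
* a constant nuisance covariate (e.g. no subject on antidepressants in
  a small cohort) is dropped with a message, since it is collinear with
  the intercept;
* voxels with numerically zero residual variance (relative RSS below
  1e-20, i.e. noise-free synthetic data) report a signed infinite t
  sentinel instead of failing the map.

Coding: gender and antidepressant are 0/1 indicators; group is
0 = control, 1 = UHR. CAR is mean-centred before the interaction column
is formed, reducing collinearity between `group` and `group_x_car`
while leaving the interaction coefficient itself unchanged. The
interaction map is one map thresholded in both directions (positive =
stronger CAR slope in UHR, negative = stronger in controls). The
default analysis mask is voxels with a non-background atlas label and
positive mean GMV across subjects.

`criticalT()` converts $p$ thresholds to cutoffs via the one-sided
upper Student quantile (the CAR correlation is a directional
hypothesis); a two-sided option halves $p$. Cluster reporting uses
26-neighbour connectivity with no extent threshold by default
(`minClusterVoxels` is an optional knob), and peak coordinates are
reported both as 0-based voxel indices and as mm = index × voxel size
from the grid corner — stated explicitly to fix the convention.

## What the synthetic-data module emulates

`generateAtlas()` partitions the grid into axis-aligned connected
blocks by recursive halving — the simplest parcellation with the only
property the thresholding semantics need (every voxel belongs to
exactly one connected region). `generateExpressionTable()` emulates the
donor/probe/sampling-site structure of postmortem microarray atlases:
expression = region mean + per-donor offset + per-measurement noise,
with a multi-site region and multiple probes per gene so every
aggregation branch is exercised. `generateCohort()` draws per-subject
AUCi from the group distributions truncated at zero (the CAR is the
magnitude of a waking response; planted negative values would be
confounded with the $\Delta_{30}$ exclusion) and synthesises a
consistent concentration triple ($c_{30} = c_0 + r$,
$c_{60} = c_0 + r/2$, $r = \mathrm{AUCi}/37.5$, waking baseline
$c_0 \sim N(10, 2^2)$ truncated at 0) so the AUC path reconstructs the
planted value exactly; raw per-sample concentrations are never
published in summary papers, so some synthesis convention is
unavoidable and this one is the simplest consistent rising-falling
profile. QC failures are planted on distinct subjects (UHR first,
mirroring who was excluded in the reference design), and transition
flags go to the lowest-CAR retained UHR subjects by default — matching
the direction of the blunting finding — with a `"random"` option for
null tests. `generateGmvImages()` is the forward model of the GLM
itself (region baseline + slope×CAR + covariates + interaction + iid
Gaussian noise), which is what makes exact noise-free inversion and
calibrated null simulation possible.

Defaults: cohort sizes 26 + 17 with four planted QC failures (one per
rule; the reference exclusion count is four, its per-rule breakdown
unreported), group AUC means/SDs 223.84/233.52 and 320.97/253.85
nmol·min/l, four transitions, antidepressant fraction 5/26 in the UHR
group, ages 18–30; images default to baseline 0.5 with noise SD 0.05
(≈10% of baseline, typical of modulated grey-matter maps), and planted
slopes of 2×10⁻⁴ GMV units per nmol·min/l — chosen so the effect SD
across a realistic CAR range is comparable to the voxel noise, i.e. a
strong but not degenerate effect.

**What it does not emulate:** brain anatomy, registration error,
spatially correlated scanner noise, non-Gaussian GMV distributions,
partial-volume effects, or any real GR/MR expression topography.
Passing tests therefore demonstrate the *statistical machinery* —
recovery, calibration, exactness — under the stated assumptions, not
performance on real MRI data.

## Simulation study sizes

The packaged simulation checks use 39 retained subjects (22 + 17), a
16³ grid of 2-mm voxels and 8 regions: large enough that every region
holds 512 voxels (so even the Bonferroni-corrected region has
resolvable expected false-positive counts across 500 null simulations)
and small enough to keep each study in the low minutes on one CPU.
Parameter recovery uses 200 seeded cohorts; its success criterion is
all three planted regions reporting at least one significant voxel.
These studies run the pipeline with `fwhm_mm = 0`: the phantom is
piecewise-constant with iid noise, so smoothing would only mix signal
across block boundaries and induce the voxel correlations that the
binomial calibration bounds assume away; on real data the 8-mm default
applies.

## Known limitations

* The flexible thresholding controls the false-positive rate *per
  region at its assigned level*; it is not a single family-wise or FDR
  guarantee over the whole mask, and is intended as a biologically
  weighted prior, not a replacement for formal FWE control.
* Pooled t-tests assume equal group variances; the Welch option is
  provided but changes the printed degrees of freedom.
* The OLS GLM assumes iid Gaussian errors per voxel; no spatial or
  robust variance modelling is included.
* Exact reproduction of third-decimal published t values from printed
  2-dp summary statistics is limited by the rounding of those inputs.
* Registration, segmentation, modulation and homogeneity checking are
  out of scope: volumes must arrive registered in a common space.
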