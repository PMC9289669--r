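---
title: "Structure-function coupling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the coupling metric and its statistical machinery, the parameters that
matter, what the synthetic cohort does and does not emulate, and the
places where the underlying analysis description left a genuine design
choice open.

## The coupling metric

Regional homogeneity (ReHo) at a voxel is Kendall's coefficient of
concordance between the voxel's BOLD time series and those of its 26
neighbors:

$$W \;=\; \frac{\sum_t \left(R_t - \bar R\right)^2}{K^2 (n^3 - n)/12},
\qquad \bar R = K(n+1)/2,$$

with $K$ series (the voxel plus its in-mask neighbors, so $K \le 27$) of
$n$ time points, and $R_t$ the cross-series rank sum at time $t$. $W = 1$
means all series rank every time point identically; under temporal
independence $E[W] \approx 1/K$. Because $W$ is rank-based, the map is
invariant to any voxelwise strictly monotone transform of the data —
a property the test suite asserts directly.

The coupling metric divides ReHo by the modulated gray-matter (GM) volume
at the same MNI coordinate. ReHo rises with local synchrony of function;
the modulated GM value measures local structural volume; their ratio reads
as functional demand per unit structure, and radiation-induced *decoupling*
appears as regional shifts of the ratio in either direction. Per subject
the ratio map is variance-stabilized and then smoothed (in that order)
before any group statistics.

Assumptions worth stating: inputs are already preprocessed and
MNI-normalized (registration, segmentation, modulation are out of scope);
all subjects in a cohort share one grid (shape exactly equal, affine
entries within 1e-6 — NIfTI headers are floats); the time axis is long
enough for ranks to be informative ($T \ge 10$ enforced, 60+ recommended).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `connectivity` | 26 | — | the classic ReHo neighborhood (27-voxel cube); also the default cluster-forming connectivity, matching the common Monte-Carlo cluster-correction configuration (edge distance ≈ 5 mm on 3 mm voxels). The analysis description does not pin the cluster connectivity, so it is exposed as a setting. |
| `min_neighbors` | 7 | voxels | boundary policy: voxels with at least 7 in-mask neighbors are computed with what is available rather than discarded; requiring all 26 would erase the cortical rim. Voxels below the floor get 0 and are flagged in `meta`. |
| `tie_policy` | mid-ranks, no correction | — | matches the de facto behavior of the standard ReHo toolchains; the tie-corrected denominator is available by flag. A constant series contributes all-equal mid-ranks, deflating W rather than erroring. |
| `gm_floor` | 0.1 | GM fraction | the usual absolute VBM threshold; prevents the ratio from blowing up in non-gray-matter voxels. Voxels below the floor leave the coupling mask (group analyses then use the intersection of all subjects' coupling masks, since the GLM needs every subject at every voxel). |
| `transform` | z-score in mask | — | see "The transform ambiguity" below. |
| `smooth_fwhm_mm` | 6 | mm | isotropic Gaussian FWHM applied after the transform; smoothing is restricted to the mask and renormalized by the smoothed mask so nothing bleeds in from outside-mask zeros and a constant map stays constant. |
| FDR `q` | 0.05 / 0.01 | — | the two pairwise contrasts against pre-RT run at q = 0.05 and 0.01 respectively; the post-RT subgroup contrast falls back to the Monte-Carlo cluster correction (voxel p < 0.001, cluster alpha 0.01). |
| `n_iter` (alphasim) | 1000 | iterations | the iteration count is a convention (unstated in the analysis description); 1000 resolves a cluster alpha of 0.01 with ~3 iterations in the tail. |
| `k_outer`, `k_inner` | 10, 10 | folds | nested stratified CV; the inner CV tunes (LASSO penalty, SVM cost) by mean inner-fold accuracy, ties broken toward the stronger penalty and then the smaller cost — parsimony where the description is silent. |
| `mask_p` | 0.05 | — | uncorrected two-sample t threshold of the fold-internal stage-1 feature mask. |
| `n_permutations` | 1000 | — | label permutations; p uses the add-one convention $(1 + \#\{null \ge obs\})/(B+1)$ so it is never 0. |

## The transform ambiguity

"Fisher's z-transformation" ($\operatorname{atanh}$) is undefined for a
ratio that can exceed 1, and ReHo/GM routinely does. Both readings are
implemented:

* **`zscore_in_mask`** (default): per-subject standardization within the
  coupling mask — well-defined everywhere, achieves the stated goal
  (normality improvement) and puts all subjects on one scale;
* **`atanh`**: the literal transform after clipping to
  $[-1+10^{-6},\, 1-10^{-6}]$, with the clip count logged. Values at or
  above 1 saturate near 7.25, so this variant compresses exactly the
  high-coupling voxels of interest — which is why it is not the default.

Which variant the original analysis used for values ≥ 1 is unknowable from
its description; the choice is surfaced as a parameter rather than buried.

## Smoothness estimation and the cluster-extent threshold

The Monte-Carlo cluster correction needs the map smoothness. The package
uses a derivative-variance estimator on standardized GLM residuals:
per axis, $\mathrm{FWHM} = \Delta \sqrt{4\ln 2 / \widehat{var}(d)}$ with
$d$ the first differences between in-mask neighbor pairs and $\Delta$ the
voxel size. For a Gaussian autocorrelation this inverts to the smoothing
kernel's FWHM; for unsmoothed voxel noise it returns ≈ 1.18 voxels, the
natural resolution floor of the grid (an estimator based on inverting the
lag-one autocorrelation instead degenerates to 0 there). Difference
variances are pooled over residual maps before inversion.

The threshold itself repeats, per iteration: white Gaussian noise on the
analysis mask (the mask, not its bounding box — cluster sizes depend on
mask geometry), masked smoothing to the estimated FWHM, in-mask
standardization, a two-tailed threshold at the voxel p, and the maximum
cluster size with positive and negative excursions clustered separately.
The reported extent $k$ is the smallest size whose exceedance frequency is
at most the cluster alpha; it is nonincreasing in the alpha and
nondecreasing in the FWHM, and the suite checks both monotonicities plus
seed-to-seed stability within the binomial confidence interval.

## What the synthetic cohort emulates

`generate_cohort()` reproduces the study conditions the analysis targets:

* **Cohort structure** — 22 pre-RT, 22 post-RT RE-negative, 18 post-RT
  RE-positive subjects; sex counts 18/4, 16/6, 14/4 male/female; ages ~
  Normal(44, 9) years; per-hemisphere maximum radiotherapy doses ~
  Normal(66, 8) Gy truncated at 0; RT-to-scan intervals ~ truncated
  Normal(10.8, 9.7) and (17.0, 17.6) months for the two post-RT groups;
  doses unrecorded (NA) for 3 RE-negative and 10 RE-positive subjects, and
  absent entirely pre-RT. Missingness hides the dose from the analyst
  *after* its biological effect is applied.
* **BOLD** — spatially autocorrelated noise (Gaussian smoothing of white
  noise at FWHM 6 mm) mixed per voxel with a region-shared temporal
  component; the mixing weight sets local concordance and hence ReHo, with
  designated high-ReHo regions at elevated weight. TR defaults to 2.4 s
  and T to 60 volumes on a 24 × 28 × 24 grid of 3 mm voxels — a desk-scale
  stand-in for a 64 × 64 × 40 acquisition at 240 volumes.
* **GM** — a shared smooth template in [0.12, 0.95] plus per-subject
  smooth noise (sd 0.03), clipped to [0, 1].
* **Effects** — injected in coupling-z units at known spherical clusters
  (defaults: +0.5/+1.2 z in a deep-gray cluster and −0.5/−1.2 z in a
  medial-temporal cluster for the two post-RT groups, echoing the reported
  direction pattern: deep-gray coupling up, medial-temporal coupling down
  after radiotherapy; the magnitudes are conventions, since no effect sizes
  are published). A designated temporal region per hemisphere additionally
  carries a negative dose slope (−0.04 z/Gy around the 66 Gy mean).

**Calibration.** "One z unit" is anchored to the spatial SD of a baseline
reference subject's coupling map, generated internally from the cohort
seed. Effects are delivered half through the GM denominator and half
through temporal concordance. The concordance half uses a
concordance-to-ReHo response curve simulated at generation time; because
that curve overstates delivery at cluster boundaries (neighborhoods
straddle the region edge), the generator measures the actually delivered
share with a matched-noise probe subject and routes the shortfall through
the GM factor, composing the two routes multiplicatively so the total
shift equals the configured amount.

**What it does not emulate** — hemodynamics, head motion, scanner
artifacts, physiological noise, anatomy-faithful templates, or realistic
long-range functional connectivity. Passing tests therefore demonstrate
that the *statistical machinery* is correct and calibrated under the
stated noise model, not that the pipeline's power on real patient data
matches any published figure; the published classification metrics were
computed on clinical MRI data that are not publicly deposited and are not
reproduction targets here.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based inside R (the array convention); world
  coordinates go through the NIfTI affine on 0-based indices, and cluster
  tables report both. Volumes are written as float64 so write/read
  round-trips are exact.
* Gaussian smoothing is separable, with per-axis band matrices truncated
  at 6σ and column-normalized to unit mass, so unmasked smoothing
  preserves the array sum even at the array edge and an interior impulse
  reproduces the analytic kernel to < 1e-6.
* Cluster labels are canonical (largest first, ties by smallest member
  index), so labelling is invariant to scan order.
* A zero residual variance (e.g. identical groups relabelled) yields
  t = 0, p = 1 rather than 0/0; a zero in-mask variance under the z
  transform warns and returns an all-zero map; constant residual maps make
  smoothness estimation stop with an explicit error; zero dose variance is
  an explicit error in the dose correlation.
* An empty LASSO selection falls back to the single smallest-p column so
  every fold can fit a model; a stage-1 mask with fewer than two columns
  skips the LASSO stage. When both hyperparameter grids are singletons the
  inner CV is skipped.
* Class imbalance (22 vs 18) is left unweighted, since plain accuracy is
  the reported training criterion; a flag could reweight but none is
  applied by default.

## Cluster-level error accounting in the recovery tests

Voxelwise BH-FDR at q admits, by construction, an expected q·R false voxel
discoveries among R rejections — with ~150 true-effect voxels rejected at
q = 0.01 that is about one isolated false voxel per analysis, and its
family-wise probability is near 1 − e^(−1), for any correct FDR
implementation. A family-wise *cluster* error rate is therefore assessed
at the cluster level: a false cluster is a connected component of rejected
voxels that lies beyond the smoothing spread (two voxels) of every
injected cluster *and* survives the package's own Monte-Carlo extent
threshold at the achieved BH voxel threshold (cluster alpha 0.05). The
recovery tests require ≥ 80% voxel sensitivity over the injected clusters
together with a ≤ 5% family-wise rate of such false clusters across seeds.

## Problem sizes used by the test suite

The suite runs the full study design where the contrast itself is under
test (effect recovery: 10 cohorts of n = 22 vs 18 on the default grid at
T = 60) and scales the remaining calibration checks down to keep the whole
suite at desk scale: GLM null calibration on 20 cohorts of 10/10/10
subjects on a 16 × 18 × 16 grid at T = 24; classifier calibration on
feature-level null matrices (n = 40, p = 40, 5 outer folds, singleton
hyperparameter grids — the classifier consumes a feature table, so its
calibration is a property of that interface) with 199-permutation tests;
Monte-Carlo thresholds at 1000 iterations on the default grid. The
permuted-dose null is checked over 100 replicates against the nominal 5%
family-wise rejection rate with a binomial allowance, since under the
global null the BH procedure rejects at least one voxel with probability
exactly q.

## Known limitations

* The coupling ratio confounds its numerator and denominator by
  construction: a group difference cannot be attributed to function or
  structure alone. The generator deliberately injects through both routes
  so tests exercise the confound.
* Whole-map ReHo normalization by the global mean (a common variant) is
  not applied by default; divide upstream if needed.
* The Monte-Carlo cluster threshold assumes stationary Gaussian smoothness
  over the mask; strongly non-stationary real data would need a
  non-stationary correction, which is out of scope.
* The dose correlation is mass-univariate Pearson with pairwise deletion;
  listwise deletion is available by flag, but no dose–response model
  beyond linearity is fitted.
* Atlas-based anatomical labelling of clusters is out of scope; reports
  carry coordinates only.
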