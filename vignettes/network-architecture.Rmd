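---
title: "Whole-brain network architecture from resting-state BOLD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain network architecture from resting-state BOLD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fmrihub` implements a complete voxel-wise analysis of functional network
architecture in resting-state fMRI: preprocessing, degree-centrality hub
mapping, Monte-Carlo cluster-extent correction, seed-based bivariate Granger
causality, covariate-adjusted group inference, and clinical correlation —
together with a synthetic BOLD cohort generator that lets the whole chain be
validated end to end by parameter recovery. This vignette documents the
models, the numerical choices, and the design decisions that were genuinely
open.

## The analysis model

### Preprocessing

Inputs are 4D BOLD series already resampled to a 3 mm isotropic template
grid (registration is out of scope). The temporal/spatial chain is, in
order:

1. **Initial-volume discard** (default 10 of 240 acquired frames, leaving
   230) for signal equilibrium.
2. **Spatial smoothing** with an isotropic Gaussian kernel, FWHM 6 mm,
   `sigma = FWHM / (2 sqrt(2 ln 2))` per axis converted by voxel size.
   Smoothing precedes the temporal operations, following the conventional
   normalise–smooth–detrend–filter resting-state stream.
3. **Linear detrending** per voxel (least-squares line removal; output
   means are exactly zero).
4. **Ideal band-pass filtering** to 0.01–0.08 Hz: a rectangular filter on
   the discrete Fourier transform with bin inclusion `low <= f <= high`.
   The rectangular choice removes any filter-order ambiguity and makes the
   passband exactly reproducible. Bin selection folds the *integer* bin
   index rather than the floating-point frequency so that conjugate bins
   are always kept or dropped together and the filtered signal stays
   exactly real — with a band edge sitting exactly on a bin (0.08 Hz at 50
   frames, TR 2 s) the floating-point fold keeps one side of the spectrum
   only.

Motion exclusion consumes a 6-column motion-parameter file (translations mm,
rotations degrees, one row per volume); a subject fails QC when any
per-axis absolute value exceeds 2.0 mm / 2.0° (strict inequality: exactly
2.0 passes). Realignment itself — like slice timing and spatial
normalisation — requires raw scanner data and is not implemented. No
global-signal or motion-parameter regression is applied; the preprocessing
contract deliberately contains only the steps listed above.

### Degree centrality

Within a gray-matter mask (tissue probability strictly greater than 20%),
every voxel's time course is correlated with every other in-mask voxel.
Edges are positive correlations exceeding `r > 0.25` (strict; negative
correlations never contribute). Per voxel `i`, degree is

- binarized: the number of supra-threshold edges,
- weighted: the sum of the supra-threshold correlation values,

and the map is standardised over mask voxels as
`Z_i = (D_i - mean(D)) / sd(D)` using the **population** standard
deviation: the transform standardises a fixed, fully observed map rather
than estimating a sample quantity, and the choice is pinned so that oracle
tests agree to machine precision. When `sd(D) = 0` the z map is defined as
all zeros, with a warning. Zero-variance voxels stay in the mask with
degree 0 (dropping them would make map geometry depend on the data).

Group-level analyses use the weighted flavor by default — the hub spatial
distributions reported for this design are weighted-degree maps — with the
binarized flavor retained as an option.

`block_degree_map()` evaluates the same quantity in row blocks of the
correlation matrix (a compiled kernel) without materialising the N × N
matrix, and is the form the pipeline uses. Inside `run_study()` the
correlations are additionally computed from the real and imaginary parts of
the retained Fourier bins: after the ideal band-pass the data are exactly
band-limited, so by Parseval's identity the spectral representation (about
60 rows instead of 230) yields identical correlations at a fraction of the
cost. This is an algebraic identity, not an approximation, and a pipeline
test asserts equality with the standalone operation.

### Monte-Carlo cluster-extent correction

Cluster correction follows the AlphaSim recipe. For a given mask, noise
smoothness (FWHM), single-voxel `p` and cluster connection radius:

1. simulate in-mask Gaussian white noise;
2. smooth to the target FWHM — smoothing is masked and renormalised by the
   smoothed mask indicator so edge voxels are not artificially attenuated;
3. re-standardise within the mask and threshold at the upper `voxel_p`
   normal quantile;
4. record the maximum supra-threshold cluster size, where clusters are
   connected components under all voxel offsets whose centre distance is at
   most the connection radius (5 mm at 3 mm voxels = 18-connectivity:
   faces and edges, not corners);
5. the minimum cluster size is the smallest `k` with
   `P(max cluster >= k) <= alpha` over the simulated distribution.

The noise smoothness is *imposed* (FWHM 6 mm), not estimated from
residuals, mirroring an explicit-FWHM AlphaSim invocation. Defaults are
voxel `p = 0.01`, cluster alpha `0.01`, 5000 simulations, with a 40-voxel
minimum retained as a configuration fallback for masks where the null
simulation is not rerun. Two-sided group contrasts are corrected by running
the positive and negative tails separately at `voxel_p` each, matching
directional cluster reporting. When `alpha < 1/n_sims` the requested level
is unattainable; the estimator warns and reports the minimum achievable
size.

### Seed-based bivariate Granger causality

For a seed region (default: 6 mm-radius spheres at the mirrored superior
frontal peaks (±18, 42, 27) mm, mean time course over in-mask voxels — only
peak coordinates are available, so a sphere is the natural construction;
a cluster-mask seed can be supplied instead), and every in-mask voxel
series `y`, both directed influences are residual-based F statistics with
model order `p`:

```
F_{x->y} = [(RSS_restricted - RSS_full) / p] / [RSS_full / (T - 2p - 1)]
```

where the restricted model regresses `y_t` on its own `p` lags plus an
intercept and the full model adds the seed's lags; `F_{y->x}` swaps the
roles. `T` is the series length; the divisor `T - 2p - 1` pins the null
reference to `F(1, 227)` at `T = 230`, `p = 1`. Values are clamped at 0,
and constant series are flagged and set to 0. The model order defaults to
`p = 1` — the convention of the standard resting-state GCA toolboxes, which
leave the order unstated in most applied reports — and is exposed in the
configuration. The published "residual-based F, normalised (F′)" phrasing is
implemented as the plain residual-variance-ratio F with the subsequent
z-standardisation as the only normalisation; the F/F′ distinction has no
operational definition beyond that, and this interpretation is recorded
here deliberately.

Each direction's F map is z-standardised over the mask (in-mask mean 0,
population SD 1, exactly). Under the null the F values follow an
F(1, T−3)-like law, so the z maps are strongly right-skewed — mean and SD
are pinned by construction, higher moments are not. Seed-sphere voxels are
excluded from group-level GC inference to avoid trivial self-prediction
effects. No hemodynamic deconvolution is attempted: the statistics describe
directed prediction among BOLD signals, with the usual caveat that regional
hemodynamic differences can masquerade as directionality.

### Group inference and clinical correlation

Per-voxel group statistics on the per-subject z maps:

- **one-sample t** (df `n−1`) per group, used to build the union mask of
  each group's corrected one-sample clusters; the between-group comparison
  is restricted to that union, falling back to the gray-matter mask (with a
  warning) if it is empty;
- **two-sample GLM t** for the group contrast with age, sex and education
  as nuisance covariates: sex coded 0/1, group +1/−1 with intercept,
  covariates mean-centred (this affects only the intercept's
  interpretation); df = `n − rank(design)`; constant covariate columns are
  dropped, which reduces the model exactly to the pooled two-sample t-test.

Significant-cluster mean values per patient are correlated with THQ score
and tinnitus duration by **partial Pearson correlation**: residualise both
variables on (intercept, age, sex, education) and correlate the residuals,
with `t = r sqrt((n−k−2)/(1−r²))`, two-tailed. "Corrected for age, sex and
education" could also mean a group-matched design; partial correlation is
the implemented reading, with plain Pearson available. Bonferroni
correction multiplies by the total number of tests performed (significant
regions × clinical variables), recorded in the report.

The demographics table uses pooled-variance (Student) two-sample t-tests
for continuous variables and a Pearson chi-square **without** continuity
correction for sex — these are the conventions that reproduce the published
group-comparison p-values (0.144 for age, 0.813 for the 9:15 vs 9:13 sex
split) from the printed summary moments. Not every printed p-value is
recoverable from rounded summaries (education and right-ear hearing differ
in the third decimal under any standard t variant, presumably computed on
unrounded raw data), and those are not asserted anywhere.

## The synthetic cohort generator

No scan data are deposited for this design, so the package ships a
generator whose defaults *are* the study conditions: 24 patients + 22
controls, TR 2 s, 240 acquired volumes (230 retained), 3 mm isotropic
voxels. The desk-scale grid is 20 × 24 × 20 voxels with origin
(−27, −18, −21) mm — chosen so the mirrored 9 mm hub spheres at
(±18, 42, 27) fit inside the field of view — and the gray-matter
probability map is a rounded-box superellipsoid (6-norm) reaching ~6200
mask voxels at the 20% threshold, so frontal coordinates near the corner of
the box still carry gray matter.

The noise model per subject is: voxel-wise AR(1) Gaussian noise
(coefficient 0.3), spatially smoothed to ~6 mm FWHM and rescaled to unit
SD, plus 3–5 global band-limited (0.01–0.08 Hz) network signals mixed into
gray matter with random smoothly varying loadings (SD 0.5). This gives a
realistic nonzero baseline degree without modelling physiology; cardiac and
respiratory noise, scanner drift beyond a linear trend, and hearing-loss
structure are deliberately absent.

Injected ground truth, recorded in a JSON manifest:

- **Hub effect**: a shared band-limited signal mixed at low amplitude
  (0.15) into all subjects' gray matter, and added at `hub_gain` (default
  1.6) to the two mirrored 9 mm hub spheres in patients only. Because the
  low-amplitude mix is present in both groups, patients and controls are
  exchangeable when all effect parameters are zero — the property the null
  calibration tests rely on.
- **Directed coupling**: target spheres (defaults (−6, 6, −9) and
  (9, −9, 27) mm, radius 6 mm, inside the default grid) receive
  `strength × `(lag-1 delayed left-hub mean signal) in patients only;
  per-patient strengths are drawn N(0.9, 0.25) truncated at 0.1. The mean
  of 0.9 matches the coupled-simulation strength at which direction
  dominance is essentially certain at T = 230.
- **Clinical scores**: patient THQ is drawn as a linear function of
  coupling strength plus noise targeted at Pearson r = 0.5, redrawn (up to
  50 times) until the sample correlation is within ±0.15 of the target;
  mean/SD near 49.5 ± 15.5, clipped to 0–100. Demographics are drawn from
  normal/categorical distributions matching the published group moments,
  truncated to the printed ranges.

No published effect magnitudes exist for the map-level group differences
(only t values on undeposited data), so `hub_gain` and the coupling
strength were fixed once at values detectable at n = 24 + 22 — the stated
purpose of the generator — and are not tuned thereafter. One simulated
patient can optionally exceed the motion limits to exercise the exclusion
path, mirroring a cohort that loses one of 25 recruited patients to motion.

What recovery on this generator shows: that the full chain — preprocessing,
degree mapping, cluster correction, GC mapping, covariate GLM, partial
correlation — detects hub-strength increases, directed coupling and
score–connectivity correlation of plausible magnitude at the study's sample
size, with calibrated false-positive behaviour when effects are absent.
What it does not show: robustness to physiological confounds, registration
error, hemodynamic variability or real spatial covariance structure, none
of which the generator emulates.

## Numerical choices

- Smoothing uses zero padding; edge voxels are attenuated (interior
  intensity is preserved to 1e-6). Null-field smoothing inside the
  Monte-Carlo estimator renormalises by the smoothed mask instead, because
  there the *field*, not an image, is being modelled.
- Coordinates are 0-based voxel indices against the NIfTI sform affine; all
  reported peaks are MNI mm. `mm_to_voxel()` rounds to the nearest voxel
  centre and refuses coordinates outside the grid.
- Grids must agree exactly across subjects (same dims, affine within 1e-4
  mm); no resampling is implemented.
- Cluster peaks are the largest-|statistic| voxel per cluster; tables are
  sorted by extent, ties left in discovery order.
- NIfTI output is float64 so read/write round trips are bit-identical.
- All simulation randomness flows from `rng_seed` in the configuration;
  `run_pipeline()` output is byte-identical across runs with equal inputs,
  configuration and seed.

## Problem sizes used in validation

The shipped test and acceptance runs use the generator at full cohort scale
(24 + 22 subjects, 230 retained volumes, the 20 × 24 × 20 grid) with the
Monte-Carlo null at 1000 simulations and recovery evaluated over 10 cohort
seeds; oracle equivalences use instances up to ~200 mask voxels where
all-pairs brute force is exact and fast. These sizes were chosen so the
whole validation suite runs comfortably on a laptop-class single core while
keeping every statistical property at the study's own sample size.

## Known limitations

- Bivariate (not conditional) GC on undeconvolved BOLD; directionality is
  predictive, not causal.
- The ideal band-pass has sharp spectral edges; a non-bin-aligned sinusoid
  just outside the band retains some leakage.
- The Monte-Carlo threshold assumes stationary imposed smoothness; real
  data have spatially varying smoothness.
- The generator's gray-matter geometry is a convex rounded box, not a
  cortical sheet; cluster shapes in recovery runs are blob-like by
  construction.
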