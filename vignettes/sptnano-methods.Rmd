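---
title: "Models and methods behind sptnano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptnano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptnano)
```

`sptnano` analyses single-particle-tracking PALM (sptPALM) recordings of
membrane molecules in neuronal dendrites: a localization/tracking step
upstream of this package yields trajectories (track id, frame, x, y in
micrometres), and the package characterises their mobility and nanoscale
clustering. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Diffusion from the mean square displacement

For a track with positions $r_i$ at frames $f_i$, the time-averaged MSD at
lag $k$ frames is the mean of $\lVert r_j - r_i \rVert^2$ over all frame
pairs with $f_j - f_i = k$; gapped tracks contribute every available pair.
The first lags are fitted by ordinary least squares to

$$\mathrm{MSD}(t) = a + 4 D t,$$

so $D$ is the slope over 4 and $a$ is the intercept (in two dimensions; a
static localization error $\sigma$ per coordinate shifts the apparent MSD
by $4\sigma^2$, which lands in $a$). A trajectory is called *immobile* when
$\log_{10} D \le -1.6$ (boundary inclusive), and a cell is summarised by
its lag-wise mean MSD curve, the trapezoidal area under that curve (AUC),
the $\log_{10} D$ histogram and the immobile fraction.

Key tunables, with defaults and rationale:

* `n_fit_points = 4` MSD lags in the linear fit — the short-track
  convention balancing bias (curvature at large lags for confined motion)
  against variance (few displacement pairs); exposed in every caller.
* `d_floor = 1e-5` um^2/s — noise-driven non-positive slopes are floored
  before the log transform and flagged per track, so the histogram support
  is bounded below at $-5$.
* `min_track_frames = 8`, `min_trajectories = 1000` per cell,
  `min_trajectories = 50` per ROI for the effective diffusion coefficient
  `D_eff` — the inclusion rules applied throughout; cells below the floor
  are flagged, never silently dropped.
* `auc_window = c(0.02, 0.24)` s (lags 1–12 at 50 Hz) — the lag range the
  mean curves are displayed and integrated over; the AUC is computed on
  the per-cell mean curve (not as a mean of per-track AUCs — the other
  reading of an "area under the average curve", flagged here because the
  convention matters when track lengths vary).
* Cell-average MSD is computed lag-wise over the tracks possessing that
  lag. This keeps short tracks contributing to early lags without
  extrapolation; the alternative (restricting to tracks spanning the whole
  window) discards most of a bleaching-limited dataset.

A numerical note: the per-track OLS intercept estimator is mean-unbiased
but left-skewed for short tracks, so its *median* across tracks is
slightly positive even for noise-free free diffusion. Sanity checks on the
intercept therefore test the mean, not the median.

## Motion typing by the moment scaling spectrum

For orders $\nu = 0 \dots 6$, the order-$\nu$ moment at lag $k\Delta t$ is
the mean of $\lVert\Delta r\rVert^\nu$; each moment scales as
$t^{\gamma_\nu}$ with $\gamma_\nu$ estimated as the log–log OLS slope over
the first 5 lags. The spectrum slope $S_{\mathrm{MSS}}$ is the
through-origin slope of $\gamma_\nu$ against $\nu$ (so $\gamma_0 = 0$
holds by construction), clipped to $[0, 1]$: $\approx 0$ immobile,
strictly between the immobile and free levels for confined motion,
$\approx 0.5$ free diffusion, $\approx 1$ directed transport. Only tracks
of at least 20 frames are analysed, whole-trajectory only — transient
within-track segmentation is out of scope. Tracks with a zero moment at a
fitted lag (exactly stationary) are excluded because the log is undefined.

## Three-diffusive-state inference from displacement CDFs

The single-frame displacement $r$ of a molecule diffusing freely at $D$
follows a Rayleigh-type law with CDF $1 - e^{-r^2 / 4 D \Delta t}$. A
population mixing three states — immobile ($D_1$), confined ($D_2$) and
apparently free ($D_3$) — with occupancies $f_1 + f_2 + f_3 = 1$ has

$$C(r, \Delta t) = 1 - f_1 e^{-r^2/4D_1\Delta t}
                     - f_2 e^{-r^2/4D_2\Delta t}
                     - f_3 e^{-r^2/4D_3\Delta t}.$$

To avoid over-weighting long (slow, therefore long-lived in the field)
tracks, each track contributes only its **first seven** displacements —
the step count of the shortest track analysed (8 frames). The fit is
*global*: one $(D_1, D_2, D_3)$ shared across all cells of a condition,
occupancies free per cell. Numerical choices:

* Each cell's empirical CDF is evaluated at the midpoints of its sorted
  jump points (where the ECDF equals $i/n$), uniformly subsampled to at
  most 500 points, and the summed squared deviation is minimised.
  Unweighted least squares on the CDF is a known trade-off: it
  over-weights the distribution body relative to a likelihood fit, which
  is accepted here for robustness and speed.
* The ordering $0 < D_1 < D_2 < D_3$ is guaranteed by construction:
  $D_1 = e^{a_1}$, $D_2 = D_1 + e^{a_2}$, $D_3 = D_2 + e^{a_3}$; per-cell
  occupancies live on the simplex through a two-logit softmax.
* Levenberg–Marquardt local optimisation from 10 seeded multistarts with
  $D$ initialised log-uniformly on $[10^{-3}, 1]$ um^2/s; the best start is
  returned with per-start residuals, and a near-degenerate pair of states
  (ratio < 1.01) is flagged in the diagnostics.
* Bootstrap confidence intervals for $D_{1..3}$ are deliberately not
  built in; cells are the natural resampling unit if a user needs them.

The number of states is fixed at three; model selection over the state
count is out of scope. Spine and shaft displacements can be pooled or
fitted separately by filtering tracks through the compartment module
first — both workflows are supported and neither is presumed.

## Voronoi-tessellation nanodomain detection

All localizations (not one per track) are tessellated; pooling detections
mirrors how localization-density maps are built, which means
blinking-induced recounting is reproduced, not corrected. Each
localization gets a first-rank neighbour-averaged density

$$\delta_i = \frac{1 + |N_i|}{A_i + \sum_{j \in N_i} A_j}$$

over its Voronoi neighbours with finite (unclipped) cells; cells touching
the enclosing window are flagged unbounded, carry density 0 and are
excluded from averages. The bare inverse cell area is available via
`first_rank = FALSE`. The global average density is the localization count
over the window area — the natural reference when the imaged field
contains empty space around the cell; the window can be supplied
explicitly (e.g. the camera field of view).

Segmentation proceeds in two density-threshold passes:

1. **Objects** (e.g. the neuronal contour): localizations with
   $\delta \ge 1.0\times$ the global average seed connected components
   through the Voronoi adjacency; each object additionally claims the
   finite-cell localizations adjacent to its seeds (largest component
   first), because an object is a region and its rim and interstitial
   points belong to it regardless of their own density class. The outline
   is the union of the members' Voronoi polygons (clipped cells, so no
   convex-hull concavity artefacts), and the object density is members
   over outline area.
2. **Nanodomains**: within an object, localizations with
   $\delta \ge 2.0\times$ the object average density, merged by adjacency;
   components with at least 50 detections qualify. Both defining
   thresholds are re-verified post hoc on every reported domain.

Nanodomain geometry: the diameter is $2\sqrt{2(s_1^2+s_2^2)}$ over the two
principal-component standard deviations of the member coordinates —
equivalently four times their root mean square — a convention fixed by
requiring that points uniformly filling a disc of diameter $L$ return
$L$; it is recorded in the output metadata because several PCA-diameter
conventions circulate. The area is the outline-polygon area. Drift
correction is not performed; externally corrected tables are accepted
as-is.

## Compartments and statistics

ROIs are labelled polygons (`spine` / `shaft` / `excluded`) in the
localization frame; spines may reference their adjacent shaft segment for
paired comparisons. A trajectory is assigned to the ROI holding the
largest fraction of its localizations when that fraction exceeds 0.5 —
an explicit stand-in for the manual per-trajectory curation such data
normally receive; ties, sub-majority tracks and anything touching an
`excluded` ROI are set aside rather than split, because segmenting tracks
at boundary crossings biases short-track statistics (molecules exchange
frequently between spines and shafts). Polygons are 2D; out-of-plane
spines are represented by `excluded` ROIs supplied by the user.

Statistics operate per cell (one value per cell, never pooled
trajectories), except for explicitly distribution-level comparisons of
$S_{\mathrm{MSS}}$ distributions, which use the two-sample
Kolmogorov–Smirnov test. Normality is screened per group with the
D'Agostino–Pearson omnibus $K^2$ at $\alpha = 0.05$ (implemented from the
Johnson-SU and Anscombe–Glynn approximations; samples under 8 route
conservatively to the rank tests). Two normal groups get Student's
*t*-test, Welch-corrected when an F-test flags unequal variances, paired
on request; otherwise Mann–Whitney (or the paired Wilcoxon). More than
two groups get one-way ANOVA with Holm-adjusted pairwise *t*-tests, or
Kruskal–Wallis with Dunn's post hoc (Holm-adjusted; the adjustment is
recorded in the output because conventions differ between post hoc
tables). Under identical-distribution simulation at 15 cells per group the
selected two-group route holds its nominal 5% type-I error.

## The synthetic-data generator

`simulate_cell()` emulates the statistical structure the analysis assumes
— it is the ground-truth instrument every stage is validated against by
parameter recovery:

* Acquisition: 50 Hz (`frame_interval = 0.02` s), 16,000 frames; each
  molecule appears at a uniformly random frame (stochastic
  photoconversion) and lives a geometric number of frames with mean 15
  (memoryless bleaching — chosen so both the $\ge 8$-frame MSD and the
  $\ge 20$-frame MSS populations are well populated); tracks shorter than
  8 frames are discarded, as in the analysis.
* Mobility: each molecule draws **one** of three states (defaults
  $D = 0.003, 0.03, 0.3$ um^2/s, occupancies $0.3/0.4/0.3$) and keeps it —
  a static mixture, matched to the fitted model, which is a population
  mixture at a single lag. An explicit design choice: no Markov switching,
  so that generator and model agree and recovery failures indicate
  implementation defects rather than model mismatch.
* The immobile state is slow diffusion plus localization error rather than
  frozen points, because fitted "apparent" coefficients absorb
  localization noise.
* Geometry: a rectangular shaft with mushroom spines (0.5 um heads on
  necks) built by `build_default_layout()`; molecules reflect specularly
  at their birth compartment's boundary (membrane molecules are not
  destroyed at ROI edges, so boundaries are reflecting, not absorbing or
  periodic). Confined-state molecules are born inside a ~170 nm
  nanodomain disc (default one per spine plus a sparse few in the shaft)
  and reflect at its edge; their true positions never leave the disc. If
  a compartment holds no disc, confined-state molecules diffuse freely at
  $D_2$, which is how pure mixture datasets for CDF-fit validation are
  expressed.
* Localization error: isotropic Gaussian, $\sigma = 25$ nm per coordinate
  — a conventional sptPALM precision, exposed in the config since the
  value is acquisition-dependent.
* Units are um and seconds internally; nm are accepted at the boundaries
  with explicit conversion. Coordinates are continuous — camera
  pixelation, PSF shape, drift and axons are *not* simulated, and the
  generator makes no attempt at photophysical realism (blinking gaps
  within a track, variable photon budgets). Passing recovery tests on
  this generator therefore demonstrates correctness of the estimators
  under the model's own assumptions, not robustness to every artefact of
  real recordings.

Determinism: every stochastic entry point takes a seed and runs under
`with_seed()`, which restores the caller's RNG state; the pipeline fans a
single run seed out to fixed per-stage seeds so toggling one stage never
perturbs another's randomness. Identical seeds give byte-identical output
files.

## Validation scale

The test suite validates by parameter recovery at desk scale: ensembles of
1,000–2,000 tracks per cell, 10 cells for the global CDF fit, ensembles of
several hundred $\ge 20$-frame tracks for MSS calibration, 100 seeded
replicates for the complete-spatial-randomness false-positive rate, and 20
seeded replicates for the spine/shaft directional comparison. These sizes
give comfortable margins for the documented tolerances (shared $D$ within
25%, occupancies within $\pm 0.05$, planted-cluster recall $\ge 0.9$)
while keeping the whole suite to a few minutes.

```{r example, eval = FALSE}
lay  <- build_default_layout(n_spines = 4, seed = 1)
cell <- simulate_cell(simulation_config(n_molecules = 2000, seed = 1,
                                        layout = lay))
summ <- summarize_cell(cell$localizations, min_trajectories = 1000)
fit  <- fit_three_state_global(
  list(collect_displacements(cell$localizations)), seed = 1)
nd   <- analyze_nanodomains(cell$localizations)
```

## Known limitations

* Whole-trajectory classification only; no transient-state segmentation
  and no hidden-Markov switching inference.
* Unweighted CDF least squares slightly under-weights distribution tails
  relative to maximum likelihood.
* Nanodomain detection inherits the pooled-detection convention: a single
  long-lived immobile molecule re-detected across many frames can
  masquerade as a cluster, exactly as in density-based SMLM cluster
  analysis generally.
* The 2D compartment model cannot represent spines projecting along the
  optical axis; such regions must be marked `excluded` upstream.
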