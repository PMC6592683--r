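# sptnano

Mobility states and nanoscale clustering from single-particle tracking.

`sptnano` is an R package for analysing single-particle-tracking PALM
(sptPALM) recordings of membrane molecules — kinases, receptors, scaffold
proteins — in neuronal dendrites, where mobility and nanocluster
organisation differ between dendritic spines and the shaft. It consumes
trajectory tables produced by any localization/tracking software (track id,
frame, x, y in µm) and provides, end to end:

* **MSD diffusion analysis** — per-track time-averaged mean square
  displacement, fitted by `MSD(t) = a + 4Dt`; trajectories with
  `log10(D) ≤ −1.6` are classified immobile; per-cell mean MSD curves,
  their area under the curve (AUC), diffusion-coefficient histograms, and
  per-ROI effective diffusion coefficients `D_eff` (≥ 50 trajectories per
  ROI).
* **Motion typing** — the moment scaling spectrum slope `S_MSS` of each
  ≥ 20-frame trajectory (≈ 0 immobile, 0–0.5 confined, ≈ 0.5 free,
  ≈ 1 directed).
* **Three-diffusive-state inference** — the displacement CDF at one frame
  interval, `C(r,Δt) = 1 − Σᵢ fᵢ exp(−r²/4DᵢΔt)` (i = 1..3), fitted
  globally: diffusion coefficients `D₁ < D₂ < D₃` shared across cells,
  state occupancies `f₁, f₂, f₃` per cell, using only the first seven
  displacements of each track to avoid long-track bias.
* **Nanodomain detection** — Voronoï tessellation of all pooled
  localizations with first-rank neighbour-averaged densities; objects at
  ≥ 1× the global average density; nanodomains as connected regions inside
  an object with ≥ 50 detections at ≥ 2× the object's average density;
  PCA-based diameters and outline areas; counts per spine.
* **Compartment analysis** — polygon ROIs labelled spine/shaft (JSON),
  majority-rule trajectory assignment, paired spine-vs-adjacent-shaft
  mobility reports.
* **Per-cell statistics** — D'Agostino–Pearson normality screening routing
  to t/Welch/Mann–Whitney, ANOVA+Holm or Kruskal–Wallis+Dunn, and
  Kolmogorov–Smirnov for `S_MSS` distributions.
* **A ground-truth-labelled simulator** — Brownian dynamics of a
  three-state mixture in spine/shaft geometries with ~170 nm trapping
  nanodomains, reflecting boundaries, geometric bleaching and Gaussian
  localization error, used to validate every stage by parameter recovery.

See `vignettes/sptnano-methods.Rmd` for the models, parameter defaults and
numerical conventions.

## Worked example

```r
library(sptnano)

## a simulated dendrite: 4 spines, nanodomain trapping, 2000 molecules
lay  <- build_default_layout(n_spines = 4, seed = 1)
cell <- simulate_cell(simulation_config(n_molecules = 2000, seed = 1,
                                        layout = lay))
cell
#> sim_cell: 1228 tracks, 27026 localizations

## per-cell mobility summary (8-frame filter, 1000-trajectory floor)
summarize_cell(cell$localizations, min_trajectories = 1000)
#> cell_mobility cell01: 1228 tracks, AUC = 0.008823 um^2 s, immobile fraction = 0.693

## nanodomains and their per-ROI counts
nd <- analyze_nanodomains(cell$localizations)
nanodomains_per_roi(nd$table, layout_to_rois(lay))
#>   roi_id label n_nanodomains
#> 1  shaft shaft            15
#> 2 spine1 spine             1
#> 3 spine2 spine             0
#> 4 spine3 spine             1
#> 5 spine4 spine             1

## global three-state fit over four cells of a free three-state mixture
box <- big_box_layout(20)
samples <- lapply(1:4, function(i) {
  ci <- simulate_cell(simulation_config(
    state_occupancy = c(0.3, 0.4, 0.3), localization_sigma = 0,
    n_molecules = 2500, seed = i, layout = box), cell_id = paste0("cell", i))
  collect_displacements(ci$localizations)
})
fit_three_state_global(samples, seed = 1)
#> three_state_fit: D = 0.00302, 0.031, 0.302 um^2/s over 4 cell(s); residual norm 0.0815
#> mean occupancy: 0.308, 0.397, 0.295
```

The AUC (µm²·s) and immobile fraction summarise a cell's overall mobility;
the three-state fit recovers the generating coefficients
(0.003, 0.03, 0.3 µm²/s) and the 0.3/0.4/0.3 occupancy mixture; spines
carry about one detected nanodomain each, and trapping makes the immobile
fraction high. An end-to-end run over all six stages
(simulate → metrics → motion states → nanodomains → compartments → stats)
with a written manifest:

```r
man <- run_pipeline(run_config(seed = 1, output_dir = "out"))
```

A thin command-line wrapper is provided in `inst/scripts/sptnano.R`
(`simulate` and `run-all` subcommands).

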