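# metquant

Quantitative image analysis for mesenchymal-to-epithelial transitions (MET)
in embryonic tissue — for developmental biologists who track migrating
nuclei in 4D two-photon stacks and quantify apicobasal polarity markers in
fixed confocal slices, and want both measurements reproducible and testable
without access to the original recordings.

The package implements two pipelines:

**Nucleus tracking.** Global embryo movement is estimated by FFT
cross-correlation of maximum-intensity projections and compensated by
integer-voxel shifts. Nuclei are detected per frame with an
anisotropy-aware, scale-normalized 3D Laplacian-of-Gaussian filter
(per-axis `sigma = r/sqrt(3)` in voxels for a blob of characteristic radius
`r`), followed by strict 26-connected minima detection, sub-voxel
refinement, and strongest-minima pruning (greedy suppression within the
characteristic radius). Detections are linked frame to frame by a gated
linear assignment: squared-distance link costs, birth/death alternatives at
`d_max^2`, links beyond `d_max` forbidden. Tracks that span the whole video
and start in the region of interest are kept and classified by median
nuclear diameter (PMEC < 3.5 µm, ICP > 5.5 µm). Per track, the pipeline
reports

- velocity `v = mean(||Δx_t|| / Δt)` (µm/min),
- directional persistence `||x_T − x_0|| / Σ||Δx_t||` ∈ [0, 1],
- coordination: Pearson correlation of the (z, y, x)-stacked
  instantaneous-velocity series with that of the nearest neighbouring
  track ∈ [−1, 1],

aggregates them per embryo and cell type, and compares conditions with
unpaired two-tailed t tests and one-way ANOVA (stars at 0.05/0.01/0.001).

**Apicobasal profiling.** Fixed images pass the standard chain — 8-bit
conversion, inversion, sliding-paraboloid background subtraction (exact
lower-envelope morphology), stacked-histogram thresholding keeping the
brightest 3% — then 60-px-wide line profiles are sampled from 1 µm above
the apical membrane to 1 µm below the mesoderm, averaged over ≥ 10
similar-length cells per embryo and 6 embryos per condition. Windowed peak
amplitude (apical 0–10 µm, basal 10–20 µm) and full width at half maximum
(`FWHM = 2·sqrt(2 ln 2)·σ` for a Gaussian peak) quantify marker
localization and spread.

Both pipelines are exercised end to end on ground-truthed synthetic data
from the built-in generators (`simulate_movie()`, `simulate_epithelium()`),
which emulate the acquisition geometry: 31 frames at 2-min intervals,
1.5-µm z steps, two nuclear populations (~3 µm and ~6 µm) migrating at
1.2 µm/min under global drift; and columnar epithelium cross-sections with
programmable peak position, amplitude and width.

## Worked example

Simulate one wild-type-like embryo movie, run the tracking chain, and
summarise:

```r
library(metquant)

sim   <- simulate_movie(movie_sim_params(seed = 1))
drift <- estimate_drift(sim$movie)
det   <- detect_nuclei(sim$movie, drift = drift)
trk   <- link_frames(det, max_link_dist_um = 4, n_frames = 31) |>
  curate_tracks(n_frames = 31) |>
  classify_tracks()
trk[, c("z_um", "y_um", "x_um")] <-
  restore_coordinates(trk[, c("frame", "z_um", "y_um", "x_um")], drift,
                      sim$movie$voxel_size_um)[, c("z_um", "y_um", "x_um")]

evaluate_tracking(trk, sim$truth, match_radius_um = 2.5)$fraction_recovered
#> [1] 1

s <- embryo_summary(track_metrics(trk, 2), "embryo1")
cbind(s[, 1:3],
      round(s[, c("velocity_um_per_min", "persistence", "coordination")], 3))
#>   embryo_id cell_type n_tracks velocity_um_per_min persistence coordination
#> 1   embryo1       ICP       15               1.227       0.996        0.997
#> 2   embryo1      PMEC       15               1.227       0.996        0.997
```

All 30 programmed nuclei are recovered as full-length, correctly classified
tracks; the per-embryo mean velocity (µm/min) sits within a few percent of
the programmed 1.2 µm/min directed speed, persistence is near 1 for
directed motion, and coordination is high because 80% of each step
fluctuation is shared across the field.

The profiling side, condensed (one marker, one embryo):

```r
ep  <- epithelium_sim_params(seed = 1)   # apical 0.8 µm / basal 1.3 µm peaks
sq  <- simulate_epithelium(ep)
img <- preprocess_fixed_image(sq$images[["basal_marker"]])
cells <- purrr::map_dfr(1:10, \(i) {
  p <- sample_line_profile(img, sq$rois[i, ], 0.1); p$cell_id <- i; p
})
emb <- average_cell_profiles(cells)
#> Warning: dropping 1 profile(s) outside +/-1 um of the median length
#> Warning: only 9 admissible profiles (expected >= 10)
fwhm(emb, c(10, 20))
#> # A tibble: 1 x 4
#>   fwhm_um amplitude peak_position_um bounded
#>     <dbl>     <dbl>            <dbl> <lgl>
#> 1    1.31      121.             15.0 TRUE
```

The programmed basal peak (FWHM 1.3 µm, amplitude 120, at 15 µm from the
apical membrane) is recovered through the full preprocessing chain; the
similar-length rule fired on one cell whose jittered length fell outside
±1 µm of the median, exactly as it would in a manual analysis.

Config-driven multi-condition studies run through
`run_tracking_pipeline()` / `run_profile_pipeline()` (R lists or YAML; CSV
and JSON reports plus a provenance record). See the methods vignette
(`vignettes/metquant-methods.Rmd`) for models, defaults and validation
design.

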