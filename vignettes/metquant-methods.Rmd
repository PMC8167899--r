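---
title: "Methods: nucleus tracking and apicobasal profiling on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleus tracking and apicobasal profiling on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

metquant quantifies two aspects of a mesenchymal-to-epithelial transition
(MET) in embryonic midgut tissue: how nuclei of two cell populations migrate
in 4D time-lapse stacks, and how polarity markers distribute along the
apical-to-basal axis of the epithelium that forms afterwards. Because the
original embryo recordings are not publicly deposited, every stage is
validated against synthetic data with exact ground truth; this vignette
explains the models behind both pipelines, the defaults, and what the
synthetic validation does and does not demonstrate.

## The tracking pipeline

### Movie model

`simulate_movie()` renders fields of fluorescent nuclei as isotropic 3D
Gaussian blobs whose full width at half maximum equals the nuclear diameter
(`sigma = d / (2 * sqrt(2 * log(2)))`), sampled through anisotropic voxels
(defaults: z step 1.5 µm, 0.25 µm laterally, 2-min frames, 31 frames). Two
populations are drawn: small nuclei around 3 µm ("PMEC-like", the principal
midgut epithelial cells) and large nuclei around 6 µm ("ICP-like", the
interstitial cell precursors), 15 of each. Nuclei advance by

```
step = speed * dt * direction + rho * shared + (1 - rho) * independent
```

with `shared` and `independent` zero-mean Gaussian fluctuations of SD
`step_noise_sd_um` (0.2 µm). The convex mixture makes the correlation of
neighbouring step fluctuations rise monotonically from 0 at `rho = 0` to 1
at `rho = 1`, so the coordination statistic has a tunable expectation. The
default speed is 1.2 µm/min, the wild-type migration speed scale at 25 °C;
the default `rho` is 0.8. A global embryo drift (default (0.1, 0.15, 0)
µm/frame in (z, y, x)) translates the whole field; noise is additive
Gaussian (SD 10 on a 0–255 scale against a blob amplitude of 200), with
optional Poisson resampling.

Geometry choices worth stating explicitly. The lateral field is 512 × 192 px
(128 × 48 µm): thirty frames of directed motion at 1.2 µm/min cover 72 µm,
and a shorter field cannot contain full-length tracks together with a
seeding region in which 30 nuclei fit at resolvable spacing. Nuclei are
seeded as hard spheres (pairwise separation at least the sum of their radii,
floored at 5 µm): nuclei are physical objects, and two 6-µm blobs closer
than about 5 µm merge into a single response minimum at the matching
detection scale, which would make "one track per cell" unattainable by
construction rather than by algorithmic failure. The programmed drift is
transverse to the migration axis: a projection-correlation estimator
measures *overall* field movement, and a drift component parallel to
coherent migration is not separable from the migration itself by any global
estimator — with real embryos this ambiguity is resolved by the experimenter
mounting the sample, here by the study design.

### Drift compensation

`estimate_drift()` cross-correlates maximum-intensity projections of
consecutive frames (z-projection for the lateral shift, y-projection for the
axial one) via FFT, refines the correlation peak to sub-voxel accuracy by a
quadratic fit, accumulates the per-pair displacements and rounds the
cumulative curve to integer voxels. `apply_drift()` shifts each frame
uniformly by minus its cumulative displacement, filling vacated voxels with
the stack's modal background value — integer shifts avoid interpolation
artefacts in the detector. `restore_coordinates()` adds the same shifts back
onto point coordinates, so restore-after-apply is exact by construction.
Detection and linking run on the compensated movie (smaller frame-to-frame
displacements, easier assignment); all track statistics are computed on the
restored, original-frame positions.

### Detection

`detect_nuclei()` runs, per frame and per population scale, a
scale-normalized Laplacian-of-Gaussian filter with per-axis sigma
`radius / sqrt(3)` divided by the voxel size — the LoG optimum for a 3D
Gaussian blob, made anisotropy-aware. Bright blobs give negative minima
whose depth, for matched scale, depends on amplitude but not on blob size,
so qualities are comparable across the 1.5-µm and 3-µm scales. Strict
26-connected local minima (negative response only, borders excluded because
the edge-replicated Laplacian degenerates there) are refined per axis by a
quadratic fit and pruned greedily: candidates are visited by decreasing
quality and accepted only if no accepted candidate lies within the
suppression radius; ties break by scan order for determinism. The two scales
are then merged with the same rule, using the larger radius of each pair.
The default quality threshold is five times the SD of the response volume.
A multiple of the median absolute response (about 2 SD) was considered and
rejected analytically: the deepest minima a pure-noise response produces
reach 4–5 SD, so a 2-SD cut admits false detections by construction, while
5 SD sits far below the matched-blob response at the simulated
signal-to-noise ratio (around 20).

### Linking, curation, classification

`link_frames()` solves, per consecutive frame pair, the linear assignment on
squared distances with birth/death alternatives costed at
`max_link_dist_um^2` (default 4 µm, about 1.7× the fastest programmed
per-frame displacement) and links beyond the gate forbidden. The augmented
square cost matrix (links / diagonal deaths / diagonal births / zero
dummy-dummy block) is solved with a shortest-augmenting-path assignment
solver written for this package; tests compare its total cost with an
independent bitmask dynamic program on a thousand random instances. No gap
closing: the curation rule keeps only tracks spanning every frame, so a
missed detection is fatal to its track, matching the full-span requirement.
`classify_tracks()` labels tracks by the median of the per-frame estimated
diameters (twice the detection scale): below 3.5 µm PMEC, above 5.5 µm ICP,
otherwise unclassified and excluded from statistics. The median, rather than
the mean, makes classification robust to occasional cross-scale detections.

### Track statistics

Instantaneous speed is the 3D frame-to-frame displacement over the frame
interval; track velocity its arithmetic mean. Directional persistence is net
displacement over path length — the standard definition, adopted here
because no formula is given in the sources this follows. Coordination pairs
each track with the track whose first-frame position is nearest (self
excluded, ties to the lower id) and correlates the two instantaneous
velocity series over common frames; the default stacks the (z, y, x)
components into one Pearson correlation, capturing direction and magnitude
jointly, with mean cosine similarity available behind
`method = "cosine"`. Embryo summaries average each metric over an embryo's
tracks per cell type (undefined values drop out of the mean and the defined
count is reported); `compare_groups()` then applies unpaired two-tailed
t tests (classic equal-variance by default, Welch by flag) against the
control and a one-way ANOVA across three or more conditions, with stars at
0.05/0.01/0.001.

## The profiling pipeline

### Epithelium model

`simulate_epithelium()` draws a band of columnar cells (10 cells, 15 ± 1 µm
long, 7 µm wide at 0.1 µm/px) on a mesoderm layer, and renders each marker
as its own image: intensity along the apicobasal axis is a sum of Gaussian
peaks with programmed position, amplitude and FWHM, over a smooth background
gradient plus pixel noise; per-cell multiplicative amplitude jitter (SD 5%)
emulates staining variability. Peak positions are anchored to the apical
membrane so that profiles align across cells of jittered length. Line ROIs
are emitted as ground truth: one vertical 60-px-wide line per cell from 1 µm
above the apical membrane to 1 µm below the basal surface of the mesoderm.
By default images are written with dark signal on a light background,
because the preprocessing chain they feed — 8-bit conversion, inversion,
background subtraction, thresholding, in that order — presumes raw exports
of that polarity. The 1024 × 1024 px field is deliberately much larger than
the cell band: the thresholding step keeps a fixed brightest fraction of the
pooled histogram, and the retained fraction must comfortably exceed the area
the peaks occupy above their half-maximum, otherwise the threshold would cut
into the very flanks the FWHM is read from. With the default geometry the
3% threshold lands near a third of the peak amplitude.

### Preprocessing

`to_8bit_inverted()` maps the input range linearly to 0–255 and inverts.
Data already within an 8-bit range pass through unscaled (the behaviour of
standard image software, and the only choice under which amplitudes keep a
meaningful scale across images); higher-bit data are rescaled from their
observed range. A constant image outside the 8-bit range maps to 0 and
inverts to 255 — a documented degenerate case.
`subtract_background_paraboloid()` estimates the background as the
grayscale opening by a paraboloid of height `d²/(2·radius)` — computed
exactly by 1D lower-envelope erosions and dilations along rows and columns —
and subtracts it. The radius default is 200 px: the structuring surface must
be much flatter than any feature to preserve, and the broadest peaks
measured here (2.4 µm FWHM) are about 36 px wide at their 5% level, where a
50-px paraboloid already creeps several percent up the ridge. The background
is estimated on a 3×3-mean presmoothed copy (and subtracted from the
original), because a morphological envelope slid under a noisy surface rides
the noise's lower tail and biases amplitudes upward by about two noise SDs.
`threshold_stack_histogram()` keeps the brightest 3% of the pooled
histogram: the threshold is the value of the `ceiling(0.03 n)`-th brightest
voxel, everything below is zeroed. The 3% is read as a pixel-count
percentile, not 3% of the intensity scale; the fraction is a parameter.

### Profiles and peaks

`sample_line_profile()` walks the line in pixel steps, averaging a
perpendicular band of bilinear samples (60 px wide, symmetric about the
line), and reports distances from the apical membrane (the line starts 1 µm
above it). `average_cell_profiles()` enforces the similar-length rule
(±1 µm of the median; violators dropped with a warning, fewer than 10
admissible cells warns), aligns profiles at the apical end, interpolates
onto the median-length grid and averages pointwise; `condition_average()`
repeats this across embryos and keeps the per-embryo curves for the
standard plot (dashed black embryo curves, solid red condition mean).
`peak_amplitude()` takes the windowed maximum (apical window 0–10 µm, basal
10–20 µm, configurable per marker) with parabolic position refinement;
multiple peaks in one window resolve to the global maximum. `fwhm()` walks
outward from the peak to the first crossings of half the amplitude above a
zero baseline (profiles are background-subtracted and thresholded
upstream), locating each crossing by linear interpolation; a flank that
never descends to the half level flags the peak unbounded rather than
guessing. `nuclear_mean_gray()` averages elliptical nucleus ROIs and then
the 30 per-nucleus means into one embryo value.

## Validation design and problem sizes

The test suite checks each stage against ground truth or an independent
oracle: blob centroids against programmed positions; drift against the
programmed displacement (on static-cell movies, since collective migration
is part of "overall movement" for any global estimator); assignment cost
against a brute-force dynamic program; statistics against closed forms;
FWHM against the generating Gaussians (including the closed form
`2·sqrt(2·ln 2)·σ`) over the programmed range 0.8–2.4 µm; and two
end-to-end studies in which a "mutant" arm programmed slower, less
coordinated and broader-peaked than its control must be detected in the
correct direction at p ≤ 0.05 with six embryos per arm, across ten
replicate seeds. The replicate studies use reduced problem sizes chosen as
the smallest that keep every per-arm estimate far above its sampling noise
at the programmed effect sizes — 8-frame movies of 8 + 8 nuclei in a
96 × 288 px field, and 512 × 512 px epithelium images of 6 cells — while the
single-study checks run at the full default sizes.

What passing these tests shows: the implementation recovers what it is
programmed to see, at realistic noise, calibration anisotropy and drift. What
it does not show: robustness to phenomena the generator deliberately omits —
photobleaching, cell division and death, nuclear deformation, non-rigid
tissue movement, segmentation-grade size estimation (diameters come from the
detection scale, not from boundaries), or densities beyond the hard-sphere
seeding. Real-data use should treat those as open validation questions.

## Reproducing the numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` re-runs both
pipelines from scratch at the default study conditions and writes the
recovered quantities (tracking recovery fraction, wild-type-scale velocity,
persistence and coordination, drift error, assignment mismatches, the
analytic statistic cases, recovered FWHMs, and the two-arm contrast
p-values) as JSON. All randomness derives from the given seed.
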