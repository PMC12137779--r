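# cdtimoco

Respiratory motion correction and diffusion-tensor mapping for
free-breathing cardiac diffusion MRI.

## What it does, and for whom

Free-breathing cardiac DTI acquires diffusion-weighted (DW) spin-echo EPI
frames over many heart beats; each frame catches the heart at a different
respiratory position, dominantly shifted head-foot in short-axis view.
Fitting tensors to misaligned frames corrupts the mean diffusivity (MD),
fractional anisotropy (FA) and helix-angle (HA) maps that cardiac DTI
exists to measure. This package, aimed at cardiac MR physicists and image
analysts, provides the full post-processing chain:

* a pair-wise **symmetric, inverse-consistent deformable 2D registration**
  engine (log-domain diffeomorphic demons: forward map `exp(v)`, inverse
  `exp(-v)` from one stationary velocity field, so the two fields are
  mutually inverse by construction), with a locally normalised,
  polarity-corrected similarity force that registers b50 frames to b500
  frames without chasing diffusion contrast;
* two **motion-correction schedules**: `moco_naive()` (every frame to the
  first low-b frame) and `moco_avg()` (low-b frames averaged into a
  high-SNR reference; high-b frames registered to it, averaged per
  direction, and re-registered, with transforms composed so each frame is
  resampled once);
* **tensor fitting and cardiac maps**: cubic-spline interpolation to a
  1.4 mm grid, per-pixel weighted linear least squares on
  `ln S = ln S0 - b g'Dg`, MD / FA / helix-angle maps over an LV
  coordinate system built from endo/epi contours, and helix-angle
  transmurality (HAT, deg/% depth) as sector-wise OLS slopes of HA against
  transmural depth;
* the **epicardium line-tracking metric**: per-frame argmax of the
  unfiltered forward first difference along a head-foot line, whose
  population SD over frames quantifies residual motion, plus paired
  t-tests with Bonferroni correction;
* a **synthetic free-breathing phantom** with complete ground truth
  (motion fields, tensors, helix structure) emulating the target
  acquisition: 12 directions, 1 average at b = 50 s/mm^2 and 8 at
  b = 500 s/mm^2 per direction (108 frames/slice), 128 x 48 matrix at
  2.7 mm, sinusoidal head-foot respiration.

## Worked example

```r
library(cdtimoco)

# simulate one free-breathing short-axis slice (5 px respiratory motion,
# myocardial SNR 20) with ground truth
ph <- make_phantom(phantom_params(snr = 20, motion_amplitude_px = 5, seed = 1))
ph$series
#> <image_series> 108 frame(s) of 128 x 48 px @ 2.70 x 2.70 mm, slice 0
#>   b-values: 50, 500 s/mm^2; 12 direction(s)

# correct it with the averaged-reference schedule
res <- moco(ph$series, "avg")
res
#> <moco_result> strategy 'avg': 108 corrected frame(s), 24 averaged frame(s)
#>   mean |field| 2.858 px; 0 frame(s) flagged for inverse-consistency

# residual motion before and after, by epicardium line tracking
ln <- ph$truth$line
before <- track_line(ph$series, ln$start, ln$end, ln$window_center,
                     n_samples = ln$n_samples)
after  <- track_line(res$corrected_series, ln$start, ln$end, ln$window_center,
                     n_samples = ln$n_samples)
c(sd_before = before$sd, sd_after = after$sd)
#> sd_before  sd_after
#> 3.4998898 0.2133652

# tensor maps on the corrected, averaged series
interp <- interpolate_series(res$averaged_series)
geom <- build_geometry(rescale_contours(ph$truth$contours, c(2.7, 2.7), c(1.4, 1.4)),
                       dim(interp$frames)[1:2], c(1.4, 1.4))
tf <- fit_tensor(interp, series_scheme(interp, ph$truth$directions), geom$mask)
glance(tf)
#> # A tibble: 1 x 5
#>   n_pixels md_mean md_sd fa_mean  fa_sd
#>      <int>   <dbl> <dbl>   <dbl>  <dbl>
#> 1     1550    1.42 0.161   0.323 0.0503

ha <- helix_angle(tensor_maps(tf)$e1, geom)
hat(ha, geom)$global
#> [1] -1.150828
```

Reading the numbers: the uncorrected epicardium wanders with SD 3.5
(interpolated) pixels; after correction it is stable to 0.21 px. The fitted
myocardium recovers MD 1.42 um^2/ms against a ground truth of 1.40, FA 0.32
against 0.361 (slightly low at this SNR from boundary partial volume), and a
helix-angle transmurality of -1.15 deg/% against the prescribed -1.2 (a
known ~2-4% partial-volume slope shrink, discussed in the vignette).

`autoplot(after)` draws the line-versus-frame image with the tracked
epicardium overlaid; `autoplot(tf)` and `plot_helix_angle(ha, geom)` render
the maps. `run_pipeline()` orchestrates the whole chain from a YAML
configuration and writes NIfTI maps, CSV summaries and a resolved config;
`inst/cli/cdti.R` exposes the same steps as shell subcommands
(`phantom`, `moco`, `fit`, `track`, `run`).

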