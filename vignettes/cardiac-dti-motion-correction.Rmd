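---
title: "Respiratory motion correction and tensor mapping for free-breathing cardiac diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory motion correction and tensor mapping for free-breathing cardiac diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac diffusion tensor imaging (DTI) maps the microstructure of the
myocardium from diffusion-weighted (DW) spin-echo EPI frames acquired over
many heart beats. Under free breathing, each frame is acquired at a
different respiratory state, so the heart sits at a different in-plane
position (dominantly head-foot in short-axis orientation) from frame to
frame. Averaging or tensor-fitting misaligned frames corrupts the mean
diffusivity (MD), fractional anisotropy (FA) and helix-angle (HA) maps.
`cdtimoco` implements a registration-based motion-correction (MOCO)
pipeline for such data: every frame is brought onto a common reference grid
by pair-wise symmetric, inverse-consistent deformable 2D registration, after
which the standard per-direction averaging, interpolation and tensor fit
proceed as if the acquisition had been breath-held.

The emulated acquisition protocol per slice is: 12 diffusion directions;
one average at the low b-value (50 s/mm^2, the near-baseline "b0" shell)
followed by eight averages per direction at the high b-value (500 s/mm^2);
matrix 128 x 48 at 2.7 x 2.7 mm in-plane. That gives 108 frames per slice.

## The registration engine

`register_pair()` is a log-domain diffeomorphic demons scheme. A single
stationary velocity field $v$ is optimised; the forward map is
$\exp(v)$ and the inverse map $\exp(-v)$, both computed by scaling and
squaring, so the two returned displacement fields are mutually inverse *by
construction* — inverse consistency is structural, not a penalty. The force
is symmetric: at each iteration the update is
$\tfrac12\,(F(\text{fixed}\!\to\!\text{warped moving}) -
F(\text{moving}\!\to\!\text{warped fixed}))$, which also makes the result
nearly symmetric under swapping the two images.

Three design choices matter for DW frames specifically, where the engine
must align b50 frames to b500 frames "without probing diffusion contrast":

* **Locally normalised, polarity-corrected force.** Images are locally
  normalised (Gaussian-window mean/variance) before the force is evaluated,
  which removes global and slowly varying contrast differences. On top of
  that, the residual that drives the force is confidence-weighted by the
  local correlation $\rho$ between the target and the warped source:
  $d = \rho\,\text{warped} - |\rho|\,\text{target}$. Where the two
  contrasts agree up to a local gain *of either sign* — e.g. at the
  endocardial border, where the blood pool is bright at b50 and dark at
  b500, inverting the edge polarity — $|\rho| \to 1$ and the force restores
  alignment; where the patterns genuinely differ (diffusion contrast inside
  the wall, noise) $|\rho| \to 0$ and the force vanishes.
* **Stiff velocity regularisation** (`sigma_diffusion` = 12 px). Respiratory
  motion is near-rigid at the scale of the LV wall. A floppy field (1-2 px
  smoothing) measurably chased the direction-dependent diffusion contrast
  inside the wall, rotating the fitted eigenvectors by several degrees even
  on noiseless data. Uniform (translational) velocity components pass
  through Gaussian smoothing unattenuated, so stiffness does not limit
  translation recovery.
* **An identity gate** (`min_gain` = 0.005). After optimisation the engine
  compares the mean local correlation of the warped pair against the
  unwarped pair, *on lightly smoothed copies of the images* — smoothing
  removes the spurious gain a deformation earns by fitting pixel noise. If
  the deformation does not pay its way, the identity transform is returned.
  Aligned frames (including cross-contrast pairs of identical geometry) are
  therefore left untouched, while genuine motion of 0.5 px or more produces
  similarity gains roughly an order of magnitude above the gate.

Remaining parameters: 3 pyramid levels with fixed iteration counts
(50/30/15, coarsest first — fixed counts keep the engine deterministic),
fluid smoothing of each update (4 px), local-correlation window (4 px),
4 scaling-and-squaring steps, update step scale 2. Forces are zeroed on a
2-px border and all sampling is edge-clamped. Inside the demons loop the
large-width velocity smoothing uses a 5-pass cascaded box filter (a
standard O(1)-per-pixel Gaussian approximation; kernel deviation about 6%
of peak) — at 12 px an exact FIR kernel would dominate the runtime.

## The two correction schedules

`moco_naive()` registers every frame to the first acquired b50 frame.
`moco_avg()` proceeds in three stages: (1) all b50 frames are registered to
the first acquired b50 frame and averaged into a high-SNR reference;
(2) every high-b frame is registered to that reference and averaged within
its diffusion direction; (3) each per-direction average is registered to the
reference once more. Stage-2 and stage-3 transforms are composed and each
original frame is resampled *once* (single-warp accumulation), so repeated
interpolation does not blur the averages. The low-b output keeps the twelve
individually corrected b50 frames (each direction has only one average).
Frames whose inverse-consistency error exceeds 10 x `ic_tol` are flagged in
the diagnostics but never discarded automatically — outlier rejection is
left to the user.

With the identity gate, stage 3 is usually a no-op on well-corrected data;
it exists for the case where per-frame registration left a residual that
only becomes visible (and correctable) after averaging.

## Tensor fitting and cardiac maps

Frames are resampled to a 1.4 x 1.4 mm grid (separable natural cubic
splines) before fitting. The tensor is estimated per pixel from the
log-linear model $\ln S = \ln S_0 - b\, g^\top D g$ by weighted linear
least squares: an OLS pass initialises the fit and one reweighting pass
with weights equal to the squared predicted signals follows. Both shells
carry diffusion encoding (the b50 shell is treated as a weighted
measurement with its own directions, not as a pure baseline). Non-positive
signals are excluded per pixel below a floor of 1e-6 times the series
maximum; pixels with fewer than 7 usable measurements are dropped.
Eigenvalues are clipped at zero before any scalar map; MD is their mean
(um^2/ms) and FA the usual normalised dispersion.

The LV coordinate system comes from endo/epi contours: the wall mask is the
set of pixels between the rasterised polygons; transmural depth is the
two-distance normalisation $100\,a/(a+b)$ of signed distances to the two
contours (0% endocardium, 100% epicardium); the radial direction follows
the depth gradient, the longitudinal direction is the slice normal, and the
circumferential direction completes the right-handed orthonormal triad.
The helix angle is the signed angle, in the circumferential-longitudinal
tangent plane, between the circumferential direction and the projected
primary eigenvector, with the antipodal sign fixed so the circumferential
component is non-negative; pixels whose tangent-plane projection norm falls
below 0.2 are masked. Helix-angle transmurality (HAT, degrees per percent
depth) is estimated as the ordinary-least-squares slope of HA against depth
within each of 6 equal angular sectors about the mask centroid, averaged
over sectors; sectors with fewer than 10 valid pixels are excluded. This
slope-based estimator is the simplest one consistent with HAT's units, and
it reproduces a prescribed linear HA profile exactly.

ROI summaries use the population (divide-by-N) standard deviation, with the
global row defined as the arithmetic mean of the per-slice statistics.

## The residual-motion metric

`track_line()` reproduces the line-tracking measure used to grade MOCO:
intensity profiles are sampled along a manually placed head-foot line
across the heart (after the same 1.4 mm interpolation used for mapping);
per frame, the epicardium index is the argmax of the *unfiltered forward
first difference* of the profile within a 10-pixel window around the
expected epicardial position (ties break toward the window centre); the
population SD of the indices over all frames is the residual-motion
statistic. `compare_groups()` supplies the paired two-sided t-test with
Bonferroni adjustment ($p_{adj} = \min(1, p \cdot m)$); identical samples
are reported as $t = 0$, $p = 1$ by convention, and a constant non-zero
paired difference (zero variance) as $p = 0$ with a warning. The signed
maximum of the derivative is used (the edge of interest is a signal rise);
`use_magnitude = TRUE` switches to the absolute value.

## The synthetic phantom

`make_phantom()` generates the study conditions the pipeline is validated
under. The anatomy is a short-axis slice: an LV wall annulus (endo radius 8
px, epi radius 14 px — a 16 mm wall at 2.7 mm pixels), a bright blood pool
(free-water-like isotropic diffusion, 3.0 um^2/ms), lung anterior to the
heart (near-zero signal, as in thoracic DW-EPI — this is what makes the
anterior epicardial rise the dominant edge the tracking metric presumes),
and diaphragm/liver-equivalent tissue inferior (slow isotropic). Myocardial
tensors have eigenvalues (2.0, 1.2, 1.0) um^2/ms — MD 1.4, FA 0.361 — with
the primary eigenvector in the circumferential-longitudinal plane at a
helix angle varying linearly from +60 deg (endo) to -60 deg (epi), i.e. a
true transmurality of -1.2 deg/%. Signals follow
$S = S_0 \exp(-b\,g^\top D g)$ rendered on a 3x supersampled grid and
block-averaged down (partial-volume averaging, the dominant resolution
effect of the acquisition). The 12 directions are spread electrostatically
on the half-sphere, deterministically from the seed.

Motion is a sinusoidal head-foot translation (default amplitude 5 px,
period 11.3 frames — deliberately non-integer so the frames sample many
respiratory phases, with the first frame at the zero-displacement phase so
the reference grid coincides with the truth grid), optionally plus a
smooth non-rigid component scaled by the same trace
(`deformation_fraction`). Rician noise is added as the magnitude of a
complex Gaussian perturbation with sigma set by the requested myocardial
SNR at b50. Ground truth (per-frame pull-back motion fields, clean series,
geometry, HA/MD/FA/HAT values) is emitted alongside.

The tracking line that the phantom recommends is calibrated on the
noiseless unique frames only: candidate sub-pixel line offsets are scored
by how stable the tracked integer index is under small line perturbations,
and the most stable placement is kept. This is the phantom's analog of the
operator placing line and window by hand — an edge sitting exactly on an
inter-sample boundary would give an index SD of 0.5 px even under perfect
correction, purely from quantisation.

What the phantom does *not* emulate: through-plane motion (the pipeline is
2D, matching the acquisition's limitation), EPI distortion and eddy
currents, cardiac-phase strain, respiratory hysteresis, and realistic
breathing spectra. Passing the phantom therefore demonstrates correctness
of the algorithms under controlled in-plane conditions, not robustness to
every artifact of in vivo data.

## Validation scale and known limitations

The bundled tests validate the full pipeline at protocol scale (108-frame
series, 128 x 48) across five phantom seeds for the noisy conditions, with
smaller phantoms (64 x 48, two high-b averages) for unit-level properties;
the summary script (`scripts/acceptance.R`) uses five phantoms for the
motion-correction effectiveness measurements and three for the
strategy-ordering comparison. These sizes were chosen to exercise every
code path at realistic geometry while keeping a full run in the tens of
minutes on one core.

Two measured limitations are worth knowing:

* **HAT carries a small partial-volume bias.** On the noiseless motion-free
  phantom the recovered transmurality is about 2% shallower than the
  prescribed slope: the outermost depth deciles of the HA map are biased by
  roughly +-3 deg because each boundary pixel's myocardial content is
  centred deeper (endo) or shallower (epi) than the pixel centre. The
  estimator itself is exact on the true HA map; the bias is measurement
  physics of a 1.4 mm grid on a 16 mm wall and would shrink with thicker
  walls or finer acquisition.
* **The two schedules are equivalent on these conditions.** With the
  converged engine, naive and averaged-reference correction produce
  image-RMSE differences of at most a few tenths of a percent with no
  consistent ordering — consistent with the volunteer-level finding that
  the two schedules do not differ significantly. The averaged reference
  shows its robustness advantage when convergence is marginal (e.g. under a
  reduced iteration budget) or, in vivo, in failure-prone patient data;
  neither regime is part of the default phantom conditions.

## Conventions and numerical choices

* In-memory coordinates are R-native 1-based `(row, col)`; the row axis is
  the head-foot direction. On-disk sidecar metadata keeps 0-based
  `direction_index` / `average_index` / `acquisition_order` labels.
* Displacement fields use the pull-back convention
  `out(p) = in(p + d(p))`, in pixels, with edge-clamped sampling.
* All randomness (directions, deformation pattern, noise) derives from the
  phantom seed through isolated RNG scopes; repeated calls with one seed
  are bit-identical, and the caller's RNG stream is never disturbed.
* Degenerate inputs: tensors with a vanishing leading eigenvalue gap are
  flagged and excluded from direction-dependent maps; flat tracking
  profiles fall back to the window centre with a warning; zero-variance
  paired comparisons are reported by convention rather than erroring.
* The gradient-direction reference frame is the image frame. Real
  acquisitions may deliver scanner-frame bvecs; reorient before fitting if
  the two differ.
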