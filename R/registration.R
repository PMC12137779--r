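#' Registration parameters
#'
#' Settings for the symmetric, inverse-consistent deformable registration
#' engine (log-domain diffeomorphic demons with a locally normalised,
#' contrast-robust similarity force).
#'
#' @param n_levels Pyramid depth (coarse-to-fine, downsampling x2 per level).
#' @param iters_per_level Iteration counts, coarsest first; length `n_levels`.
#'   Iteration counts are fixed (no tolerance-based early exit) so results are
#'   deterministic.
#' @param sigma_fluid Gaussian smoothing (pixels) of each update field
#'   ("fluid" regularisation).
#' @param sigma_diffusion Gaussian smoothing (pixels) of the accumulated
#'   velocity field ("diffusion" regularisation). The default is deliberately
#'   stiff: respiratory motion is near-rigid at the scale of the LV wall, and
#'   a floppy field would chase per-direction diffusion contrast instead of
#'   motion. Uniform (translational) velocity components pass through the
#'   smoothing unattenuated, so large stiffness does not limit translation
#'   recovery.
#' @param lncc_window_sigma Gaussian window (pixels) of the local intensity
#'   normalisation that makes the force robust to b-value contrast changes.
#' @param n_squaring_steps Scaling-and-squaring steps used to exponentiate the
#'   stationary velocity field.
#' @param step_scale Multiplier on the demons update.
#' @param ic_tol Inverse-consistency tolerance (pixels, mean norm) used by
#'   downstream quality flags.
#' @param min_gain Identity gate: the optimised deformation is accepted only
#'   if it raises the mean local correlation between lightly smoothed copies
#'   of the images by at least this much over the unwarped pair; otherwise
#'   the identity transform is returned. Smoothing the images before scoring
#'   removes the apparent gain a deformation earns by fitting pixel noise,
#'   so already-aligned frames stay untouched while genuine motion, whose
#'   gain survives smoothing, is always corrected.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(n_levels = 3L,
                                iters_per_level = c(50L, 30L, 15L),
                                sigma_fluid = 4.0,
                                sigma_diffusion = 12.0,
                                lncc_window_sigma = 4.0,
                                n_squaring_steps = 4L,
                                step_scale = 2.0,
                                ic_tol = 0.1,
                                min_gain = 0.005) {
  p <- list(
    n_levels = as.integer(n_levels),
    iters_per_level = as.integer(iters_per_level),
    sigma_fluid = sigma_fluid,
    sigma_diffusion = sigma_diffusion,
    lncc_window_sigma = lncc_window_sigma,
    n_squaring_steps = as.integer(n_squaring_steps),
    step_scale = step_scale,
    ic_tol = ic_tol,
    min_gain = min_gain
  )
  if (p$n_levels < 1) stop("n_levels must be >= 1")
  if (length(p$iters_per_level) != p$n_levels) {
    stop("iters_per_level must have one entry per pyramid level")
  }
  nums <- unlist(p[c("sigma_fluid", "sigma_diffusion", "lncc_window_sigma",
                     "n_squaring_steps", "step_scale", "ic_tol")])
  if (any(nums <= 0) || any(p$iters_per_level <= 0)) {
    stop("all registration parameters must be positive")
  }
  structure(p, class = "registration_params")
}

# A dense displacement field: list(dr, dc) of matrices, pixel units.
disp_field <- function(dr, dc) {
  structure(list(dr = dr, dc = dc), class = "disp_field")
}

zero_field <- function(shape) {
  z <- matrix(0, shape[1], shape[2])
  disp_field(z, z)
}

field_max_abs <- function(f) max(abs(f$dr), abs(f$dc))

#' Warp an image by a displacement field
#'
#' Pull-back convention: `out(p) = image(p + field(p))`, so the field maps
#' output-grid points into the input image. Out-of-bounds samples take the
#' nearest edge value.
#'
#' @param image 2D numeric matrix.
#' @param field A displacement field (`list(dr, dc)` of matrices, pixels).
#' @param mode `"linear"` (bilinear) or `"nearest"` interpolation.
#' @return The warped matrix.
#' @export
warp <- function(image, field, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!all(dim(image) == dim(field$dr))) stop("image and field shapes differ")
  if (mode == "linear") {
    cpp_warp_bilinear(image, field$dr, field$dc)
  } else {
    cpp_warp_nearest(image, field$dr, field$dc)
  }
}

#' Compose two displacement fields
#'
#' Returns the field of the composed map: `(f o g)(p) = g(p) + f(p + g(p))`,
#' with `f` sampled bilinearly. Warping by the result equals warping by `g`
#' then by `f` under the pull-back convention.
#'
#' @param f,g Displacement fields of equal shape.
#' @return A displacement field.
#' @export
compose_fields <- function(f, g) {
  h <- cpp_compose(f$dr, f$dc, g$dr, g$dc)
  disp_field(h$dr, h$dc)
}

# exp of a stationary velocity field by scaling and squaring.
field_exp <- function(v, n_steps) {
  e <- cpp_field_exp(v$dr, v$dc, n_steps)
  disp_field(e$dr, e$dc)
}

#' Mean inverse-consistency error of a field pair
#'
#' Mean Euclidean norm, over interior pixels, of the composition of the
#' forward and inverse fields (zero for perfectly mutually inverse maps). The
#' interior excludes a border wide enough that edge-clamped sampling cannot
#' contaminate the estimate.
#'
#' @param pair A `displacement_field_pair` (or `list(forward, inverse)`).
#' @return Mean residual displacement norm in pixels.
#' @export
inverse_consistency_error <- function(pair) {
  h1 <- compose_fields(pair$forward, pair$inverse)
  h2 <- compose_fields(pair$inverse, pair$forward)
  margin <- max(2, ceiling(max(field_max_abs(pair$forward), field_max_abs(pair$inverse))) + 1)
  nr <- nrow(h1$dr)
  nc <- ncol(h1$dr)
  if (2 * margin + 1 >= nr || 2 * margin + 1 >= nc) margin <- 0
  rows <- (1 + margin):(nr - margin)
  cols <- (1 + margin):(nc - margin)
  e1 <- sqrt(h1$dr[rows, cols]^2 + h1$dc[rows, cols]^2)
  e2 <- sqrt(h2$dr[rows, cols]^2 + h2$dc[rows, cols]^2)
  mean(c(e1, e2))
}

#' Jacobian determinant map of a displacement field
#'
#' Determinant of the Jacobian of the map `p + field(p)`; positive values
#' indicate a locally invertible (fold-free) deformation.
#'
#' @param field A displacement field.
#' @return Matrix of determinant values.
#' @export
jacobian_determinant <- function(field) {
  gr <- image_gradient(field$dr)
  gc <- image_gradient(field$dc)
  (1 + gr$dr) * (1 + gc$dc) - gr$dc * gc$dr
}

# Local intensity normalisation: subtract a Gaussian-window local mean and
# divide by the local standard deviation (regularised). Two images normalised
# this way can be compared by an SSD-type force irrespective of their global
# contrast, which is what lets b50 frames register to b500 frames.
local_normalize <- function(img, sigma) {
  mu <- cpp_gauss_smooth(img, sigma)
  v <- cpp_gauss_smooth(img^2, sigma) - mu^2
  v[v < 0] <- 0
  eps <- 0.1 * stats::sd(as.vector(img)) + 1e-12
  (img - mu) / (sqrt(v) + eps)
}

#' Mean local normalized cross-correlation of two images
#'
#' Gaussian-window local correlation coefficient, averaged over pixels.
#' Used as the similarity score reported by [register_pair()].
#'
#' @param a,b Matrices of equal shape.
#' @param sigma Gaussian window width in pixels.
#' @return Scalar in `[-1, 1]`.
#' @export
lncc <- function(a, b, sigma = 4) {
  mu_a <- cpp_gauss_smooth(a, sigma)
  mu_b <- cpp_gauss_smooth(b, sigma)
  va <- pmax(cpp_gauss_smooth(a^2, sigma) - mu_a^2, 0)
  vb <- pmax(cpp_gauss_smooth(b^2, sigma) - mu_b^2, 0)
  cab <- cpp_gauss_smooth(a * b, sigma) - mu_a * mu_b
  eps <- 1e-5 * (stats::sd(a) + stats::sd(b)) + 1e-12
  mean(cab / (sqrt(va * vb) + eps^2))
}

# Local correlation coefficient within a Gaussian window (regularised).
local_corr <- function(a, b, sigma) {
  mu_a <- cpp_gauss_smooth(a, sigma)
  mu_b <- cpp_gauss_smooth(b, sigma)
  va <- pmax(cpp_gauss_smooth(a^2, sigma) - mu_a^2, 0)
  vb <- pmax(cpp_gauss_smooth(b^2, sigma) - mu_b^2, 0)
  cab <- cpp_gauss_smooth(a * b, sigma) - mu_a * mu_b
  cab / (sqrt(va * vb) + 1e-3)
}

# One pyramid level of symmetric log-domain demons. f, m are the (already
# locally normalised) fixed and moving images at this level; v the velocity.
#
# The residual driving the force is polarity-corrected and confidence-
# weighted by the local correlation rho between the target and the warped
# source: d = |rho| * (sign(rho) * warped - target). Where the two contrasts
# agree up to a local gain of either sign (consistent edges) |rho| -> 1 and
# the force restores alignment; where the patterns genuinely differ
# (diffusion contrast, noise) |rho| -> 0 and the force vanishes, so the
# engine does not chase b-value contrast. The iteration itself runs in
# compiled code.
demons_level <- function(f, m, v, params, iters) {
  out <- cpp_demons_level(
    f, m, v$dr, v$dc, iters,
    params$sigma_fluid, params$sigma_diffusion, params$lncc_window_sigma,
    params$n_squaring_steps, params$step_scale
  )
  disp_field(out$dr, out$dc)
}

# Gaussian anti-aliased downsampling by a factor of 2 (bilinear resize).
pyr_down <- function(img) {
  sm <- cpp_gauss_smooth(img, 1.0)
  cpp_resize_bilinear(sm, max(1L, ceiling(nrow(img) / 2)), max(1L, ceiling(ncol(img) / 2)))
}

#' Pair-wise symmetric, inverse-consistent deformable registration
#'
#' Registers `moving` to `fixed` with a multi-resolution, log-domain
#' diffeomorphic demons scheme. A single stationary velocity field `v` is
#' optimised with a symmetric force; the forward map is `exp(v)` and the
#' inverse map `exp(-v)` (scaling and squaring), so the two returned fields
#' are mutually inverse by construction. Intensities are locally normalised
#' within a Gaussian window before the force is evaluated, which makes the
#' engine robust to the contrast difference between b-value shells.
#'
#' @param fixed,moving 2D numeric matrices of equal shape with finite values.
#' @param params A [registration_params()].
#' @return A `displacement_field_pair`: list with `forward` (maps fixed-grid
#'   points into the moving image; `warp(moving, forward)` aligns to `fixed`),
#'   `inverse` (the reverse map), `ic_error`, `similarity_before`,
#'   `similarity_after` (mean LNCC of lightly smoothed copies, the gate's own score), `gated` (`TRUE` when the identity
#'   transform was returned because the deformation did not pay its way; see
#'   `min_gain`), and `params`. Non-convergence is not an error: the best of
#'   the final iterate and the identity is returned.
#' @export
register_pair <- function(fixed, moving, params = registration_params()) {
  if (!all(dim(fixed) == dim(moving))) stop("fixed and moving must share one shape")
  if (!all(is.finite(fixed)) || !all(is.finite(moving))) stop("image intensities must be finite")

  # image pyramids on the locally normalised images
  fn <- local_normalize(fixed, params$lncc_window_sigma)
  mn <- local_normalize(moving, params$lncc_window_sigma)
  pyr_f <- vector("list", params$n_levels)
  pyr_m <- vector("list", params$n_levels)
  pyr_f[[params$n_levels]] <- fn
  pyr_m[[params$n_levels]] <- mn
  if (params$n_levels > 1) {
    for (l in (params$n_levels - 1):1) {
      pyr_f[[l]] <- pyr_down(pyr_f[[l + 1]])
      pyr_m[[l]] <- pyr_down(pyr_m[[l + 1]])
    }
  }

  v <- zero_field(dim(pyr_f[[1]]))
  for (l in seq_len(params$n_levels)) {
    if (l > 1) {
      shp <- dim(pyr_f[[l]])
      sr <- shp[1] / nrow(v$dr)
      sc <- shp[2] / ncol(v$dr)
      v <- disp_field(
        cpp_resize_bilinear(v$dr, shp[1], shp[2]) * sr,
        cpp_resize_bilinear(v$dc, shp[1], shp[2]) * sc
      )
    }
    v <- demons_level(pyr_f[[l]], pyr_m[[l]], v, params, params$iters_per_level[l])
  }

  forward <- field_exp(v, params$n_squaring_steps)
  inverse <- field_exp(disp_field(-v$dr, -v$dc), params$n_squaring_steps)
  # similarity (and the gate gain) is measured on lightly smoothed images:
  # apparent gains from fitting pixel noise evaporate under smoothing,
  # gains from genuine motion survive it
  fs <- cpp_gauss_smooth(fixed, 1)
  sim_before <- lncc(fs, cpp_gauss_smooth(moving, 1), params$lncc_window_sigma)
  sim_after <- lncc(fs, cpp_gauss_smooth(warp(moving, forward), 1),
                    params$lncc_window_sigma)
  gated <- sim_after - sim_before < params$min_gain
  if (gated) {
    # no meaningful similarity gain: prefer the identity transform
    z <- zero_field(dim(fixed))
    forward <- z
    inverse <- z
    sim_after <- sim_before
  }
  pair <- structure(
    list(forward = forward, inverse = inverse, params = params, gated = gated),
    class = "displacement_field_pair"
  )
  pair$ic_error <- inverse_consistency_error(pair)
  pair$similarity_before <- sim_before
  pair$similarity_after <- sim_after
  pair
}

#' @export
print.displacement_field_pair <- function(x, ...) {
  cat(sprintf(
    "<displacement_field_pair> %d x %d px; mean |fwd| %.3f px; IC error %.4f px; LNCC %.3f -> %.3f\n",
    nrow(x$forward$dr), ncol(x$forward$dr),
    mean(sqrt(x$forward$dr^2 + x$forward$dc^2)),
    x$ic_error %||% NA_real_,
    x$similarity_before %||% NA_real_, x$similarity_after %||% NA_real_
  ))
  invisible(x)
}

#' Save / load a displacement field pair as 2-channel NIfTI
#'
#' Channels along the third axis are the row- and column-displacement in
#' pixels; forward and inverse are written side by side as channels 1:2 and
#' 3:4.
#'
#' @param pair A `displacement_field_pair`.
#' @param path Output NIfTI path.
#' @return Invisibly `path`; `read_field_pair` returns the pair.
#' @export
write_field_pair <- function(pair, path) {
  a <- array(0, dim = c(dim(pair$forward$dr), 4))
  a[, , 1] <- pair$forward$dr
  a[, , 2] <- pair$forward$dc
  a[, , 3] <- pair$inverse$dr
  a[, , 4] <- pair$inverse$dc
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "float"), path, datatype = "float")
  invisible(path)
}

#' @rdname write_field_pair
#' @export
read_field_pair <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  pair <- structure(
    list(
      forward = disp_field(a[, , 1], a[, , 2]),
      inverse = disp_field(a[, , 3], a[, , 4])
    ),
    class = "displacement_field_pair"
  )
  pair$ic_error <- inverse_consistency_error(pair)
  pair
}
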