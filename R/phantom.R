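# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Phantom parameters
#'
#' Study conditions of the synthetic free-breathing short-axis cardiac DWI
#' phantom. Defaults follow the emulated acquisition protocol: 128 x 48
#' matrix at 2.7 x 2.7 mm, 12 diffusion directions, one low-b average
#' (b = 50 s/mm^2) followed by eight high-b averages (b = 500 s/mm^2) per
#' direction, respiratory displacement dominantly along the row (head-foot)
#' axis.
#'
#' @param shape Grid size `(rows, cols)`.
#' @param spacing_mm In-plane pixel spacing.
#' @param center LV centre `(row, col)`; default mid-grid.
#' @param r_endo,r_epi Endo-/epicardial radii in pixels.
#' @param ha_endo,ha_epi Helix angle (degrees) at the endo- and epicardium;
#'   HA varies linearly with transmural depth, so the true transmurality is
#'   `(ha_epi - ha_endo) / 100` degrees/percent.
#' @param eigenvalues Myocardial tensor eigenvalues in um^2/ms, descending.
#' @param b_low,b_high Shell b-values, s/mm^2.
#' @param n_directions Diffusion directions (spread electrostatically on the
#'   half-sphere, deterministically from `seed`).
#' @param n_averages_high Repeats of each high-b direction.
#' @param motion_amplitude_px Peak respiratory translation, pixels.
#' @param motion_period_frames Frames per respiratory cycle. The default is
#'   deliberately non-integer so frames sample many phases of the cycle, as
#'   free-breathing acquisition does.
#' @param motion_axis `"row"` (head-foot) or `"col"`.
#' @param deformation_fraction Amplitude of a smooth non-rigid component,
#'   relative to the translation (0 = rigid motion only).
#' @param snr Reference-region SNR at the low b-value (`Inf` = noiseless);
#'   the Rician noise level is `sigma = mean LV myocardial signal at b_low / snr`.
#' @param seed RNG seed for directions, deformation pattern and noise.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(128L, 48L),
                           spacing_mm = c(2.7, 2.7),
                           center = NULL,
                           r_endo = 8,
                           r_epi = 14,
                           ha_endo = 60,
                           ha_epi = -60,
                           eigenvalues = c(2.0, 1.2, 1.0),
                           b_low = 50,
                           b_high = 500,
                           n_directions = 12L,
                           n_averages_high = 8L,
                           motion_amplitude_px = 5,
                           motion_period_frames = 11.3,
                           motion_axis = c("row", "col"),
                           deformation_fraction = 0,
                           snr = Inf,
                           seed = 1L) {
  p <- list(
    shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
    center = center %||% ((as.numeric(shape) + 1) / 2),
    r_endo = r_endo, r_epi = r_epi,
    ha_endo = ha_endo, ha_epi = ha_epi,
    eigenvalues = as.numeric(eigenvalues),
    b_low = b_low, b_high = b_high,
    n_directions = as.integer(n_directions),
    n_averages_high = as.integer(n_averages_high),
    motion_amplitude_px = motion_amplitude_px,
    motion_period_frames = motion_period_frames,
    motion_axis = match.arg(motion_axis),
    deformation_fraction = deformation_fraction,
    snr = snr, seed = as.integer(seed)
  )
  if (p$r_endo <= 0 || p$r_epi <= p$r_endo) {
    stop_cdti("infeasible geometry: need 0 < r_endo < r_epi", "cdtimoco_geometry_error")
  }
  margin <- p$r_epi + abs(p$motion_amplitude_px)
  if (p$center[1] - margin < 1 || p$center[1] + margin > p$shape[1] ||
      p$center[2] - margin < 1 || p$center[2] + margin > p$shape[2]) {
    stop_cdti("infeasible geometry: LV plus motion leaves the field of view",
              "cdtimoco_geometry_error")
  }
  if (p$snr <= 0) stop("snr must be positive")
  if (any(diff(p$eigenvalues) > 0) || any(p$eigenvalues < 0)) {
    stop("eigenvalues must be non-negative and descending")
  }
  structure(p, class = "phantom_params")
}

#' Electrostatically spread diffusion directions on the half-sphere
#'
#' Minimises an antipodally symmetric Coulomb energy by fixed-step projected
#' gradient descent from a seeded random start; deterministic given `seed`.
#'
#' @param n Number of directions.
#' @param seed RNG seed.
#' @param n_iter,step Optimiser settings (fixed; no early exit).
#' @return `n x 3` matrix of unit vectors with non-negative z.
#' @export
spread_directions <- function(n, seed = 1L, n_iter = 500L, step = 0.1) {
  x <- with_seed(seed, {
    z <- stats::runif(n)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    cbind(s * cos(phi), s * sin(phi), z)
  })
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d1 <- x[i, ] - x[j, ]
        d2 <- x[i, ] + x[j, ]
        f[i, ] <- f[i, ] + d1 / (sum(d1^2)^2 + 1e-9) + d2 / (sum(d2^2)^2 + 1e-9)
      }
    }
    # project onto the tangent plane; normalise the step by the largest force
    # and decay it so the iteration contracts instead of oscillating
    f <- f - x * rowSums(f * x)
    fmax <- max(sqrt(rowSums(f^2)))
    if (fmax < 1e-12) break
    x <- x + (step * 0.99^it / fmax) * f
    x <- x / sqrt(rowSums(x^2))
  }
  flip <- x[, 3] < 0
  x[flip, ] <- -x[flip, ]
  x
}

#' Per-frame diffusion scheme from series metadata
#'
#' Expands a direction table into one `(b, g)` row per frame of a series,
#' using the series' per-frame `b_value` and `direction_index`.
#'
#' @param series An [image_series()].
#' @param directions `n x 3` matrix of unit direction vectors; row `k`
#'   corresponds to `direction_index = k - 1`.
#' @return Scheme tibble as used by [fit_tensor()].
#' @export
series_scheme <- function(series, directions) {
  g <- directions[series$meta$direction_index + 1L, , drop = FALSE]
  tibble(
    b_value = series$meta$b_value,
    gx = g[, 1], gy = g[, 2], gz = g[, 3],
    zero_direction = FALSE
  )
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude of `(S + n1) + i n2` with `n1, n2 ~ N(0, sigma^2)`; Rayleigh in
#' the background where `S = 0`.
#'
#' @param img Numeric matrix of noiseless magnitudes.
#' @param sigma Gaussian channel noise SD.
#' @return Noisy matrix.
#' @export
add_rician_noise <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n1 <- matrix(stats::rnorm(length(img), 0, sigma), nrow(img))
  n2 <- matrix(stats::rnorm(length(img), 0, sigma), nrow(img))
  sqrt((img + n1)^2 + n2^2)
}

# Closed-form FA of a set of eigenvalues.
fa_of_eigenvalues <- function(l) {
  sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / sqrt(sum(l^2))
}

# Average ss x ss blocks of a (ss*nr) x (ss*nc) matrix down to nr x nc
# (partial-volume averaging from the supersampled rendering grid).
block_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  nr <- nrow(m) / ss
  nc <- ncol(m) / ss
  a <- array(m, dim = c(ss, nr, ss, nc))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# Render the 2*n_directions unique noise-free frames (one per shell and
# direction) on a supersampled grid, then block-average down. Compartments:
# LV myocardium (helical tensor), blood pool (fast isotropic), surrounding
# body (slow isotropic), air (zero signal).
render_clean_frames <- function(p, directions, supersample = 3L) {
  nr <- p$shape[1]
  nc <- p$shape[2]
  ss <- supersample
  rr <- (seq_len(nr * ss) - 0.5) / ss + 0.5
  cc <- (seq_len(nc * ss) - 0.5) / ss + 0.5
  R <- matrix(rr, nr * ss, nc * ss)
  C <- matrix(cc, nr * ss, nc * ss, byrow = TRUE)
  dr <- R - p$center[1]
  dc <- C - p$center[2]
  r <- sqrt(dr^2 + dc^2)
  myo <- r >= p$r_endo & r <= p$r_epi
  blood <- r < p$r_endo
  thorax <- (dr / (nr * 0.46))^2 + (dc / (nc * 0.47))^2 <= 1 & !myo & !blood
  # anterior to the heart lies lung (near-zero DWI signal); the inferior wall
  # rests on diaphragm/liver. This makes the anterior epicardial rise the
  # dominant edge along a head-foot line, as the tracking metric presumes.
  lung <- thorax & dr < 0 & r > p$r_epi
  body <- thorax & !lung

  s0 <- matrix(0, nr * ss, nc * ss)
  s0[body] <- 0.55
  s0[lung] <- 0.08
  s0[blood] <- 1.8
  s0[myo] <- 1.0

  # local frame and fiber direction inside the wall
  ru <- dr / pmax(r, 1e-9)   # rad, row component
  cu <- dc / pmax(r, 1e-9)   # rad, col component
  depth <- 100 * (r - p$r_endo) / (p$r_epi - p$r_endo)
  ha <- (p$ha_endo + (p$ha_epi - p$ha_endo) * depth / 100) * pi / 180
  # circ = long x rad = (-rad_c, rad_r, 0); long = (0, 0, 1)
  ch <- cos(ha)
  sh <- sin(ha)
  e1x <- ch * (-cu); e1y <- ch * ru; e1z <- sh
  # e2 = rad x e1 = cos(ha) * long - sin(ha) * circ
  e2x <- -sh * (-cu); e2y <- -sh * ru; e2z <- ch
  l <- p$eigenvalues
  adc_blood <- 3.0   # um^2/ms, free-water-like pool
  adc_body <- 1.0    # um^2/ms, slow isotropic surround
  adc_lung <- 0.6    # um^2/ms; signal is near-zero regardless

  out <- vector("list", 2L * p$n_directions)
  k <- 0L
  for (b in c(p$b_low, p$b_high)) {
    for (d in seq_len(p$n_directions)) {
      g <- directions[d, ]
      q <- matrix(0, nr * ss, nc * ss)          # g' D g in um^2/ms
      p1 <- g[1] * e1x + g[2] * e1y + g[3] * e1z
      p2 <- g[1] * e2x + g[2] * e2y + g[3] * e2z
      p3 <- g[1] * ru + g[2] * cu               # e3 = rad (z component 0)
      q[myo] <- (l[1] * p1^2 + l[2] * p2^2 + l[3] * p3^2)[myo]
      q[blood] <- adc_blood
      q[body] <- adc_body
      q[lung] <- adc_lung
      sig <- s0 * exp(-b * q * 1e-3)            # b s/mm^2, D um^2/ms
      k <- k + 1L
      out[[k]] <- block_mean(sig, ss)
    }
  }
  names(out) <- c(
    paste0("b_low_dir", seq_len(p$n_directions)),
    paste0("b_high_dir", seq_len(p$n_directions))
  )
  out
}

# Choose the tracking line for the phantom. The line runs head-foot through
# the LV centre column; candidate sub-pixel start offsets are scored on the
# 2 x n_directions unique noiseless frames and the offset whose tracked
# epicardium index is most stable (lowest population SD, ties toward zero
# offset) is kept. Calibration sees only clean, motion-free frames.
calibrate_track_line <- function(clean, p, target_spacing = c(1.4, 1.4)) {
  nr <- p$shape[1]
  nd <- p$n_directions
  uniq <- image_series(
    array(unlist(clean), dim = c(p$shape, 2L * nd)),
    p$spacing_mm,
    tibble(
      b_value = rep(c(p$b_low, p$b_high), each = nd),
      direction_index = rep(seq_len(nd) - 1L, 2),
      average_index = 0L,
      acquisition_order = seq_len(2L * nd) - 1L
    )
  )
  interp_u <- interpolate_series(uniq, target_spacing)
  fr <- p$spacing_mm[1] / target_spacing[1]
  edge_row <- p$center[1] - p$r_epi
  row0 <- max(2, round(p$center[1] - p$r_epi - 26))
  row1 <- min(nr - 1, round(p$center[1] + p$r_epi + 26))
  n_samples <- round((row1 - row0) * fr) + 1
  delta <- (row1 - row0) * fr / (n_samples - 1)
  # score an offset by how stable the tracked index is when the line is
  # perturbed by a small sub-pixel amount: a mid-bin placement keeps the same
  # index, a bin-boundary placement flips it
  track_at <- function(off) {
    st <- c(row0 + off, p$center[2])
    # line_profiles on the pre-interpolated series takes its identity path
    prof <- suppressWarnings(
      line_profiles(
        interp_u,
        c((st[1] - 1) * fr + 1, (st[2] - 1) * fr + 1),
        c((row1 + off - 1) * fr + 1, (st[2] - 1) * fr + 1),
        n_samples = n_samples, target_spacing_mm = target_spacing
      )
    )
    ctr <- round(((edge_row - st[1]) * fr) / delta) + 1
    suppressWarnings(track_epicardium(prof, ctr))
  }
  best <- NULL
  for (off in seq(0, 0.96, by = 0.12)) {
    idx0 <- track_at(off)
    pooled <- c(idx0 - 0, track_at(off - 0.2) - 0, track_at(off + 0.2) - 0)
    score <- pop_sd(pooled)
    if (is.null(best) || score < best$score - 1e-12) {
      best <- list(
        score = score, off = off, n_samples = n_samples,
        window_center = as.integer(round(stats::median(idx0)))
      )
    }
  }
  list(
    start = c(row0 + best$off, p$center[2]),
    end = c(row1 + best$off, p$center[2]),
    n_samples = best$n_samples, window_center = best$window_center
  )
}

# Circular endo/epi contours in pixel coordinates of the acquisition grid.
phantom_contours <- function(p, n_points = 96L) {
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  circle <- function(radius) {
    cbind(p$center[1] + radius * sin(th), p$center[2] + radius * cos(th))
  }
  contour_set(circle(p$r_endo), circle(p$r_epi))
}

#' Generate a synthetic free-breathing cardiac DWI series with ground truth
#'
#' Builds the protocol-shaped frame series (all low-b directions first, then
#' the high-b averages direction-major), applies per-frame respiratory motion
#' (sinusoidal translation along the chosen axis, optionally plus a smooth
#' non-rigid component scaled by the same trace; the first frame is at the
#' zero-displacement phase) and Rician noise. Every quantity the pipeline
#' estimates is emitted as ground truth alongside the images.
#'
#' @param params A [phantom_params()].
#' @return List with `series` (the noisy moving [image_series()]) and
#'   `truth`: contours, `geometry` (on the acquisition grid), `directions`,
#'   per-frame `scheme`, `motion_fields` (pull-back fields: warping the clean
#'   frames by them reproduces the pre-noise moving frames), `clean_series`
#'   (motion-free, noiseless), truth maps/values `md_true`, `fa_true`,
#'   `ha_true` (map on the acquisition grid), `hat_true`, noise `sigma`, and
#'   the tracking `line` used by the motion metric.
#' @export
make_phantom <- function(params = phantom_params()) {
  p <- params
  directions <- spread_directions(p$n_directions, seed = p$seed)
  clean <- render_clean_frames(p, directions)
  nd <- p$n_directions
  nav <- p$n_averages_high
  n_total <- nd + nd * nav

  meta <- tibble(
    b_value = c(rep(p$b_low, nd), rep(p$b_high, nd * nav)),
    direction_index = c(seq_len(nd) - 1L, rep(seq_len(nd) - 1L, each = nav)),
    average_index = c(rep(0L, nd), rep(seq_len(nav) - 1L, times = nd)),
    acquisition_order = seq_len(n_total) - 1L
  )
  clean_idx <- ifelse(meta$b_value == p$b_low,
                      meta$direction_index + 1L,
                      nd + meta$direction_index + 1L)

  nr <- p$shape[1]
  nc <- p$shape[2]
  clean_frames <- array(0, dim = c(nr, nc, n_total))
  for (i in seq_len(n_total)) clean_frames[, , i] <- clean[[clean_idx[i]]]
  clean_series <- image_series(clean_frames, p$spacing_mm, meta)

  # smooth static deformation pattern, unit peak norm, scaled per frame
  defo <- with_seed(p$seed + 1L, {
    u <- cpp_gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 10)
    v <- cpp_gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 10)
    peak <- max(sqrt(u^2 + v^2))
    list(dr = u / peak, dc = v / peak)
  })

  t0 <- seq_len(n_total) - 1
  shift <- p$motion_amplitude_px * sin(2 * pi * t0 / p$motion_period_frames)
  motion_fields <- vector("list", n_total)
  frames <- array(0, dim = c(nr, nc, n_total))
  lv_ref <- NULL
  for (i in seq_len(n_total)) {
    dr <- matrix(if (p$motion_axis == "row") shift[i] else 0, nr, nc)
    dc <- matrix(if (p$motion_axis == "col") shift[i] else 0, nr, nc)
    if (p$deformation_fraction > 0) {
      dr <- dr + p$deformation_fraction * shift[i] * defo$dr
      dc <- dc + p$deformation_fraction * shift[i] * defo$dc
    }
    motion_fields[[i]] <- disp_field(dr, dc)
    frames[, , i] <- cpp_warp_bilinear(clean_frames[, , i], dr, dc)
  }

  contours <- phantom_contours(p)
  geometry <- build_geometry(contours, p$shape, p$spacing_mm)
  sigma <- 0
  if (is.finite(p$snr)) {
    sigma <- mean(clean_frames[, , 1][geometry$mask]) / p$snr
    frames <- with_seed(p$seed + 2L, {
      for (i in seq_len(n_total)) frames[, , i] <- add_rician_noise(frames[, , i], sigma)
      frames
    })
  }
  series <- image_series(frames, p$spacing_mm, meta)

  ha_true <- matrix(NA_real_, nr, nc)
  ha_true[geometry$mask] <- p$ha_endo +
    (p$ha_epi - p$ha_endo) * geometry$depth[geometry$mask] / 100

  # head-foot tracking line through the LV centre column; the anterior
  # epicardial edge (centre row - r_epi) is the tracked feature. The
  # sub-pixel start offset is calibrated on the noiseless clean frames so
  # the detected edge index is stable across b-values and directions
  # (mid-bin placement) — the phantom analog of the operator placing the
  # line manually on the images.
  line <- calibrate_track_line(clean, p)

  truth <- list(
    params = p,
    contours = contours,
    geometry = geometry,
    directions = directions,
    scheme = series_scheme(series, directions),
    motion_fields = motion_fields,
    clean_series = clean_series,
    md_true = mean(p$eigenvalues),
    fa_true = fa_of_eigenvalues(p$eigenvalues),
    ha_true = ha_true,
    hat_true = (p$ha_epi - p$ha_endo) / 100,
    sigma = sigma,
    line = line
  )
  list(series = series, truth = truth)
}

#' Write a phantom to disk in the pipeline's on-disk formats
#'
#' @param phantom Output of [make_phantom()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series(phantom$series, file.path(dir, "series.nii"),
               file.path(dir, "series_meta.csv"))
  write_scheme(phantom$truth$scheme, file.path(dir, "series.bval"),
               file.path(dir, "series.bvec"))
  write_contours(phantom$truth$contours, file.path(dir, "contours.json"))
  g <- phantom$truth$geometry
  write_maps(
    list(
      ha_true = phantom$truth$ha_true,
      depth = g$depth,
      lv_mask = g$mask + 0
    ),
    file.path(dir, "truth"),
    pixel_spacing_mm = phantom$truth$params$spacing_mm
  )
  invisible(dir)
}
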