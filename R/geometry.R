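# Resample a closed contour polygon to a dense polyline (for distance
# queries). Linear interpolation along arc length.
densify_contour <- function(pts, n = 512) {
  pts <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  t_out <- seq(0, s[length(s)], length.out = n + 1)[-(n + 1)]
  cbind(
    stats::approx(s, pts[, 1], xout = t_out)$y,
    stats::approx(s, pts[, 2], xout = t_out)$y
  )
}

# Minimum distance from query points (n x 2) to a dense polyline (m x 2).
min_dist_to_curve <- function(q, curve) {
  # chunked to bound memory on large grids
  out <- numeric(nrow(q))
  chunk <- 4096L
  for (s in seq(1, nrow(q), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(q))
    d2 <- outer(q[s:e, 1], curve[, 1], "-")^2 + outer(q[s:e, 2], curve[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Build the left-ventricular coordinate system from contours
#'
#' Rasterises the endo/epi contours into an LV wall mask, computes a
#' transmural depth map (0% at the endocardium, 100% at the epicardium, by
#' two-distance normalisation of signed distances to the contours), and a
#' per-pixel right-handed orthonormal local frame: `rad` (in-plane outward,
#' along the depth gradient), `long` (slice normal) and `circ = long x rad`
#' (in-plane circumferential).
#'
#' @param contours A [contour_set()] in pixel coordinates of the target grid.
#' @param shape Length-2 integer grid size `(n_rows, n_cols)`.
#' @param spacing Length-2 pixel spacing in mm (used for distances; depth is
#'   unitless).
#' @return An `lv_geometry`: list with logical `mask`, `depth` (percent),
#'   arrays `circ`, `long`, `rad` (rows x cols x 3), the `centroid` of the
#'   mask and the input contours.
#' @export
build_geometry <- function(contours, shape, spacing = c(1, 1)) {
  nr <- shape[1]
  nc <- shape[2]
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  # physical coordinates for distances (anisotropic spacing supported)
  qr_mm <- g$row * spacing[1]
  qc_mm <- g$col * spacing[2]
  endo_d <- densify_contour(contours$endo)
  epi_d <- densify_contour(contours$epi)
  if (any(pracma::inpolygon(contours$endo[, 1], contours$endo[, 2],
                            epi_d[, 1], epi_d[, 2]) == FALSE)) {
    stop_cdti("contours cross: endocardium not inside epicardium", "cdtimoco_geometry_error")
  }
  in_endo <- pracma::inpolygon(g$row, g$col, endo_d[, 1], endo_d[, 2])
  in_epi <- pracma::inpolygon(g$row, g$col, epi_d[, 1], epi_d[, 2])
  mask <- matrix(in_epi & !in_endo, nr, nc)

  to_mm <- function(curve) cbind(curve[, 1] * spacing[1], curve[, 2] * spacing[2])
  d_endo <- min_dist_to_curve(cbind(qr_mm, qc_mm), to_mm(endo_d))
  d_epi <- min_dist_to_curve(cbind(qr_mm, qc_mm), to_mm(epi_d))
  # signed: positive outside endo / inside epi, so the ratio field is smooth
  # across the wall boundaries and its gradient is valid on every mask pixel
  a <- ifelse(in_endo, -d_endo, d_endo)
  b <- ifelse(in_epi, d_epi, -d_epi)
  depth_full <- matrix(100 * a / pmax(a + b, 1e-9), nr, nc)
  depth <- matrix(NA_real_, nr, nc)
  depth[mask] <- pmin(pmax(depth_full[mask], 0), 100)

  gd <- image_gradient(depth_full)
  # gradient in physical units so anisotropic spacing does not skew rad
  gr <- gd$dr / spacing[1]
  gc <- gd$dc / spacing[2]
  nrm <- sqrt(gr^2 + gc^2)
  nrm[nrm == 0] <- 1
  rad <- array(0, dim = c(nr, nc, 3))
  rad[, , 1] <- gr / nrm
  rad[, , 2] <- gc / nrm
  long <- array(0, dim = c(nr, nc, 3))
  long[, , 3] <- 1
  # circ = long x rad = (-rad_c, rad_r, 0)
  circ <- array(0, dim = c(nr, nc, 3))
  circ[, , 1] <- -rad[, , 2]
  circ[, , 2] <- rad[, , 1]

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  centroid <- c(mean(rows[mask]), mean(cols[mask]))
  structure(
    list(
      mask = mask, depth = depth, circ = circ, long = long, rad = rad,
      centroid = centroid, contours = contours, spacing = as.numeric(spacing)
    ),
    class = "lv_geometry"
  )
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf(
    "<lv_geometry> %d x %d px grid, %d wall pixel(s), centroid (%.1f, %.1f)\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask), x$centroid[1], x$centroid[2]
  ))
  invisible(x)
}

#' Helix angle map
#'
#' Signed angle, within the wall-tangent (circumferential-longitudinal)
#' plane, between the circumferential direction and the projection of the
#' primary eigenvector onto that plane. The eigenvector sign is first fixed
#' so its circumferential component is non-negative (removing the antipodal
#' ambiguity), giving HA in `(-90, 90]` degrees; positive when the
#' longitudinal component points along the slice normal. Pixels whose
#' tangent-plane projection norm falls below `min_projection` (mostly radial
#' fibers) are masked out.
#'
#' @param primary Array rows x cols x 3 of principal directions (e.g.
#'   `tensor_maps(tf)$e1`).
#' @param geom An `lv_geometry` on the same grid.
#' @param min_projection Minimum in-tangent-plane norm to accept a pixel.
#' @return Matrix of helix angles in degrees (NaN outside the usable mask).
#' @export
helix_angle <- function(primary, geom, min_projection = 0.2) {
  a <- primary[, , 1] * geom$circ[, , 1] + primary[, , 2] * geom$circ[, , 2] +
    primary[, , 3] * geom$circ[, , 3]
  b <- primary[, , 1] * geom$long[, , 1] + primary[, , 2] * geom$long[, , 2] +
    primary[, , 3] * geom$long[, , 3]
  flip <- !is.na(a) & a < 0
  a[flip] <- -a[flip]
  b[flip] <- -b[flip]
  ha <- atan2(b, pmax(a, 0)) * 180 / pi
  # a = 0, b < 0 gives exactly -90; fold onto +90 so HA lies in (-90, 90]
  ha[!is.na(ha) & ha == -90] <- 90
  proj <- sqrt(a^2 + b^2)
  ha[!geom$mask | !is.finite(proj) | proj < min_projection] <- NaN
  ha
}

#' Helix-angle transmurality
#'
#' The LV wall is divided into `n_sectors` equal angular sectors about the
#' mask centroid; within each sector the ordinary least-squares slope of
#' helix angle (degrees) against transmural depth (percent) is computed, and
#' the global HAT is the mean of the sector slopes. Sectors with fewer than
#' `min_pixels` valid pixels are excluded (slope `NA`) with a message.
#'
#' @param ha_map Helix-angle map from [helix_angle()].
#' @param geom The `lv_geometry` used to build it.
#' @param n_sectors Number of angular sectors (default 6).
#' @param min_pixels Minimum valid pixels per sector.
#' @return List with `global` (mean sector slope, degrees/percent) and
#'   `sectors`, a tibble of per-sector slopes and pixel counts.
#' @export
hat <- function(ha_map, geom, n_sectors = 6L, min_pixels = 10L) {
  nr <- nrow(ha_map)
  nc <- ncol(ha_map)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  theta <- atan2(rows - geom$centroid[1], cols - geom$centroid[2])
  sector <- pmin(floor((theta + pi) / (2 * pi) * n_sectors) + 1L, n_sectors)
  valid <- geom$mask & is.finite(ha_map) & is.finite(geom$depth)
  slopes <- rep(NA_real_, n_sectors)
  counts <- integer(n_sectors)
  for (s in seq_len(n_sectors)) {
    sel <- valid & sector == s
    counts[s] <- sum(sel)
    if (counts[s] < min_pixels) next
    x <- geom$depth[sel]
    y <- ha_map[sel]
    vx <- stats::var(x)
    if (!is.finite(vx) || vx == 0) next
    slopes[s] <- stats::cov(x, y) / vx
  }
  if (anyNA(slopes)) {
    message(sprintf(
      "HAT: sector(s) %s excluded (fewer than %d valid pixels or no depth spread)",
      paste(which(is.na(slopes)), collapse = ", "), min_pixels
    ))
  }
  list(
    global = mean(slopes, na.rm = TRUE),
    sectors = tibble(sector = seq_len(n_sectors), slope = slopes, n_pixels = counts)
  )
}

#' Per-slice and global ROI summaries
#'
#' Mean and population SD of each map inside the LV mask, per slice, plus a
#' `global` row per map holding the arithmetic mean of the per-slice means
#' (and of the per-slice SDs).
#'
#' @param slices List of slices; each slice is a list with elements `maps`
#'   (named list of matrices) and `geom` (an `lv_geometry`). Scalar entries
#'   in `maps` (e.g. a HAT value) are summarised as themselves with SD `NA`.
#' @return Tibble with columns `slice`, `map`, `mean`, `sd`.
#' @export
roi_summary <- function(slices) {
  rows <- list()
  for (si in seq_along(slices)) {
    sl <- slices[[si]]
    for (nm in names(sl$maps)) {
      m <- sl$maps[[nm]]
      if (length(m) == 1) {
        rows[[length(rows) + 1]] <- tibble(
          slice = si, map = nm, mean = as.numeric(m), sd = NA_real_
        )
      } else {
        vals <- m[sl$geom$mask & is.finite(m)]
        rows[[length(rows) + 1]] <- tibble(
          slice = si, map = nm, mean = mean(vals), sd = pop_sd(vals)
        )
      }
    }
  }
  per_slice <- do.call(rbind, rows)
  glob <- list()
  for (nm in unique(per_slice$map)) {
    sub <- per_slice[per_slice$map == nm, ]
    glob[[length(glob) + 1]] <- tibble(
      slice = NA_integer_, map = nm,
      mean = mean(sub$mean), sd = mean(sub$sd)
    )
  }
  out <- rbind(per_slice, do.call(rbind, glob))
  out$scope <- ifelse(is.na(out$slice), "global", "slice")
  out
}
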