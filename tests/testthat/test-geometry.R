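annulus_geom <- function(r_in = 10, r_out = 20, n = 48, center = NULL) {
  center <- center %||% c((n + 1) / 2, (n + 1) / 2)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  cs <- contour_set(
    cbind(center[1] + r_in * sin(th), center[2] + r_in * cos(th)),
    cbind(center[1] + r_out * sin(th), center[2] + r_out * cos(th))
  )
  build_geometry(cs, c(n, n), c(1, 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("transmural depth interpolates between the contours", {
  g <- annulus_geom()
  c0 <- c(24.5, 24.5)
  rows <- matrix(seq_len(48), 48, 48)
  cols <- matrix(seq_len(48), 48, 48, byrow = TRUE)
  r <- sqrt((rows - c0[1])^2 + (cols - c0[2])^2)
  mid <- g$mask & abs(r - 15) < 0.5
  expect_equal(mean(g$depth[mid]), 50, tolerance = 2 / 50)
  near_endo <- g$mask & abs(r - 10.2) < 0.3
  expect_lt(mean(g$depth[near_endo]), 3)
  expect_true(all(g$depth[g$mask] >= 0 & g$depth[g$mask] <= 100))
})

test_that("the local frame is orthonormal and circumferentially tangent", {
  g <- annulus_geom()
  idx <- which(g$mask)
  pick <- idx[seq(1, length(idx), by = 7)]
  for (p in pick) {
    i <- ((p - 1) %% 48) + 1
    j <- ((p - 1) %/% 48) + 1
    circ <- g$circ[i, j, ]
    long <- g$long[i, j, ]
    rad <- g$rad[i, j, ]
    expect_equal(sum(circ^2), 1, tolerance = 1e-10)
    expect_equal(sum(circ * long), 0, tolerance = 1e-10)
    expect_equal(sum(circ * rad), 0, tolerance = 1e-10)
    expect_equal(sum(long * rad), 0, tolerance = 1e-10)
    # right-handed: circ x long = rad
    cx <- c(circ[2] * long[3] - circ[3] * long[2],
            circ[3] * long[1] - circ[1] * long[3],
            circ[1] * long[2] - circ[2] * long[1])
    expect_equal(cx, rad, tolerance = 1e-8)
  }
  # tangent direction at angle theta on the annulus
  theta <- atan2(40 - 24.5, 24.5 - 24.5)  # due "south" in row terms
  i <- 40; j <- 24
  if (g$mask[i, j]) {
    tangent <- c(-cos(theta), -sin(theta))  # perpendicular to the radial
    circ_ij <- g$circ[i, j, 1:2]
    ang <- acos(min(1, abs(sum(tangent * circ_ij)))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("crossing contours are rejected", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  inner <- cbind(24 + 10 * sin(th), 24 + 10 * cos(th))
  outer <- cbind(30 + 10 * sin(th), 30 + 10 * cos(th))  # offset: endo pokes out
  expect_error(contour_set(inner, outer), class = "cdtimoco_format_error")
})

test_that("helix angle reproduces constructed fiber fields", {
  g <- annulus_geom()
  n <- 48
  e1 <- g$circ
  expect_equal(median(abs(helix_angle(e1, g)[g$mask])), 0, tolerance = 1e-8)

  e45 <- (g$circ + g$long) / sqrt(2)
  ha45 <- helix_angle(e45, g)
  expect_equal(median(ha45[g$mask]), 45, tolerance = 1e-8)

  # antipodal flips do not change the angle
  eflip <- -e45
  expect_equal(median(helix_angle(eflip, g)[g$mask]), 45, tolerance = 1e-8)

  # radial fibers are masked out (no tangent-plane projection)
  expect_true(all(is.na(helix_angle(g$rad, g)[g$mask])))
})

test_that("transmurality is the exact OLS slope for linear helix maps", {
  g <- annulus_geom()
  ha_lin <- matrix(NA_real_, 48, 48)
  ha_lin[g$mask] <- 60 - 1.2 * g$depth[g$mask]
  h <- hat(ha_lin, g)
  expect_equal(h$global, -1.2, tolerance = 1e-6)
  expect_true(all(abs(h$sectors$slope + 1.2) < 1e-6))

  const <- matrix(NA_real_, 48, 48)
  const[g$mask] <- 30
  expect_equal(hat(const, g)$global, 0, tolerance = 1e-9)

  # starving a sector drops it from the mean with a message
  ha_holey <- ha_lin
  rows <- matrix(seq_len(48), 48, 48)
  cols <- matrix(seq_len(48), 48, 48, byrow = TRUE)
  sector1 <- atan2(rows - g$centroid[1], cols - g$centroid[2]) < -2 * pi / 3
  ha_holey[sector1] <- NA
  expect_message(h2 <- hat(ha_holey, g), "excluded")
  expect_true(anyNA(h2$sectors$slope))
  expect_equal(h2$global, -1.2, tolerance = 1e-6)
})

test_that("helix maps are invariant to a consistent in-plane rotation", {
  # rotate the frames AND the in-plane gradient components by 30 degrees;
  # the recovered helix pattern must match the (rotationally symmetric) truth
  ph <- ph_small_clean()
  p <- ph$truth$params
  avg <- average_by_direction(ph$series)
  ang <- 30 * pi / 180
  nr <- p$shape[1]; nc <- p$shape[2]
  rows <- matrix(seq_len(nr), nr, nc); cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr0 <- rows - p$center[1]; dc0 <- cols - p$center[2]
  # pull-back rotation field: sample at R^-1 (p - c) + c
  fld <- list(
    dr = (cos(ang) * dr0 - sin(ang) * dc0) - dr0,
    dc = (sin(ang) * dr0 + cos(ang) * dc0) - dc0
  )
  rot <- avg
  for (i in seq_len(series_length(avg))) {
    rot$frames[, , i] <- warp(avg$frames[, , i], fld)
  }
  # content rotates by -ang under the pull-back field above, so the gradient
  # frame rotates the same way: g' = R(-ang) g
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  dirs_rot <- spread_directions(p$n_directions, seed = p$seed) %*% Rz

  run_ha <- function(series, dirs) {
    interp <- interpolate_series(series, c(1.4, 1.4))
    ct <- cdtimoco:::rescale_contours(ph$truth$contours, p$spacing_mm, c(1.4, 1.4))
    geom <- build_geometry(ct, dim(interp$frames)[1:2], c(1.4, 1.4))
    tf <- fit_tensor(interp, series_scheme(interp, dirs), geom$mask)
    list(ha = helix_angle(tensor_maps(tf)$e1, geom), geom = geom)
  }
  base <- run_ha(avg, spread_directions(p$n_directions, seed = p$seed))
  rotr <- run_ha(rot, dirs_rot)
  truth_ha <- matrix(NA_real_, nrow(base$geom$mask), ncol(base$geom$mask))
  truth_ha[base$geom$mask] <- p$ha_endo +
    (p$ha_epi - p$ha_endo) * base$geom$depth[base$geom$mask] / 100
  ok <- is.finite(rotr$ha) & is.finite(truth_ha) & base$geom$depth > 15 &
    base$geom$depth < 85
  expect_lt(median(abs(rotr$ha[ok] - truth_ha[ok])), 2)
})

test_that("ROI summaries follow the population-SD and slice-mean conventions", {
  g <- annulus_geom(8, 14, 32)
  const <- matrix(1.5, 32, 32)
  s <- roi_summary(list(list(maps = list(md = const), geom = g)))
  expect_equal(s$mean[s$scope == "slice"], 1.5)
  expect_equal(s$sd[s$scope == "slice"], 0)

  two <- roi_summary(list(
    list(maps = list(md = matrix(1, 32, 32)), geom = g),
    list(maps = list(md = matrix(2, 32, 32)), geom = g)
  ))
  expect_equal(two$mean[two$scope == "global"], 1.5)

  checker <- matrix(rep(c(1, 2), length.out = 32 * 32), 32, 32)
  s3 <- roi_summary(list(list(maps = list(m = checker), geom = g)))
  row3 <- s3[s3$scope == "slice", ]
  expect_equal(row3$mean, mean(checker[g$mask]), tolerance = 1e-12)
  expect_equal(row3$sd, 0.5, tolerance = 0.02)

  # scalar entries (a HAT value) are carried through
  s4 <- roi_summary(list(list(maps = list(hat = -1.2), geom = g)))
  expect_equal(s4$mean[s4$scope == "slice"], -1.2)
})
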