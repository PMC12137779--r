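test_that("the protocol phantom has the protocol shape", {
  ph <- ph_protocol_clean()
  expect_equal(series_length(ph$series), 108L)  # 12 low-b + 12 x 8 high-b
  expect_equal(dim(ph$series$frames)[1:2], c(128L, 48L))
  expect_equal(ph$series$pixel_spacing_mm, c(2.7, 2.7))
  m <- ph$series$meta
  expect_equal(sum(m$b_value == 50), 12L)
  expect_equal(sum(m$b_value == 500), 96L)
  expect_true(all(table(m$direction_index[m$b_value == 500]) == 8L))
  expect_equal(ph$truth$hat_true, -1.2)
  expect_equal(ph$truth$md_true, 1.4)
  expect_equal(ph$truth$fa_true, sqrt(3 / 2) * sqrt(0.56) / sqrt(6.44),
               tolerance = 1e-12)
})

test_that("noise and motion off reproduces the clean series exactly", {
  ph <- ph_small_clean()
  expect_identical(ph$series$frames, ph$truth$clean_series$frames)
})

test_that("the signal model attenuates along the fiber as prescribed", {
  ph <- ph_small_clean()
  p <- ph$truth$params
  mask <- ph$truth$geometry$mask
  # interior wall pixels only (away from partial-volume boundaries)
  interior <- mask & ph$truth$geometry$depth > 25 & ph$truth$geometry$depth < 75
  lowf <- ph$series$frames[, , 1:12]
  # first frame of each high-b direction (direction-major ordering)
  highf <- ph$series$frames[, , 13L + p$n_averages_high * (0:11)]
  implied_adc <- array(0, dim = c(sum(interior), 12))
  for (d in 1:12) {
    ratio <- highf[, , d][interior] / lowf[, , d][interior]
    implied_adc[, d] <- -log(ratio) / ((p$b_high - p$b_low) * 1e-3)
  }
  # g' D g must lie within the eigenvalue range
  expect_gt(min(implied_adc), min(p$eigenvalues) - 0.05)
  expect_lt(max(implied_adc), max(p$eigenvalues) + 0.05)
  # some direction approaches the fiber-aligned attenuation e^{-0.9} per
  # 450 s/mm^2 at lambda1 = 2.0
  expect_gt(max(implied_adc), 0.9 * max(p$eigenvalues))
})

test_that("background noise is Rayleigh with the prescribed sigma", {
  ph <- fixture("ph_noise", function() {
    make_phantom(small_phantom_params(snr = 15, motion_amplitude_px = 0, seed = 4))
  })
  sigma <- ph$truth$sigma
  expect_gt(sigma, 0)
  # air corners carry pure Rayleigh noise
  bg <- ph$series$frames[1:6, 1:6, ]
  expect_gt(length(bg), 1e3)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.05)

  # measured LV SNR within 10% of the requested value
  mask <- ph$truth$geometry$mask
  b50 <- ph$series$frames[, , 1:12]
  snr_meas <- mean(b50[rep(mask, 12)]) / sigma
  expect_equal(snr_meas, 15, tolerance = 0.10)
})

test_that("ground-truth motion fields regenerate the moving frames", {
  pp <- small_phantom_params(snr = Inf, motion_amplitude_px = 4,
                             deformation_fraction = 0.3, seed = 2)
  ph <- make_phantom(pp)
  for (i in c(2, 7, 20)) {
    regen <- warp(get_frame(ph$truth$clean_series, i), ph$truth$motion_fields[[i]])
    expect_lt(max(abs(regen - get_frame(ph$series, i))),
              1e-6 * max(ph$series$frames))
  }
  # first frame is at the zero-displacement phase
  expect_equal(max(abs(ph$truth$motion_fields[[1]]$dr)), 0)
})

test_that("diffusion directions are unit, spread and well-conditioned", {
  for (seed in c(1, 5)) {
    g <- spread_directions(12, seed = seed)
    expect_equal(rowSums(g^2), rep(1, 12), tolerance = 1e-9)
    expect_true(all(g[, 3] >= 0))
    # antipodally-aware minimum separation
    cosang <- abs(g %*% t(g))
    diag(cosang) <- 0
    expect_lt(max(cosang), cos(20 * pi / 180))
    X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
               2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
    expect_equal(qr(X)$rank, 6L)
  }
})

test_that("infeasible geometries are rejected", {
  expect_error(phantom_params(r_endo = 10, r_epi = 8), class = "cdtimoco_geometry_error")
  expect_error(phantom_params(shape = c(32L, 20L), r_epi = 14),
               class = "cdtimoco_geometry_error")
  expect_error(phantom_params(snr = 0), "snr")
  expect_error(phantom_params(eigenvalues = c(1, 2, 3)), "descending")
})

test_that("phantom generation and the recovery report are deterministic", {
  pp <- small_phantom_params(snr = 30, motion_amplitude_px = 2, seed = 6)
  a <- make_phantom(pp)
  b <- make_phantom(pp)
  expect_identical(a$series$frames, b$series$frames)
  expect_identical(a$truth$directions, b$truth$directions)

  r1 <- suppressWarnings(suppressMessages(end_to_end_recovery(pp, strategy = "none")))
  r2 <- suppressWarnings(suppressMessages(end_to_end_recovery(pp, strategy = "none")))
  expect_identical(r1, r2)
})

test_that("a phantom written to disk reloads into the same pipeline inputs", {
  ph <- ph_small_clean()
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  s <- read_series(file.path(dir, "series.nii"), file.path(dir, "series_meta.csv"))
  expect_equal(series_length(s), series_length(ph$series))
  sch <- read_scheme(file.path(dir, "series.bval"), file.path(dir, "series.bvec"))
  expect_equal(nrow(sch), series_length(ph$series))
  ct <- read_contours(file.path(dir, "contours.json"))
  expect_s3_class(ct, "contour_set")
  ha <- read_map(file.path(dir, "truth", "ha_true.nii"))
  expect_equal(dim(ha), dim(ph$truth$ha_true))
})
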