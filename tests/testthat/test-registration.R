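test_that("warp follows the pull-back convention with edge clamping", {
  img <- matrix(runif(30), 5, 6)
  z <- uniform_field(c(5, 6))
  expect_identical(warp(img, z), img)

  # +2-column field on an impulse: output(p) = img(p + 2 cols), so the
  # impulse appears 2 columns to the LEFT of its input position
  imp <- matrix(0, 5, 5)
  imp[3, 4] <- 1
  out <- warp(imp, uniform_field(c(5, 5), dc = 2))
  expect_equal(out[3, 2], 1)
  expect_equal(sum(out), 1)

  # nearest mode keeps a binary mask binary
  mask <- matrix(rbinom(56, 1, 0.5), 7, 8)
  wn <- warp(mask, uniform_field(c(7, 8), dr = 0.4, dc = -0.6), mode = "nearest")
  expect_true(all(wn %in% c(0, 1)))

  expect_error(warp(img, uniform_field(c(3, 3))), "shape")
})

test_that("field composition is associative with translations and zero-neutral", {
  g <- uniform_field(c(10, 12), dr = 1)
  z <- uniform_field(c(10, 12))
  expect_equal(compose_fields(z, g)$dr, g$dr)
  expect_equal(compose_fields(z, g)$dc, g$dc)
  h <- compose_fields(uniform_field(c(10, 12), dr = 1), uniform_field(c(10, 12), dr = 2))
  # interior pixels see exactly +3 rows
  expect_equal(h$dr[3:7, 3:9], matrix(3, 5, 7))
})

test_that("inverse consistency error is exact on uniform field pairs", {
  p0 <- list(forward = uniform_field(c(30, 30)), inverse = uniform_field(c(30, 30)))
  expect_equal(inverse_consistency_error(p0), 0)
  p1 <- list(forward = uniform_field(c(30, 30), dr = 3),
             inverse = uniform_field(c(30, 30), dr = -3))
  expect_equal(inverse_consistency_error(p1), 0)
  p2 <- list(forward = uniform_field(c(30, 30), dr = 3),
             inverse = uniform_field(c(30, 30), dr = -2))
  expect_equal(inverse_consistency_error(p2), 1.0)
})

test_that("registering an image to itself returns the identity", {
  f <- get_frame(ph_small_clean()$series, 1)
  pair <- register_pair(f, f)
  expect_lt(mean(sqrt(pair$forward$dr^2 + pair$forward$dc^2)), 0.05)
  expect_true(pair$gated)
  expect_equal(pair$ic_error, 0)
})

test_that("a known translation is recovered inside the LV with inverse consistency", {
  ph <- ph_small_clean()
  f <- get_frame(ph$series, 1)
  mask <- ph$truth$geometry$mask
  # content moved +3 rows: moving(p) = f(p - 3)
  moving <- warp(f, uniform_field(dim(f), dr = -3))
  pair <- register_pair(f, moving)
  expect_equal(mean(pair$forward$dr[mask]), 3, tolerance = 0.5 / 3)
  expect_lt(pair$ic_error, 0.1)
  # converged pair composition stays below the tolerance
  comp <- compose_fields(pair$forward, pair$inverse)
  expect_lt(mean(sqrt(comp$dr^2 + comp$dc^2)[mask]), 0.1)
})

test_that("registration treats the two images symmetrically", {
  ph <- ph_small_clean()
  f <- get_frame(ph$series, 1)
  mask <- ph$truth$geometry$mask
  moving <- warp(f, uniform_field(dim(f), dr = -3))
  ab <- register_pair(f, moving)
  ba <- register_pair(moving, f)
  d <- sqrt((ab$forward$dr - ba$inverse$dr)^2 + (ab$forward$dc - ba$inverse$dc)^2)
  expect_lt(mean(d[mask]), 0.25)
})

test_that("recovered deformations are fold-free over the LV", {
  ph <- ph_small_motion()
  f <- get_frame(ph$truth$clean_series, 1)
  i <- which.max(abs(vapply(ph$truth$motion_fields, function(m) m$dr[1, 1], 1)))
  pair <- register_pair(f, get_frame(ph$series, i))
  jd <- jacobian_determinant(pair$forward)
  mask <- ph$truth$geometry$mask
  expect_gte(mean(jd[mask] > 0), 0.995)
})

test_that("the engine is deterministic", {
  ph <- ph_small_motion()
  f <- get_frame(ph$truth$clean_series, 1)
  m <- get_frame(ph$series, 5)
  p1 <- register_pair(f, m)
  p2 <- register_pair(f, m)
  expect_identical(p1$forward, p2$forward)
  expect_identical(p1$inverse, p2$inverse)
})

test_that("cross-contrast frames of identical geometry do not acquire motion", {
  ph <- ph_small_clean()
  b50 <- get_frame(ph$series, 1)
  b500 <- get_frame(ph$series, 13)
  mask <- ph$truth$geometry$mask
  pair <- register_pair(b50, b500)
  expect_lt(mean(sqrt(pair$forward$dr^2 + pair$forward$dc^2)[mask]), 0.5)
})

test_that("field pairs round-trip through 2-channel NIfTI", {
  ph <- ph_small_clean()
  f <- get_frame(ph$series, 1)
  pair <- register_pair(f, warp(f, uniform_field(dim(f), dr = -2)))
  path <- withr::local_tempfile(fileext = ".nii")
  write_field_pair(pair, path)
  back <- read_field_pair(path)
  expect_lt(max(abs(back$forward$dr - pair$forward$dr)), 1e-6)
  expect_lt(max(abs(back$inverse$dc - pair$inverse$dc)), 1e-6)
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(registration_params(n_levels = 0), "n_levels")
  expect_error(registration_params(n_levels = 2, iters_per_level = c(10, 10, 10)),
               "iters_per_level")
  expect_error(registration_params(sigma_fluid = -1), "positive")
})
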