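# scheme with two shells spanning the tensor space (phantom directions)
two_shell_scheme <- function(n_dir = 12, seed = 1) {
  g <- spread_directions(n_dir, seed = seed)
  tibble::tibble(
    b_value = rep(c(50, 500), each = n_dir),
    gx = rep(g[, 1], 2), gy = rep(g[, 2], 2), gz = rep(g[, 3], 2),
    zero_direction = FALSE
  )
}

signal_for_tensor <- function(scheme, D, s0 = 1) {
  g <- as.matrix(scheme[, c("gx", "gy", "gz")])
  q <- rowSums((g %*% D) * g)          # um^2/ms
  s0 * exp(-scheme$b_value * q * 1e-3)
}

series_from_signals <- function(sig, nr = 5, nc = 5) {
  fr <- array(rep(sig, each = nr * nc), dim = c(nr, nc, length(sig)))
  image_series(fr, c(1, 1), data.frame(
    b_value = sig * 0 + rep(c(50, 500), each = length(sig) / 2),
    direction_index = rep(seq_len(length(sig) / 2) - 1L, 2),
    average_index = 0L, acquisition_order = seq_along(sig) - 1L
  ))
}

test_that("interpolation grid arithmetic and identity short-circuit", {
  ph <- ph_protocol_clean()
  avg <- average_by_direction(ph$series)
  interp <- interpolate_series(avg, c(1.4, 1.4))
  expect_equal(dim(interp$frames)[1:2],
               c(ceiling(128 * 2.7 / 1.4), ceiling(48 * 2.7 / 1.4)))
  expect_equal(dim(interp$frames)[2], 93)  # 48 cols at 2.7 mm -> 93 at 1.4 mm

  const <- image_series(matrix(2.5, 10, 8), c(2.7, 2.7), data.frame(
    b_value = 50, direction_index = 0L, average_index = 0L, acquisition_order = 0L
  ))
  ci <- interpolate_series(const, c(1.4, 1.4))
  expect_lt(diff(range(ci$frames)), 1e-9)

  expect_identical(interpolate_series(avg, c(2.7, 2.7)), avg)
})

test_that("noiseless signals invert to the exact tensor", {
  sch <- two_shell_scheme()
  D <- diag(c(1.5, 1.5, 1.5))
  s <- series_from_signals(signal_for_tensor(sch, D, s0 = 2), 3, 3)
  tf <- fit_tensor(s, sch)
  expect_lt(max(abs(tf$tensors[2, 2, ] - tensor6_from_matrix(D))), 1.5e-8)
  expect_equal(tf$s0[2, 2], 2, tolerance = 1e-8)

  # anisotropic, rotated
  R <- random_rotation(4)
  D2 <- R %*% diag(c(2.0, 1.2, 1.0)) %*% t(R)
  s2 <- series_from_signals(signal_for_tensor(sch, D2), 3, 3)
  tf2 <- fit_tensor(s2, sch)
  expect_lt(max(abs(tf2$tensors[1, 1, ] - tensor6_from_matrix(D2))), 1e-8)
})

test_that("degenerate designs and unusable pixels are rejected cleanly", {
  g1 <- c(1, 0, 0)
  sch_bad <- tibble::tibble(
    b_value = rep(c(50, 500), each = 6),
    gx = g1[1], gy = g1[2], gz = g1[3], zero_direction = FALSE
  )
  s <- series_from_signals(rep(0.5, 12), 3, 3)
  expect_error(fit_tensor(s, sch_bad), "rank-deficient")

  sch <- two_shell_scheme()
  sig <- signal_for_tensor(sch, diag(c(1.5, 1.5, 1.5)))
  s2 <- series_from_signals(sig, 3, 3)
  s2$frames[2, 2, ] <- 0  # dead pixel
  tf <- fit_tensor(s2, sch)
  expect_false(tf$mask[2, 2])
  expect_true(all(is.na(tf$tensors[2, 2, ])))
  expect_true(tf$mask[1, 1])
})

test_that("MD and FA match closed forms and are rotation invariant", {
  expect_equal(md(diag(c(1, 1, 1))), 1.0)
  expect_equal(md(diag(c(2, 1, 1))), 4 / 3)
  expect_equal(fa(diag(c(1, 1, 1))), 0)
  expect_equal(fa(diag(c(2, 1, 1))), sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(fa(diag(c(5, 0, 0))), 1)

  for (seed in 1:3) {
    R <- random_rotation(seed)
    D <- R %*% diag(c(2, 1, 1)) %*% t(R)
    expect_equal(md(D), 4 / 3, tolerance = 1e-10)
    expect_equal(fa(D), sqrt(1 / 6), tolerance = 1e-10)
  }
})

test_that("principal direction has a fixed sign and flags degeneracy", {
  v <- principal_direction(diag(c(2, 1, 1)))
  expect_equal(abs(v), c(1, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_gte(v[1], 0)
  expect_false(attr(v, "degenerate"))

  vd <- principal_direction(diag(c(1, 1, 1)))
  expect_true(attr(vd, "degenerate"))
  expect_true(all(is.nan(vd[1:3])))
})

simulate_voxel_fits <- function(snr, n_draws, seed, evals = c(2.0, 1.2, 1.0),
                                n_avg_high = 8L) {
  sch_dir <- spread_directions(12, seed = 1)
  R <- random_rotation(11)
  D <- R %*% diag(evals) %*% t(R)
  meta_b <- c(rep(50, 12), rep(500, 12 * n_avg_high))
  g_idx <- c(1:12, rep(1:12, each = n_avg_high))
  g <- sch_dir[g_idx, , drop = FALSE]
  q <- rowSums((g %*% D) * g)
  s_true <- exp(-meta_b * q * 1e-3)
  sigma <- 1 / snr
  sch_fit <- tibble::tibble(
    b_value = c(rep(50, 12), rep(500, 12)),
    gx = c(sch_dir[, 1], sch_dir[, 1]),
    gy = c(sch_dir[, 2], sch_dir[, 2]),
    gz = c(sch_dir[, 3], sch_dir[, 3]),
    zero_direction = FALSE
  )
  set.seed(seed)
  res <- t(vapply(seq_len(n_draws), function(i) {
    noisy <- sqrt((s_true + rnorm(length(s_true), 0, sigma))^2 +
                    rnorm(length(s_true), 0, sigma)^2)
    # average the high-b repeats per direction
    avg <- c(noisy[1:12], vapply(1:12, function(d) {
      mean(noisy[12 + (d - 1) * n_avg_high + seq_len(n_avg_high)])
    }, 1))
    s <- series_from_signals(avg, 1, 1)
    tf <- fit_tensor(s, sch_fit)
    e <- eigen(matrix(c(
      tf$tensors[1, 1, 1], tf$tensors[1, 1, 4], tf$tensors[1, 1, 5],
      tf$tensors[1, 1, 4], tf$tensors[1, 1, 2], tf$tensors[1, 1, 6],
      tf$tensors[1, 1, 5], tf$tensors[1, 1, 6], tf$tensors[1, 1, 3]
    ), 3, 3), symmetric = TRUE)
    ang <- acos(min(1, abs(sum(e$vectors[, 1] * (R %*% c(1, 0, 0)))))) * 180 / pi
    c(md = md(tf$tensors[1, 1, ]), fa = fa(tf$tensors[1, 1, ]), ang = ang)
  }, c(md = 1, fa = 1, ang = 1)))
  list(md = res[, "md"], fa = res[, "fa"], ang = res[, "ang"],
       md_true = mean(evals), fa_true = fa(diag(evals)))
}

test_that("noisy single-voxel recovery is unbiased within protocol tolerances", {
  r <- simulate_voxel_fits(snr = 25, n_draws = 200, seed = 7)
  expect_lt(abs(median(r$md) - r$md_true) / r$md_true, 0.05)
  expect_lt(abs(median(r$fa) - r$fa_true), 0.03)
  expect_lt(median(r$ang), 5)
})

test_that("FA noise bias grows as SNR falls (eigenvalue repulsion)", {
  lo <- simulate_voxel_fits(snr = 10, n_draws = 200, seed = 21)
  hi <- simulate_voxel_fits(snr = 40, n_draws = 200, seed = 22)
  bias_lo <- median(lo$fa) - lo$fa_true
  bias_hi <- median(hi$fa) - hi$fa_true
  expect_gt(bias_lo, bias_hi)
})

test_that("tensor maps and tidiers agree with per-pixel closed forms", {
  sch <- two_shell_scheme()
  D <- diag(c(2.0, 1.2, 1.0))
  s <- series_from_signals(signal_for_tensor(sch, D), 3, 3)
  tf <- fit_tensor(s, sch)
  maps <- tensor_maps(tf)
  expect_equal(maps$md[2, 2], mean(c(2, 1.2, 1)), tolerance = 1e-8)
  expect_equal(maps$fa[2, 2], fa(diag(c(2, 1.2, 1))), tolerance = 1e-8)
  expect_equal(abs(maps$e1[2, 2, ]), c(1, 0, 0), tolerance = 1e-6)

  td <- tidy(tf)
  expect_equal(nrow(td), 9L)
  expect_true(all(abs(td$md - 1.4) < 1e-8))
  gl <- glance(tf)
  expect_equal(gl$n_pixels, 9L)
  expect_equal(gl$fa_sd, 0, tolerance = 1e-8)
})
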