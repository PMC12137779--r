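make_const_series <- function(values, b = 500, dirs = 0L, navg = length(values)) {
  fr <- array(rep(values, each = 16), dim = c(4, 4, length(values)))
  image_series(fr, c(1, 1), data.frame(
    b_value = b, direction_index = rep(dirs, length.out = length(values)),
    average_index = seq_along(values) - 1L,
    acquisition_order = seq_along(values) - 1L
  ))
}

test_that("per-direction averaging is the arithmetic mean within groups", {
  s8 <- make_const_series(rep(3.5, 8))
  a <- average_by_direction(s8)
  expect_equal(series_length(a), 1L)
  expect_equal(unique(as.vector(a$frames)), 3.5)

  s18 <- make_const_series(1:8)
  a2 <- average_by_direction(s18)
  expect_equal(unique(as.vector(a2$frames)), 4.5)
  expect_equal(a2$meta$average_index, 0L)

  s1 <- make_const_series(7)
  expect_equal(as.vector(average_by_direction(s1)$frames),
               as.vector(s1$frames))
})

test_that("zero-motion series pass through both schedules unchanged", {
  ph <- ph_small_clean()
  rn <- suppressMessages(moco(ph$series, "naive"))
  expect_true(all(vapply(rn$fields, function(f)
    mean(abs(f$forward$dr)) + mean(abs(f$forward$dc)), 1) < 0.1))
  # averaged series equals plain per-direction means when nothing moved
  plain <- average_by_direction(ph$series)
  expect_lt(max(abs(rn$averaged_series$frames - plain$frames)), 1e-9)

  ra <- suppressMessages(moco(ph$series, "avg"))
  low <- ph$series$frames[, , ph$series$meta$b_value == 50]
  expect_lt(max(abs(ra$reference - apply(low, c(1, 2), mean))),
            1e-3 * max(low))
  expect_equal(series_length(ra$averaged_series),
               2L * length(unique(ph$series$meta$direction_index)))
})

test_that("protocol assumptions are enforced with informative errors", {
  ph <- ph_small_clean()
  meta <- ph$series$meta
  # rotate acquisition order so a high-b frame comes first
  hi_first <- meta
  first_high <- which(hi_first$b_value == 500)[1]
  hi_first$acquisition_order[1] <- hi_first$acquisition_order[first_high]
  hi_first$acquisition_order[first_high] <- 0L
  s_bad <- image_series(ph$series$frames, ph$series$pixel_spacing_mm, hi_first)
  expect_error(moco_naive(s_bad), class = "cdtimoco_protocol_error")
  expect_error(moco_avg(s_bad), class = "cdtimoco_protocol_error")

  # drop one low-b direction entirely
  keep <- !(meta$b_value == 50 & meta$direction_index == 3)
  m2 <- meta[keep, , drop = FALSE]
  m2$acquisition_order <- rank(meta$acquisition_order[keep]) - 1L
  s_missing <- image_series(ph$series$frames[, , keep], ph$series$pixel_spacing_mm, m2)
  err <- tryCatch(moco_avg(s_missing), error = function(e) conditionMessage(e))
  expect_match(err, "missing low-b direction")
  expect_match(err, "3")
})

test_that("correction preserves total LV signal on zero-motion data", {
  ph <- ph_small_clean()
  mask <- ph$truth$geometry$mask
  for (s in c("naive", "avg")) {
    res <- suppressMessages(moco(ph$series, s))
    before <- sum(ph$series$frames[rep(mask, series_length(ph$series))])
    after <- sum(res$corrected_series$frames[rep(mask, series_length(ph$series))])
    expect_lt(abs(after - before) / before, 0.02)
  }
})

test_that("running a schedule on its own output is a no-op", {
  ph <- ph_small_motion()
  r1 <- suppressMessages(moco(ph$series, "naive"))
  r2 <- suppressMessages(moco(r1$corrected_series, "naive"))
  mean_abs <- vapply(r2$fields, function(f)
    mean(sqrt(f$forward$dr^2 + f$forward$dc^2)), 1)
  expect_lt(mean(mean_abs), 0.1)
})

test_that("motion correction restores the averaged series toward truth", {
  ph <- ph_small_motion()
  un <- moco(ph$series, "none")
  ra <- suppressMessages(moco(ph$series, "avg"))
  expect_lt(lv_rmse_vs_truth(ra, ph$truth), lv_rmse_vs_truth(un, ph$truth))
  # diagnostics are tidy and complete
  d <- tidy(ra)
  expect_true(all(c("frame", "ic_error", "flagged") %in% names(d)))
  g <- glance(ra)
  expect_equal(g$strategy, "avg")
  expect_equal(g$n_averaged, 24L)
})

test_that("slice-wise processing yields one corrected frame per input frame", {
  phs <- lapply(1:2, function(s) {
    make_phantom(small_phantom_params(snr = 25, motion_amplitude_px = 2, seed = s))
  })
  res <- lapply(phs, function(p) suppressMessages(moco(p$series, "naive")))
  total <- sum(vapply(res, function(r) series_length(r$corrected_series), 1L))
  expect_equal(total, 2L * series_length(phs[[1]]$series))
})
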