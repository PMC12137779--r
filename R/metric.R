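#' Intensity profiles along a line, per frame
#'
#' Samples every frame of a series along one straight line (a manually placed
#' head-foot line across the heart). The series is first resampled to the
#' mapping grid (default 1.4 mm) exactly as done before tensor fitting, then
#' bilinearly sampled at `n_samples` equispaced points between the two
#' endpoints.
#'
#' @param series An [image_series()].
#' @param start,end Line endpoints `(row, col)` in pixel coordinates of the
#'   ORIGINAL grid (1-based); they are converted to the interpolated grid.
#' @param n_samples Samples along the line; default one per interpolated
#'   pixel of line length.
#' @param target_spacing_mm Interpolation grid spacing applied first.
#' @return Matrix `n_frames x n_samples` of class `line_profiles`, with the
#'   sampling geometry in attributes.
#' @export
line_profiles <- function(series, start, end, n_samples = NULL,
                          target_spacing_mm = c(1.4, 1.4)) {
  interp <- interpolate_series(series, target_spacing_mm)
  f <- series$pixel_spacing_mm / interp$pixel_spacing_mm
  p0 <- c((start[1] - 1) * f[1] + 1, (start[2] - 1) * f[2] + 1)
  p1 <- c((end[1] - 1) * f[1] + 1, (end[2] - 1) * f[2] + 1)
  len <- sqrt(sum((p1 - p0)^2))
  n_samples <- n_samples %||% (round(len) + 1)
  t_par <- seq(0, 1, length.out = n_samples)
  rr <- p0[1] + t_par * (p1[1] - p0[1])
  cc <- p0[2] + t_par * (p1[2] - p0[2])
  n <- n_frames(interp)
  out <- matrix(0, n, n_samples)
  for (i in seq_len(n)) {
    out[i, ] <- bilinear_sample(get_frame(interp, i), rr, cc)
  }
  structure(out,
    class = c("line_profiles", "matrix", "array"),
    start = p0, end = p1, spacing = interp$pixel_spacing_mm
  )
}

#' Track the epicardial edge along per-frame line profiles
#'
#' For each frame, computes the unfiltered forward first difference of the
#' profile (`d[i] = p[i+1] - p[i]`, reported at index `i`) and returns the
#' index of its largest value within a window around the expected epicardium
#' position. Ties are broken toward the window centre (then toward the lower
#' index). A frame whose windowed differences are all equal is assigned the
#' centre with a warning.
#'
#' @param profiles Matrix `n_frames x n_samples` (e.g. from
#'   [line_profiles()]).
#' @param window_center Expected epicardium sample index (1-based).
#' @param window_half_width Half-width of the search window; the default 5
#'   reproduces a 10-pixel range around the epicardium.
#' @param use_magnitude If `TRUE`, pick the largest `|d|` instead of the
#'   largest signed value.
#' @return Integer vector of per-frame edge indices.
#' @export
track_epicardium <- function(profiles, window_center, window_half_width = 5L,
                             use_magnitude = FALSE) {
  n_samp <- ncol(profiles)
  lo <- window_center - window_half_width
  hi <- window_center + window_half_width
  if (lo < 1 || hi > n_samp - 1) {
    stop("search window must lie within the profile (forward differences end at n_samples - 1)")
  }
  cand <- lo:hi
  idx <- integer(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    d <- diff(profiles[i, ])[cand]
    if (use_magnitude) d <- abs(d)
    if (diff(range(d)) == 0) {
      warning(sprintf("frame %d: flat profile in window; index set to window centre", i))
      idx[i] <- window_center
      next
    }
    best <- which(d == max(d))
    if (length(best) > 1) {
      dist <- abs(cand[best] - window_center)
      best <- best[order(dist, cand[best])][1]
    }
    idx[i] <- cand[best]
  }
  idx
}

#' Population SD of tracked positions
#'
#' Frame-to-frame standard deviation (population convention, divide by N) of
#' the epicardium indices — the residual-motion statistic. Zero means the
#' edge never moved.
#'
#' @param indices Integer vector from [track_epicardium()].
#' @return SD in interpolated pixels.
#' @export
position_sd <- function(indices) pop_sd(indices)

#' Track residual motion of the epicardium across a series
#'
#' Convenience wrapper: [line_profiles()] then [track_epicardium()] then
#' [position_sd()].
#'
#' @inheritParams line_profiles
#' @inheritParams track_epicardium
#' @return A `track_result`: list with per-frame `indices`, the `profiles`
#'   matrix, the line used and `sd` (pixels on the interpolated grid).
#' @export
track_line <- function(series, start, end, window_center,
                       window_half_width = 5L, n_samples = NULL,
                       target_spacing_mm = c(1.4, 1.4),
                       use_magnitude = FALSE) {
  profiles <- line_profiles(series, start, end, n_samples, target_spacing_mm)
  indices <- track_epicardium(profiles, window_center, window_half_width, use_magnitude)
  structure(
    list(
      indices = indices, profiles = profiles,
      start = start, end = end, window_center = window_center,
      window_half_width = window_half_width,
      sd = position_sd(indices)
    ),
    class = "track_result"
  )
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf(
    "<track_result> %d frame(s); epicardium index SD %.3f px (window %d +/- %d)\n",
    length(x$indices), x$sd, x$window_center, x$window_half_width
  ))
  invisible(x)
}

#' Paired comparison of residual-motion statistics
#'
#' Two-sided paired Student t-test with Bonferroni adjustment
#' (`p_adjusted = min(1, p_raw * n_comparisons)`). Identical paired samples
#' (all differences zero) are reported as `t = 0`, `p_raw = 1` by convention;
#' a constant non-zero difference (zero variance) is reported as `p_raw = 0`
#' with a warning.
#'
#' @param values_a,values_b Paired numeric vectors of equal length.
#' @param n_comparisons Number of simultaneous comparisons for the
#'   Bonferroni correction.
#' @return One-row tibble with `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
compare_groups <- function(values_a, values_b, n_comparisons = 1L) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  df <- length(d) - 1L
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      t_stat <- 0
      p_raw <- 1
    } else {
      warning("constant non-zero paired difference: zero variance, p set to 0")
      t_stat <- sign(mean(d)) * Inf
      p_raw <- 0
    }
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_raw <- tt$p.value
  }
  tibble(
    t = t_stat, df = df, p_raw = p_raw,
    p_adjusted = min(1, p_raw * n_comparisons)
  )
}
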