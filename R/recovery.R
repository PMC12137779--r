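#' End-to-end phantom recovery report
#'
#' Runs the full pipeline on a synthetic phantom — generation, motion
#' correction, interpolation, tensor fit, LV geometry, helix-angle and
#' transmurality maps, epicardium tracking — and measures every result
#' against the phantom's ground truth. Deterministic given the phantom seed.
#'
#' @param params A [phantom_params()].
#' @param strategy Motion-correction strategy: `"avg"`, `"naive"` or
#'   `"none"`.
#' @param reg_params A [registration_params()].
#' @param target_spacing_mm Mapping grid spacing (interpolation before the
#'   tensor fit).
#' @param n_sectors Sectors for the transmurality estimate.
#' @param return_details Also return the intermediate objects (phantom, moco
#'   result, tensor field, maps, geometry).
#' @return A list of scalar measurements: `md_bias_pct` (median MD error,
#'   percent of truth), `fa_bias` (median FA error), `ha_mae_deg` (median
#'   absolute helix-angle error), `hat_est` and `hat_true` (degrees/percent),
#'   `sd_uncorrected` / `sd_corrected` (epicardium-position SD, interpolated
#'   pixels), `epe_mean_px` (mean endpoint error of the estimated vs true
#'   per-frame displacement inside the LV, acquisition-grid pixels), plus
#'   bookkeeping (`strategy`, `seed`, `n_frames`).
#' @export
end_to_end_recovery <- function(params = phantom_params(),
                                strategy = c("avg", "naive", "none"),
                                reg_params = registration_params(),
                                target_spacing_mm = c(1.4, 1.4),
                                n_sectors = 6L,
                                return_details = FALSE) {
  strategy <- match.arg(strategy)
  ph <- make_phantom(params)
  truth <- ph$truth
  mres <- moco(ph$series, strategy, reg_params)

  interp <- interpolate_series(mres$averaged_series, target_spacing_mm)
  scheme <- series_scheme(interp, truth$directions)
  contours_i <- rescale_contours(truth$contours, params$spacing_mm, target_spacing_mm)
  geom <- build_geometry(contours_i, dim(interp$frames)[1:2], target_spacing_mm)
  tf <- fit_tensor(interp, scheme, geom$mask)
  maps <- tensor_maps(tf)
  ha_map <- helix_angle(maps$e1, geom)
  hat_res <- hat(ha_map, geom, n_sectors = n_sectors)

  ok <- geom$mask & is.finite(maps$md)
  md_bias_pct <- 100 * (median(maps$md[ok]) - truth$md_true) / truth$md_true
  fa_bias <- median(maps$fa[ok & is.finite(maps$fa)]) - truth$fa_true
  ha_true_i <- matrix(NA_real_, nrow(geom$mask), ncol(geom$mask))
  ha_true_i[geom$mask] <- params$ha_endo +
    (params$ha_epi - params$ha_endo) * geom$depth[geom$mask] / 100
  ha_ok <- is.finite(ha_map) & is.finite(ha_true_i)
  ha_mae_deg <- median(abs(ha_map[ha_ok] - ha_true_i[ha_ok]))

  line <- truth$line
  tr_un <- track_line(ph$series, line$start, line$end, line$window_center,
                      n_samples = line$n_samples)
  tr_co <- track_line(mres$corrected_series, line$start, line$end,
                      line$window_center, n_samples = line$n_samples)

  # endpoint error of estimated forward fields against the (negated) true
  # motion fields, inside the LV wall on the acquisition grid
  mask <- truth$geometry$mask
  epe <- NA_real_
  if (strategy != "none") {
    errs <- vapply(seq_along(mres$fields), function(i) {
      est <- mres$fields[[i]]$forward
      tru <- truth$motion_fields[[i]]
      mean(sqrt((est$dr + tru$dr)[mask]^2 + (est$dc + tru$dc)[mask]^2))
    }, numeric(1))
    epe <- mean(errs)
  }

  out <- list(
    strategy = strategy,
    seed = params$seed,
    n_frames = n_frames(ph$series),
    md_est = median(maps$md[ok]),
    md_true = truth$md_true,
    md_bias_pct = md_bias_pct,
    fa_est = median(maps$fa[ok & is.finite(maps$fa)]),
    fa_true = truth$fa_true,
    fa_bias = fa_bias,
    ha_mae_deg = ha_mae_deg,
    hat_est = hat_res$global,
    hat_true = truth$hat_true,
    hat_err = hat_res$global - truth$hat_true,
    sd_uncorrected = tr_un$sd,
    sd_corrected = tr_co$sd,
    epe_mean_px = epe
  )
  if (return_details) {
    out$details <- list(
      phantom = ph, moco = mres, tensor_field = tf, maps = maps,
      ha_map = ha_map, hat = hat_res, geom = geom,
      track_uncorrected = tr_un, track_corrected = tr_co
    )
  }
  out
}

#' RMSE of a corrected series against phantom truth
#'
#' Root-mean-square error between a strategy's per-direction averaged output
#' and the ground-truth motion-free averages, over the LV wall mask — the
#' robustness measure used to order strategies.
#'
#' @param mres A `moco_result`.
#' @param truth The `truth` element of [make_phantom()].
#' @return Scalar RMSE in image intensity units.
#' @export
lv_rmse_vs_truth <- function(mres, truth) {
  clean_avg <- average_by_direction(truth$clean_series)
  est <- mres$averaged_series
  stopifnot(n_frames(est) == n_frames(clean_avg))
  # align frames by (b, direction)
  key_e <- paste(est$meta$b_value, est$meta$direction_index)
  key_c <- paste(clean_avg$meta$b_value, clean_avg$meta$direction_index)
  ord <- match(key_e, key_c)
  mask <- truth$geometry$mask
  err2 <- 0
  n <- 0
  for (i in seq_len(n_frames(est))) {
    d <- get_frame(est, i) - get_frame(clean_avg, ord[i])
    err2 <- err2 + sum(d[mask]^2)
    n <- n + sum(mask)
  }
  sqrt(err2 / n)
}
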