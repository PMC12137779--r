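#' Average frames within each (b-value, direction) group
#'
#' Arithmetic mean over the repeated averages of every `(b_value,
#' direction_index)` pair present in the series. The output carries one frame
#' per group with `average_index = 0`, ordered by b-value shell then
#' direction.
#'
#' @param series An [image_series()].
#' @return An [image_series()] with one frame per group.
#' @export
average_by_direction <- function(series) {
  meta <- series$meta
  key <- paste(meta$b_value, meta$direction_index, sep = "_")
  groups <- unique(key[order(meta$b_value, meta$direction_index)])
  d <- dim(series$frames)
  out <- array(0, dim = c(d[1], d[2], length(groups)))
  b_out <- numeric(length(groups))
  dir_out <- integer(length(groups))
  for (gi in seq_along(groups)) {
    sel <- which(key == groups[gi])
    if (length(sel) == 1) {
      out[, , gi] <- series$frames[, , sel]
    } else {
      out[, , gi] <- apply(series$frames[, , sel, drop = FALSE], c(1, 2), mean)
    }
    b_out[gi] <- meta$b_value[sel[1]]
    dir_out[gi] <- meta$direction_index[sel[1]]
  }
  image_series(
    out, series$pixel_spacing_mm,
    tibble(
      b_value = b_out,
      direction_index = dir_out,
      average_index = 0L,
      acquisition_order = seq_along(groups) - 1L
    ),
    slice_index = series$slice_index
  )
}

new_moco_result <- function(corrected, averaged, reference, fields, strategy,
                            diagnostics, fields_stage3 = NULL) {
  structure(
    list(
      corrected_series = corrected,
      averaged_series = averaged,
      reference = reference,
      fields = fields,
      strategy = strategy,
      diagnostics = diagnostics,
      fields_stage3 = fields_stage3
    ),
    class = "moco_result"
  )
}

#' @export
print.moco_result <- function(x, ...) {
  cat(sprintf(
    "<moco_result> strategy '%s': %d corrected frame(s), %d averaged frame(s)\n",
    x$strategy, n_frames(x$corrected_series), n_frames(x$averaged_series)
  ))
  flagged <- sum(x$diagnostics$flagged)
  cat(sprintf(
    "  mean |field| %.3f px; %d frame(s) flagged for inverse-consistency\n",
    mean(x$diagnostics$mean_abs_displacement), flagged
  ))
  invisible(x)
}

frame_diagnostics <- function(i, pair, ic_tol) {
  tibble(
    frame = i,
    mean_abs_displacement = mean(sqrt(pair$forward$dr^2 + pair$forward$dc^2)),
    ic_error = pair$ic_error,
    similarity_after = pair$similarity_after %||% NA_real_,
    flagged = pair$ic_error > 10 * ic_tol
  )
}

# Register every frame of `series` to `reference`, pull each back onto the
# reference grid (one interpolation per frame), collect field pairs and
# per-frame quality diagnostics.
register_series_to <- function(series, reference, params) {
  n <- n_frames(series)
  fields <- vector("list", n)
  corrected <- series$frames
  diag_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- register_pair(reference, get_frame(series, i), params)
    corrected[, , i] <- warp(get_frame(series, i), pair$forward)
    fields[[i]] <- pair
    diag_rows[[i]] <- frame_diagnostics(i, pair, params$ic_tol)
  }
  flagged <- which(vapply(diag_rows, function(d) d$flagged, TRUE))
  if (length(flagged) > 0) {
    message(sprintf(
      "inverse-consistency above 10 x ic_tol for frame(s): %s (flagged, not discarded)",
      paste(flagged, collapse = ", ")
    ))
  }
  list(
    series = image_series(corrected, series$pixel_spacing_mm, series$meta,
                          slice_index = series$slice_index),
    fields = fields,
    diagnostics = do.call(rbind, diag_rows)
  )
}

#' Naive motion-correction schedule
#'
#' Registers every frame of the series to the first acquired low-b frame and
#' pulls each frame back onto that reference grid, then averages within each
#' (b-value, direction) group. The protocol assumption that the first
#' acquired frame is a low-b frame is enforced.
#'
#' @param series An [image_series()] whose first acquired frame carries the
#'   low b-value.
#' @param params A [registration_params()].
#' @return A `moco_result` with `corrected_series` (same frames/metadata
#'   shape as the input), `averaged_series` (one frame per shell and
#'   direction), the reference image, per-frame field pairs and a
#'   diagnostics tibble.
#' @export
moco_naive <- function(series, params = registration_params()) {
  lb <- low_b(series)
  first <- which(series$meta$acquisition_order == 0L)
  if (series$meta$b_value[first] != lb) {
    stop_cdti(
      paste0(
        "protocol assumption violated: the first acquired frame must be a low-b frame ",
        sprintf("(found b = %g, low b = %g)", series$meta$b_value[first], lb)
      ),
      "cdtimoco_protocol_error"
    )
  }
  reference <- get_frame(series, first)
  reg <- register_series_to(series, reference, params)
  new_moco_result(
    corrected = reg$series,
    averaged = average_by_direction(reg$series),
    reference = reference,
    fields = reg$fields,
    strategy = "naive",
    diagnostics = reg$diagnostics
  )
}

#' Averaged-reference motion-correction schedule
#'
#' Three-stage schedule: (1) all low-b frames are registered to the first
#' acquired low-b frame and averaged into a high-SNR reference; (2) every
#' high-b frame is registered to that reference and averaged within its
#' diffusion direction; (3) each per-direction high-b average is registered
#' to the reference once more. Stage-2 and stage-3 transforms are composed
#' and each original high-b frame is resampled once (single-warp
#' accumulation), so repeated interpolation does not blur the averages. The
#' averaged output holds the stage-1 corrected low-b frames (one per
#' direction, individually corrected, since each direction has a single
#' average) plus the per-direction means of the fully corrected high-b
#' frames.
#'
#' @inheritParams moco_naive
#' @return A `moco_result`; `fields` holds one field pair per input frame
#'   (stage 1 for low-b, composed stage 2+3 for high-b) and `fields_stage3`
#'   the per-direction re-registration pairs.
#' @export
moco_avg <- function(series, params = registration_params()) {
  lb <- low_b(series)
  hb <- high_b(series)
  if (lb == hb) stop_cdti("series must carry two b-value shells", "cdtimoco_protocol_error")
  meta <- series$meta
  low_idx <- which(meta$b_value == lb)
  high_idx <- which(meta$b_value == hb)
  dirs_all <- sort(unique(meta$direction_index))
  low_dirs <- meta$direction_index[low_idx]
  missing <- setdiff(dirs_all, low_dirs)
  dup <- unique(low_dirs[duplicated(low_dirs)])
  if (length(missing) > 0 || length(dup) > 0) {
    parts <- c(
      if (length(missing) > 0) paste0("missing low-b direction(s): ", paste(missing, collapse = ", ")),
      if (length(dup) > 0) paste0("duplicated low-b direction(s): ", paste(dup, collapse = ", "))
    )
    stop_cdti(paste0("one low-b frame per direction required; ", paste(parts, collapse = "; ")),
              "cdtimoco_protocol_error")
  }
  first <- which(meta$acquisition_order == 0L)
  if (meta$b_value[first] != lb) {
    stop_cdti("the first acquired frame must be a low-b frame", "cdtimoco_protocol_error")
  }

  subset_series <- function(sel) {
    m <- meta[sel, , drop = FALSE]
    m$acquisition_order <- rank(m$acquisition_order) - 1L
    image_series(series$frames[, , sel, drop = FALSE], series$pixel_spacing_mm,
                 m, slice_index = series$slice_index)
  }

  # stage 1: low-b frames to the first acquired low-b frame, average -> reference
  low_series <- subset_series(low_idx)
  reg1 <- register_series_to(low_series, get_frame(series, first), params)
  reference <- apply(reg1$series$frames, c(1, 2), mean)

  # stage 2: each high-b frame to the reference, then per-direction averaging
  high_series <- subset_series(high_idx)
  reg2 <- register_series_to(high_series, reference, params)
  high_avg <- average_by_direction(reg2$series)

  # stage 3: per-direction high-b averages back to the reference once more
  reg3 <- register_series_to(high_avg, reference, params)

  # single-warp accumulation: compose each high-b frame's stage-2 field with
  # its direction's stage-3 field and resample the original frame once, so
  # the averaged output is not blurred by repeated interpolation
  d <- dim(series$frames)
  n_dir <- length(dirs_all)
  high_meta <- high_series$meta
  high_fields <- vector("list", length(high_idx))
  high_corrected <- array(0, dim = c(d[1], d[2], length(high_idx)))
  for (k in seq_along(high_idx)) {
    dir_k <- high_meta$direction_index[k]
    j3 <- which(reg3$series$meta$direction_index == dir_k &
                  reg3$series$meta$b_value == hb)
    f2 <- reg2$fields[[k]]
    f3 <- reg3$fields[[j3]]
    total <- structure(
      list(
        forward = compose_fields(f2$forward, f3$forward),
        inverse = compose_fields(f3$inverse, f2$inverse),
        params = params,
        gated = isTRUE(f2$gated) && isTRUE(f3$gated)
      ),
      class = "displacement_field_pair"
    )
    total$ic_error <- inverse_consistency_error(total)
    total$similarity_after <- f3$similarity_after
    high_fields[[k]] <- total
    high_corrected[, , k] <- warp(get_frame(high_series, k), total$forward)
  }

  # averaged output: stage-1 corrected low-b frames (one per direction) +
  # per-direction means of the single-warped high-b frames
  out <- array(0, dim = c(d[1], d[2], 2L * n_dir))
  b_out <- numeric(2L * n_dir)
  dir_out <- integer(2L * n_dir)
  low_meta <- reg1$series$meta
  for (k in seq_along(dirs_all)) {
    j <- which(low_meta$direction_index == dirs_all[k])
    out[, , k] <- get_frame(reg1$series, j)
    b_out[k] <- lb
    dir_out[k] <- dirs_all[k]
    sel <- which(high_meta$direction_index == dirs_all[k])
    out[, , n_dir + k] <- apply(high_corrected[, , sel, drop = FALSE], c(1, 2), mean)
    b_out[n_dir + k] <- hb
    dir_out[n_dir + k] <- dirs_all[k]
  }
  averaged <- image_series(
    out, series$pixel_spacing_mm,
    tibble(
      b_value = b_out, direction_index = dir_out,
      average_index = 0L, acquisition_order = seq_along(b_out) - 1L
    ),
    slice_index = series$slice_index
  )

  # corrected series in original frame order
  corrected <- series$frames
  fields <- vector("list", n_frames(series))
  for (k in seq_along(low_idx)) {
    corrected[, , low_idx[k]] <- get_frame(reg1$series, k)
    fields[[low_idx[k]]] <- reg1$fields[[k]]
  }
  for (k in seq_along(high_idx)) {
    corrected[, , high_idx[k]] <- high_corrected[, , k]
    fields[[high_idx[k]]] <- high_fields[[k]]
  }
  diagnostics <- rbind(
    cbind(reg1$diagnostics, stage = 1L, frame_in_series = low_idx),
    cbind(reg2$diagnostics, stage = 2L, frame_in_series = high_idx),
    cbind(reg3$diagnostics, stage = 3L, frame_in_series = NA_integer_)
  )
  new_moco_result(
    corrected = image_series(corrected, series$pixel_spacing_mm, meta,
                             slice_index = series$slice_index),
    averaged = averaged,
    reference = reference,
    fields = fields,
    strategy = "avg",
    diagnostics = as_tibble(diagnostics),
    fields_stage3 = reg3$fields
  )
}

#' Motion-correct a diffusion-weighted series
#'
#' Dispatcher over the two registration schedules. `"none"` bypasses
#' registration (the free-breathing arm): frames are only averaged per
#' direction.
#'
#' @param series An [image_series()].
#' @param strategy `"avg"`, `"naive"` or `"none"`.
#' @param params A [registration_params()].
#' @return A `moco_result`.
#' @export
moco <- function(series, strategy = c("avg", "naive", "none"),
                 params = registration_params()) {
  strategy <- match.arg(strategy)
  if (strategy == "naive") return(moco_naive(series, params))
  if (strategy == "avg") return(moco_avg(series, params))
  n <- n_frames(series)
  zf <- zero_field(dim(series$frames)[1:2])
  pair <- structure(list(forward = zf, inverse = zf, ic_error = 0),
                    class = "displacement_field_pair")
  first <- which(series$meta$acquisition_order == 0L)
  new_moco_result(
    corrected = series,
    averaged = average_by_direction(series),
    reference = get_frame(series, first),
    fields = rep(list(pair), n),
    strategy = "none",
    diagnostics = tibble(
      frame = seq_len(n), mean_abs_displacement = 0, ic_error = 0,
      similarity_after = NA_real_, flagged = FALSE
    )
  )
}
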