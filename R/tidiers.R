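#' Tidy a tensor field into one row per fitted pixel
#'
#' @param x A `tensor_field`.
#' @param ... Unused.
#' @return Tibble with pixel coordinates, the six tensor elements, `md` and
#'   `fa`.
#' @export
tidy.tensor_field <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  maps <- tensor_maps(x)
  t6 <- vapply(seq_len(nrow(idx)), function(k) x$tensors[idx[k, 1], idx[k, 2], ],
               numeric(6))
  tibble(
    row = idx[, 1], col = idx[, 2],
    dxx = t6[1, ], dyy = t6[2, ], dzz = t6[3, ],
    dxy = t6[4, ], dxz = t6[5, ], dyz = t6[6, ],
    s0 = x$s0[idx],
    md = maps$md[idx], fa = maps$fa[idx]
  )
}

#' @rdname tidy.tensor_field
#' @export
glance.tensor_field <- function(x, ...) {
  maps <- tensor_maps(x)
  ok <- x$mask & is.finite(maps$md)
  tibble(
    n_pixels = sum(x$mask),
    md_mean = mean(maps$md[ok]),
    md_sd = pop_sd(maps$md[ok]),
    fa_mean = mean(maps$fa[ok & is.finite(maps$fa)]),
    fa_sd = pop_sd(maps$fa[ok & is.finite(maps$fa)])
  )
}

#' Tidy a track result into one row per frame
#' @param x A `track_result`.
#' @param ... Unused.
#' @return Tibble with `frame` and tracked `index`.
#' @export
tidy.track_result <- function(x, ...) {
  tibble(frame = seq_along(x$indices), index = x$indices)
}

#' @rdname tidy.track_result
#' @export
glance.track_result <- function(x, ...) {
  tibble(
    n_frames = length(x$indices),
    sd = x$sd,
    index_min = min(x$indices),
    index_max = max(x$indices)
  )
}

#' Tidy a motion-correction result (per-frame registration diagnostics)
#' @param x A `moco_result`.
#' @param ... Unused.
#' @return The diagnostics tibble (frame, mean displacement, IC error, flag).
#' @export
tidy.moco_result <- function(x, ...) as_tibble(x$diagnostics)

#' @rdname tidy.moco_result
#' @export
glance.moco_result <- function(x, ...) {
  tibble(
    strategy = x$strategy,
    n_frames = n_frames(x$corrected_series),
    n_averaged = n_frames(x$averaged_series),
    mean_abs_displacement = mean(x$diagnostics$mean_abs_displacement),
    max_ic_error = max(x$diagnostics$ic_error),
    n_flagged = sum(x$diagnostics$flagged)
  )
}
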