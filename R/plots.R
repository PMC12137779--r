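map_to_df <- function(m, value_name = "value") {
  idx <- which(is.finite(m) | TRUE, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2], value = as.vector(m))
  names(df)[3] <- value_name
  df
}

#' Plot per-frame line profiles with the tracked epicardium
#'
#' The line-versus-frame image used to visualise residual respiratory
#' motion: one column per frame, intensity along the tracking line on the
#' vertical axis, with the tracked epicardium indices overlaid.
#'
#' @param object A `track_result` from [track_line()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.track_result <- function(object, ...) {
  p <- object$profiles
  df <- data.frame(
    frame = rep(seq_len(nrow(p)), times = ncol(p)),
    sample = rep(seq_len(ncol(p)), each = nrow(p)),
    intensity = as.vector(p)
  )
  pts <- data.frame(frame = seq_along(object$indices), sample = object$indices)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$sample)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = pts, colour = "red", size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "frame", y = "position along line (interpolated px)",
      title = sprintf("Epicardium tracking, SD = %.2f px", object$sd)
    ) +
    ggplot2::theme_minimal()
}

#' Plot MD and FA maps of a tensor field
#'
#' @param object A `tensor_field`.
#' @param ... Unused.
#' @return A ggplot object (faceted MD / FA).
#' @export
autoplot.tensor_field <- function(object, ...) {
  maps <- tensor_maps(object)
  df <- rbind(
    cbind(map_to_df(maps$md), map = "MD (um^2/ms)"),
    cbind(map_to_df(maps$fa), map = "FA")
  )
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~map, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a helix-angle map
#'
#' @param ha_map Matrix from [helix_angle()].
#' @param geom Optional `lv_geometry` whose contours are overlaid.
#' @return A ggplot object.
#' @export
plot_helix_angle <- function(ha_map, geom = NULL) {
  df <- map_to_df(ha_map, "ha")
  df <- df[is.finite(df$ha), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$ha)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "yellow", high = "red",
                                  limits = c(-90, 90), name = "HA (deg)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(geom)) {
    ct <- rbind(
      data.frame(row = geom$contours$endo[, 1], col = geom$contours$endo[, 2], which = "endo"),
      data.frame(row = geom$contours$epi[, 1], col = geom$contours$epi[, 2], which = "epi")
    )
    p <- p + ggplot2::geom_path(
      data = ct, ggplot2::aes(x = .data$col, y = .data$row, group = .data$which),
      inherit.aes = FALSE, colour = "black", linewidth = 0.3
    )
  }
  p
}
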