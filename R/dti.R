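#' Resample a series to a finer grid before tensor fitting
#'
#' Separable cubic-spline (order 3) resampling of every frame onto a grid
#' with the requested pixel spacing. The output grid has
#' `ceiling(n * old_spacing / new_spacing)` samples per axis, anchored at the
#' first pixel centre. Requesting the source spacing returns the input
#' unchanged.
#'
#' @param series An [image_series()].
#' @param target_spacing_mm Length-2 target spacing; default 1.4 x 1.4 mm.
#' @return An [image_series()] on the finer grid.
#' @export
interpolate_series <- function(series, target_spacing_mm = c(1.4, 1.4)) {
  old <- series$pixel_spacing_mm
  if (isTRUE(all.equal(old, as.numeric(target_spacing_mm)))) return(series)
  d <- dim(series$frames)
  nr2 <- ceiling(d[1] * old[1] / target_spacing_mm[1])
  nc2 <- ceiling(d[2] * old[2] / target_spacing_mm[2])
  out <- array(0, dim = c(nr2, nc2, d[3]))
  for (i in seq_len(d[3])) {
    out[, , i] <- resample_cubic(series$frames[, , i], old, target_spacing_mm, nr2, nc2)
  }
  image_series(out, as.numeric(target_spacing_mm), series$meta, series$slice_index)
}

# Separable natural cubic-spline resampling of one frame. Output coordinate i
# (1-based) sits at physical position (i-1)*new_spacing, mapped into source
# index space and clamped to the source extent.
resample_cubic <- function(img, old_sp, new_sp, nr2, nc2) {
  nr <- nrow(img)
  nc <- ncol(img)
  rows_out <- pmin(pmax((seq_len(nr2) - 1) * new_sp[1] / old_sp[1] + 1, 1), nr)
  cols_out <- pmin(pmax((seq_len(nc2) - 1) * new_sp[2] / old_sp[2] + 1, 1), nc)
  tmp <- matrix(0, nr2, nc)
  for (j in seq_len(nc)) {
    tmp[, j] <- splinefun(seq_len(nr), img[, j], method = "natural")(rows_out)
  }
  out <- matrix(0, nr2, nc2)
  for (i in seq_len(nr2)) {
    out[i, ] <- splinefun(seq_len(nc), tmp[i, ], method = "natural")(cols_out)
  }
  out
}

# Design matrix of the log-linear tensor model:
# ln S = ln S0 - b g' D g, columns (lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_design <- function(scheme) {
  b <- scheme$b_value
  cbind(
    1,
    -b * scheme$gx^2,
    -b * scheme$gy^2,
    -b * scheme$gz^2,
    -2 * b * scheme$gx * scheme$gy,
    -2 * b * scheme$gx * scheme$gz,
    -2 * b * scheme$gy * scheme$gz
  )
}

#' Fit the diffusion tensor per pixel
#'
#' Weighted linear least squares on the log signal: an ordinary
#' least-squares pass initialises the tensor, then one reweighting pass with
#' weights equal to the squared predicted signals (the standard WLS scheme
#' for the log-linearised tensor model). Non-positive signals are excluded
#' per pixel below a floor of `1e-6` times the series maximum; pixels left
#' with fewer than 7 usable measurements are dropped from the output mask.
#'
#' @param averaged An [image_series()] (typically the per-direction averaged
#'   output of [moco()]), with b-values in s/mm^2 so tensors come out in
#'   units of mm^2/s x 1e-3 = um^2/ms.
#' @param scheme Tibble with one row per frame of `averaged` and columns
#'   `b_value`, `gx`, `gy`, `gz` (image-frame coordinates: x = row, y =
#'   column, z = slice normal).
#' @param mask Logical matrix of pixels to fit; `NULL` fits every pixel.
#' @return A `tensor_field`: list with `tensors` (array rows x cols x 6,
#'   elements Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in um^2/ms), `s0`, logical `mask`
#'   of pixels with a valid fit, and `pixel_spacing_mm`.
#' @export
fit_tensor <- function(averaged, scheme, mask = NULL) {
  scheme <- as_tibble(scheme)
  n <- n_frames(averaged)
  if (nrow(scheme) != n) {
    stop(sprintf("scheme has %d rows for %d frames", nrow(scheme), n))
  }
  if (n < 7) stop("tensor fit needs at least 7 measurements")
  X <- tensor_design(scheme)
  qx <- qr(X)
  if (qx$rank < 7) {
    g <- as.matrix(scheme[, c("gx", "gy", "gz")])
    dup <- which(duplicated(round(abs(g), 8)) & scheme$b_value == scheme$b_value[1])
    stop(sprintf(
      "rank-deficient diffusion design (rank %d < 7): directions do not span 6 independent tensor components%s",
      qx$rank,
      if (length(dup) > 0) paste0("; collinear direction rows: ", paste(dup, collapse = ", ")) else ""
    ))
  }
  d <- dim(averaged$frames)
  floor_val <- 1e-6 * max(averaged$frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  tensors <- array(NA_real_, dim = c(d[1], d[2], 6))
  s0 <- matrix(NA_real_, d[1], d[2])
  fitted_mask <- matrix(FALSE, d[1], d[2])
  # b in s/mm^2 and D reported in um^2/ms: 1 um^2/ms = 1e-3 mm^2/s, so the
  # design is scaled by 1e-3 to read coefficients directly in um^2/ms.
  Xs <- X * c(1, rep(1e-3, 6))[col(X)]
  sig <- matrix(averaged$frames, nrow = d[1] * d[2], ncol = n)
  idx <- which(mask)
  for (p in idx) {
    s <- sig[p, ]
    ok <- is.finite(s) & s > floor_val
    if (sum(ok) < 7) next
    y <- log(s[ok])
    Xp <- Xs[ok, , drop = FALSE]
    if (qr(Xp)$rank < 7) next
    beta <- qr.coef(qr(Xp), y)
    pred <- exp(Xp %*% beta)
    w <- as.vector(pred)^2
    fit <- stats::lm.wfit(Xp, y, w)
    beta <- fit$coefficients
    i <- ((p - 1) %% d[1]) + 1
    j <- ((p - 1) %/% d[1]) + 1
    tensors[i, j, ] <- beta[2:7]
    s0[i, j] <- exp(beta[1])
    fitted_mask[i, j] <- TRUE
  }
  structure(
    list(
      tensors = tensors, s0 = s0, mask = fitted_mask,
      pixel_spacing_mm = averaged$pixel_spacing_mm
    ),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf(
    "<tensor_field> %d x %d px, %d fitted pixel(s)\n",
    dim(x$tensors)[1], dim(x$tensors)[2], sum(x$mask)
  ))
  invisible(x)
}

as_tensor_matrix <- function(tensor) {
  if (is.matrix(tensor) && all(dim(tensor) == c(3, 3))) return(tensor)
  if (length(tensor) == 6) {
    return(matrix(
      c(tensor[1], tensor[4], tensor[5],
        tensor[4], tensor[2], tensor[6],
        tensor[5], tensor[6], tensor[3]),
      3, 3
    ))
  }
  stop("tensor must be a 3x3 matrix or a length-6 vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)")
}

tensor_eigen <- function(tensor) {
  e <- eigen(as_tensor_matrix(tensor), symmetric = TRUE)
  e$values <- pmax(e$values, 0)  # clip before any scalar map
  e
}

#' Mean diffusivity of a tensor
#'
#' Average of the (non-negativity clipped) eigenvalues, in the units of the
#' tensor (um^2/ms for fields fitted by [fit_tensor()]).
#'
#' @param tensor 3x3 symmetric matrix or length-6 vector
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @return Scalar MD.
#' @export
md <- function(tensor) {
  mean(tensor_eigen(tensor)$values)
}

#' Fractional anisotropy of a tensor
#'
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||` on the clipped
#' eigenvalues; 0 for isotropic tensors, 1 in the single-fiber limit. A zero
#' tensor yields `NaN`.
#'
#' @inheritParams md
#' @return Scalar FA in `[0, 1]`.
#' @export
fa <- function(tensor) {
  l <- tensor_eigen(tensor)$values
  den <- sqrt(sum(l^2))
  if (den == 0) return(NaN)
  sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / den
}

#' Principal diffusion direction of a tensor
#'
#' Eigenvector of the largest eigenvalue. The antipodal sign ambiguity is
#' resolved by `sign_reference`: the returned vector has a non-negative dot
#' product with it (default: first axis). Tensors whose two leading
#' eigenvalues are equal within `degenerate_tol` (relative) are flagged
#' degenerate and return `NaN`s.
#'
#' @inheritParams md
#' @param sign_reference Length-3 vector fixing the sign convention.
#' @param degenerate_tol Relative eigenvalue gap below which the direction is
#'   declared undefined.
#' @return Unit 3-vector, with attribute `degenerate`.
#' @export
principal_direction <- function(tensor, sign_reference = c(1, 0, 0),
                                degenerate_tol = 1e-6) {
  e <- tensor_eigen(tensor)
  scale <- max(e$values, 1e-300)
  if ((e$values[1] - e$values[2]) / scale < degenerate_tol) {
    v <- rep(NaN, 3)
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  v <- e$vectors[, 1]
  s <- sum(v * sign_reference)
  if (s < 0) v <- -v
  attr(v, "degenerate") <- FALSE
  v
}

#' Scalar and direction maps from a tensor field
#'
#' @param tf A `tensor_field` from [fit_tensor()].
#' @return List with matrices `md`, `fa` and array `e1` (rows x cols x 3) of
#'   principal directions (NaN where the fit is invalid or degenerate).
#' @export
tensor_maps <- function(tf) {
  d <- dim(tf$tensors)
  md_map <- matrix(NA_real_, d[1], d[2])
  fa_map <- matrix(NA_real_, d[1], d[2])
  e1 <- array(NA_real_, dim = c(d[1], d[2], 3))
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      if (!tf$mask[i, j]) next
      t6 <- tf$tensors[i, j, ]
      if (!all(is.finite(t6))) next
      e <- tensor_eigen(t6)
      md_map[i, j] <- mean(e$values)
      den <- sqrt(sum(e$values^2))
      fa_map[i, j] <- if (den == 0) NaN else sqrt(3 / 2) * sqrt(sum((e$values - mean(e$values))^2)) / den
      if ((e$values[1] - e$values[2]) / max(e$values[1], 1e-300) >= 1e-6) {
        e1[i, j, ] <- e$vectors[, 1]
      }
    }
  }
  list(md = md_map, fa = fa_map, e1 = e1)
}
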