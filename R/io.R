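#' Construct a diffusion-weighted image series
#'
#' An `image_series` is an ordered stack of 2D magnitude frames from one
#' short-axis slice, together with per-frame diffusion metadata. Frames are
#' stored as a numeric array of dimension `(n_rows, n_cols, n_frames)` and are
#' kept sorted by acquisition order.
#'
#' @param frames Numeric array `(n_rows, n_cols, n_frames)`, or a list of
#'   equally sized matrices.
#' @param pixel_spacing_mm Length-2 numeric, in-plane spacing `(row_mm, col_mm)`.
#' @param meta Data frame with one row per frame and columns `b_value`
#'   (s/mm^2), `direction_index`, `average_index` and `acquisition_order`
#'   (0-based labels, matching the on-disk sidecar convention).
#' @param slice_index Integer slice identifier.
#'
#' @details Invariants enforced: all frames share one shape and spacing;
#'   `acquisition_order` is a permutation of `0:(n_frames - 1)` (ties are
#'   illegal); at most two distinct b-values occur in one series.
#'
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, pixel_spacing_mm, meta, slice_index = 0L) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1) format_error("all frames must share one shape")
    frames <- array(unlist(frames), dim = c(shapes[[1]], length(frames)))
  }
  if (length(dim(frames)) == 2) frames <- array(frames, dim = c(dim(frames), 1))
  if (length(dim(frames)) != 3) format_error("frames must be a (rows, cols, frames) array")
  meta <- as_tibble(meta)
  required <- c("b_value", "direction_index", "average_index", "acquisition_order")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    meta_error(paste0("frame metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- dim(frames)[3]
  if (nrow(meta) != n) {
    meta_error(sprintf("metadata has %d rows for %d frames", nrow(meta), n))
  }
  ord <- meta$acquisition_order
  if (!setequal(ord, seq_len(n) - 1L) || anyDuplicated(ord)) {
    meta_error("acquisition_order must be a permutation of 0..n_frames-1 (no ties)")
  }
  if (length(unique(meta$b_value)) > 2) {
    meta_error("a series may carry at most two distinct b-values")
  }
  perm <- order(ord)
  frames <- frames[, , perm, drop = FALSE]
  meta <- meta[perm, , drop = FALSE]
  structure(
    list(
      frames = frames,
      pixel_spacing_mm = as.numeric(pixel_spacing_mm),
      meta = meta,
      slice_index = as.integer(slice_index)
    ),
    class = "image_series"
  )
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_series> %d frame(s) of %d x %d px @ %.2f x %.2f mm, slice %d\n",
    d[3], d[1], d[2], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$slice_index
  ))
  bs <- sort(unique(x$meta$b_value))
  cat("  b-values:", paste(bs, collapse = ", "), "s/mm^2;",
      length(unique(x$meta$direction_index)), "direction(s)\n")
  invisible(x)
}

n_frames <- function(series) dim(series$frames)[3]

#' Extract one frame of an image series
#' @param series An `image_series`.
#' @param i Frame position (in acquisition order, 1-based).
#' @return A 2D numeric matrix.
#' @export
get_frame <- function(series, i) series$frames[, , i]

#' Number of frames in an image series
#' @param series An `image_series`.
#' @return Integer frame count.
#' @export
series_length <- function(series) n_frames(series)

low_b <- function(series) min(series$meta$b_value)
high_b <- function(series) max(series$meta$b_value)

#' Read a diffusion-weighted image series
#'
#' Reads either a single NIfTI file whose third axis holds the frames, or a
#' directory of 2D NIfTI files (stacked in lexicographic filename order), plus
#' a sidecar CSV with per-frame diffusion metadata.
#'
#' @param path NIfTI file, or directory of per-frame 2D NIfTI files.
#' @param meta_path CSV with columns `b_value`, `direction_index`,
#'   `average_index`, `acquisition_order` (one row per frame, 0-based labels).
#' @param slice_index Slice identifier attached to the series.
#' @return An [image_series()], frames ordered by `acquisition_order`.
#' @export
read_series <- function(path, meta_path, slice_index = 0L) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (length(files) == 0) format_error(paste0("no NIfTI files in ", path))
    imgs <- lapply(files, RNifti::readNifti)
    shapes <- unique(lapply(imgs, function(im) dim(im)[1:2]))
    if (length(shapes) != 1) format_error("frame shapes differ across files")
    frames <- array(unlist(lapply(imgs, as.array)), dim = c(shapes[[1]], length(imgs)))
    spacing <- RNifti::pixdim(imgs[[1]])[1:2]
  } else {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 2) a <- array(a, dim = c(dim(a), 1))
    if (length(dim(a)) != 3) format_error("expected a 2D or 3D NIfTI image")
    frames <- a
    spacing <- RNifti::pixdim(img)[1:2]
  }
  meta <- utils::read.csv(meta_path)
  image_series(frames, spacing, meta, slice_index = slice_index)
}

#' Write an image series to NIfTI plus a metadata sidecar
#'
#' @param series An [image_series()].
#' @param path Output NIfTI filename (frames stacked on the third axis,
#'   float32).
#' @param meta_path Output CSV sidecar; defaults to `path` with a `.csv`
#'   extension.
#' @return Invisibly, the paths written.
#' @export
write_series <- function(series, path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.nii(\\.gz)?$", ".csv", path)
  a <- series$frames
  attr(a, "pixdim") <- c(series$pixel_spacing_mm, 1)
  img <- RNifti::asNifti(a, datatype = "float")
  RNifti::writeNifti(img, path, datatype = "float")
  utils::write.csv(series$meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read a diffusion scheme in FSL bval/bvec dialect
#'
#' `bval` holds one whitespace-separated row of b-values; `bvec` holds three
#' rows (x, y, z) of direction components, one column per measurement.
#' Directions are normalised to unit length; all-zero columns (pure b0
#' convention) are kept as `(0, 0, 0)` and flagged.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A tibble with columns `b_value`, `gx`, `gy`, `gz`, `zero_direction`.
#' @export
read_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bvec_lines <- readLines(bvec_path)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  if (length(bvec_lines) != 3) format_error("bvec file must have exactly three rows (x, y, z)")
  rows <- lapply(bvec_lines, function(l) scan(text = l, what = numeric(), quiet = TRUE))
  lens <- vapply(rows, length, 1L)
  if (length(unique(lens)) != 1 || lens[1] != length(bvals)) {
    format_error(sprintf(
      "bval/bvec column counts disagree: %d b-values, bvec rows of length %s",
      length(bvals), paste(lens, collapse = "/")
    ))
  }
  g <- cbind(rows[[1]], rows[[2]], rows[[3]])
  nrm <- sqrt(rowSums(g^2))
  zero <- nrm < 1e-12
  g[!zero, ] <- g[!zero, , drop = FALSE] / nrm[!zero]
  g[zero, ] <- 0
  tibble(
    b_value = bvals,
    gx = g[, 1], gy = g[, 2], gz = g[, 3],
    zero_direction = zero
  )
}

#' Write a diffusion scheme as FSL bval/bvec files
#'
#' @param scheme Tibble as returned by [read_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$b_value, trim = TRUE), collapse = " "), bval_path)
  writeLines(c(
    paste(format(scheme$gx, trim = TRUE, digits = 15), collapse = " "),
    paste(format(scheme$gy, trim = TRUE, digits = 15), collapse = " "),
    paste(format(scheme$gz, trim = TRUE, digits = 15), collapse = " ")
  ), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Construct an endo/epi contour set
#'
#' @param endo,epi Two-column matrices of ordered `(row, col)` points in pixel
#'   coordinates (1-based), at least 8 points each. The epicardial contour
#'   must enclose the endocardial one.
#' @param closed Whether the contours are closed polygons.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(endo, epi, closed = TRUE) {
  endo <- as.matrix(endo)
  epi <- as.matrix(epi)
  if (nrow(endo) < 8 || nrow(epi) < 8) format_error("contours need at least 8 points")
  if (ncol(endo) != 2 || ncol(epi) != 2) format_error("contours must be (row, col) two-column matrices")
  inside <- pracma::inpolygon(endo[, 1], endo[, 2], epi[, 1], epi[, 2])
  centroid_in <- pracma::inpolygon(mean(endo[, 1]), mean(endo[, 2]), epi[, 1], epi[, 2])
  if (!all(inside) || !centroid_in) format_error("epicardial contour must enclose the endocardial contour")
  structure(list(endo = endo, epi = epi, closed = isTRUE(closed)), class = "contour_set")
}

#' Read/write left-ventricular contours as JSON
#'
#' The JSON layout is `{"endo": [[r, c], ...], "epi": [[r, c], ...]}` with
#' 1-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return For `read_contours`, a [contour_set()].
#' @export
read_contours <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  contour_set(j$endo, j$epi, closed = j$closed %||% TRUE)
}

#' @rdname read_contours
#' @param contours A [contour_set()].
#' @export
write_contours <- function(contours, path) {
  jsonlite::write_json(
    list(endo = unname(contours$endo), epi = unname(contours$epi), closed = contours$closed),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Rescale contour pixel coordinates between grids
#'
#' Converts contour coordinates drawn on one pixel grid to the coordinates
#' of a grid with different spacing (e.g. from the 2.7 mm acquisition grid
#' to the 1.4 mm mapping grid), keeping the first pixel centre anchored.
#'
#' @param contours A [contour_set()].
#' @param from_spacing,to_spacing Length-2 pixel spacings in mm.
#' @return A [contour_set()] on the target grid.
#' @export
rescale_contours <- function(contours, from_spacing, to_spacing) {
  f <- function(m) {
    cbind(
      (m[, 1] - 1) * from_spacing[1] / to_spacing[1] + 1,
      (m[, 2] - 1) * from_spacing[2] / to_spacing[2] + 1
    )
  }
  contour_set(f(contours$endo), f(contours$epi), closed = contours$closed)
}

#' Write scalar maps as 2D NIfTI files
#'
#' Each map in a named list is written as `<name>.nii` under `path` as
#' float32 with the pixel spacing recorded in the header. All maps must share
#' one shape. A map with no finite values is written with a warning.
#'
#' @param maps Named list of 2D numeric matrices.
#' @param path Output directory (created if needed).
#' @param pixel_spacing_mm Length-2 spacing recorded in the headers.
#' @return Invisibly, the written file paths.
#' @export
write_maps <- function(maps, path, pixel_spacing_mm = c(1, 1)) {
  stopifnot(is.list(maps), length(maps) > 0, !is.null(names(maps)))
  shapes <- unique(lapply(maps, dim))
  if (length(shapes) != 1) format_error("all maps in one call must share one shape")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!any(is.finite(m))) {
      warning(sprintf("map '%s' has no finite values; written anyway", nm))
    }
    attr(m, "pixdim") <- as.numeric(pixel_spacing_mm)
    img <- RNifti::asNifti(m, datatype = "float")
    fp <- file.path(path, paste0(nm, ".nii"))
    RNifti::writeNifti(img, fp, datatype = "float")
    out <- c(out, fp)
  }
  invisible(out)
}

#' Read a scalar map written by [write_maps()]
#' @param path NIfTI file path.
#' @return A numeric matrix with attribute `pixel_spacing_mm`.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  m <- as.array(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  attr(m, "pixel_spacing_mm") <- RNifti::pixdim(img)[1:2]
  m
}
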