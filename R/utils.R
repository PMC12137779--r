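`%||%` <- function(x, y) if (is.null(x)) y else x

stop_cdti <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cdtimoco_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  ))
}

format_error <- function(msg) stop_cdti(msg, "cdtimoco_format_error")
meta_error <- function(msg) stop_cdti(msg, "cdtimoco_meta_error")

# Vectorised edge-clamped bilinear sampling of a matrix at fractional
# (row, col) positions, 1-based coordinates.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img)
  nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  if (nr == 1L) r0 <- rep(1, length(r))
  if (nc == 1L) c0 <- rep(1, length(c))
  r1 <- pmin(r0 + 1, nr)
  c1 <- pmin(c0 + 1, nc)
  fr <- r - r0
  fc <- c - c0
  (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
    (1 - fr) * fc * img[cbind(r0, c1)] +
    fr * (1 - fc) * img[cbind(r1, c0)] +
    fr * fc * img[cbind(r1, c1)]
}

# Central-difference gradients with one-sided differences at the border.
image_gradient <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  gr <- img
  gc <- img
  if (nr >= 3) {
    gr[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
    gr[1, ] <- img[2, ] - img[1, ]
    gr[nr, ] <- img[nr, ] - img[nr - 1, ]
  } else {
    gr[] <- 0
  }
  if (nc >= 3) {
    gc[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
    gc[, 1] <- img[, 2] - img[, 1]
    gc[, nc] <- img[, nc] - img[, nc - 1]
  } else {
    gc[] <- 0
  }
  list(dr = gr, dc = gc)
}

# Population (divide by N) standard deviation.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
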