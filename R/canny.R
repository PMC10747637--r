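# Canny edge detection: Gaussian smoothing, Sobel gradients, non-maximum
# suppression, and hysteresis thresholding with thresholds expressed as
# fractions of the maximum gradient magnitude.

#' @keywords internal
gaussian_kernel_1d <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' @keywords internal
sep_filter <- function(img, k) {
  h <- (length(k) - 1L) %/% 2L
  p <- pad_replicate(img, h)
  # rows then columns
  tmp <- matrix(0, nrow(p), ncol(img))
  for (i in seq_along(k))
    tmp <- tmp + k[i] * p[, i:(i + ncol(img) - 1L), drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k))
    out <- out + k[i] * tmp[i:(i + nrow(img) - 1L), , drop = FALSE]
  out
}

#' Canny edge detector
#'
#' Standard Canny chain: Gaussian smoothing at `sigma`, Sobel gradient,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis with low/high thresholds given as fractions of the maximum
#' gradient magnitude.  At a symmetric two-pixel magnitude tie across an
#' ideal step edge, the pixel on the negative gradient side is kept
#' (`>=` backward, `>` forward), so a vertical step yields a single
#' one-pixel-wide line.  The edge set is invariant under intensity
#' inversion, since only gradient magnitudes enter the chain.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param low_frac,high_frac Hysteresis thresholds as fractions of the
#'   maximum gradient magnitude; `low_frac < high_frac` required.
#' @return Integer 0/1 matrix of edge pixels, same dimensions as `image`.
#' @export
canny_edges <- function(image, sigma = 1.0, low_frac = 0.1, high_frac = 0.2) {
  stopifnot(is.matrix(image))
  if (low_frac >= high_frac || low_frac <= 0 || high_frac >= 1)
    stop("degenerate thresholds: need 0 < low_frac < high_frac < 1")
  sm <- sep_filter(image, gaussian_kernel_1d(sigma))
  sx <- c(1, 2, 1); dx <- c(-1, 0, 1)
  p <- pad_replicate(sm, 1L)
  nr <- nrow(sm); nc <- ncol(sm)
  conv3 <- function(kr, kc) {
    out <- matrix(0, nr, nc)
    for (a in 1:3) for (b in 1:3)
      out <- out + kr[a] * kc[b] *
        p[a:(a + nr - 1L), b:(b + nc - 1L), drop = FALSE]
    out
  }
  gx <- conv3(sx, dx)   # d/dcol
  gy <- conv3(dx, sx)   # d/drow (downwards positive)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0L, nr, nc))

  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  fwd <- matrix(0, nr, nc); bwd <- matrix(0, nr, nc)
  steps <- list(`0` = c(0L, 1L), `45` = c(1L, 1L),
                `90` = c(1L, 0L), `135` = c(-1L, 1L))
  for (s in names(steps)) {
    d <- steps[[s]]
    sel <- sector == as.integer(s)
    fwd[sel] <- shift_matrix(mag, d[1], d[2])[sel]
    bwd[sel] <- shift_matrix(mag, -d[1], -d[2])[sel]
  }
  # near-ties (symmetric two-pixel peaks) are resolved toward the forward
  # neighbor; the tolerance absorbs floating-point asymmetry so the edge set
  # is exactly invariant under intensity inversion
  tol <- 1e-9 * mmax
  nms <- (mag >= bwd - tol) & (mag > fwd + tol) & mag > 0

  strong <- nms & mag >= high_frac * mmax
  weak <- nms & mag >= low_frac * mmax
  # grow strong edges through connected weak pixels (8-connectivity)
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L)
        grown <- grown | shift_matrix(strong, dr, dc, fill = FALSE)
    grown <- grown & weak
    new_strong <- strong | grown
    if (identical(new_strong, strong)) break
    strong <- new_strong
  }
  out <- matrix(0L, nr, nc)
  out[strong] <- 1L
  out
}
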