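# Gray-level co-occurrence matrices along the 8 compass directions.

# Displacement (row, col) of one pixel step along a compass angle, with
# 0 degrees pointing right and angles increasing counter-clockwise (row 1 at
# the top, so "up" is decreasing row index).
#' @keywords internal
direction_step <- function(direction, offset = 1L) {
  if (!direction %in% GLCM_DIRECTIONS)
    stop("direction must be one of ", paste(GLCM_DIRECTIONS, collapse = ", "))
  th <- direction * pi / 180
  c(dr = as.integer(round(-sin(th))) * offset,
    dc = as.integer(round(cos(th))) * offset)
}

#' Gray-level co-occurrence matrix
#'
#' Counts how often a pixel with gray level `i` occurs at displacement
#' `offset` along `direction` from a pixel with gray level `j`, for all
#' in-bounds pixel pairs.  The matrix is unsymmetrized and normalized to sum
#' to 1; the raw pair counts are kept in the `"counts"` attribute.
#'
#' @param image Integer-valued matrix with gray levels in `0:(n_levels-1)`.
#' @param direction One of 0, 45, 90, 135, 180, 225, 270, 315 (degrees).
#' @param offset Displacement in pixels (default 1).
#' @param n_levels Number of gray levels (default 256).
#' @return An `n_levels x n_levels` probability matrix of class `glcm` with
#'   attributes `counts`, `direction`, `offset`.
#' @export
glcm <- function(image, direction, offset = 1L, n_levels = 256L) {
  stopifnot(is.matrix(image))
  v <- as.vector(image)
  if (any(v != round(v)) || min(v) < 0L || max(v) >= n_levels)
    stop("image must hold integer gray levels in 0:(n_levels-1)")
  d <- direction_step(direction, as.integer(offset))
  nr <- nrow(image); nc <- ncol(image)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rsrc <- rs[rs + d["dr"] >= 1L & rs + d["dr"] <= nr]
  csrc <- cs[cs + d["dc"] >= 1L & cs + d["dc"] <= nc]
  if (!length(rsrc) || !length(csrc))
    stop("offset displacement larger than the image")
  i <- image[rsrc, csrc, drop = FALSE]
  j <- image[rsrc + d["dr"], csrc + d["dc"], drop = FALSE]
  counts <- tabulate(as.integer(i) * n_levels + as.integer(j) + 1L,
                     nbins = n_levels * n_levels)
  counts <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  structure(counts / sum(counts),
            counts = counts, direction = direction, offset = offset,
            class = c("glcm", "matrix"))
}

# Min-max rescale of a probability matrix to 8-bit gray levels, used to
# render a GLCM as an intensity image before edge detection.
#' @keywords internal
rescale_255 <- function(m) {
  rng <- range(m)
  if (rng[2] == rng[1]) return(matrix(0L, nrow(m), ncol(m)))
  out <- round((m - rng[1]) / (rng[2] - rng[1]) * 255)
  storage.mode(out) <- "integer"
  out
}
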