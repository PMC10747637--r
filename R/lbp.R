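# Local binary patterns on a 3x3 neighborhood (P = 8, R = 1).

#' Local binary pattern image
#'
#' Computes the 8-neighbor LBP code of every pixel:
#' `code = sum_p s(g_p - g_c) 2^p` with `s(x) = 1` iff `x >= 0`, neighbors
#' enumerated clockwise starting at the top-left pixel (weight `2^0`).  The
#' image border is handled by replicating the nearest pixel values before
#' coding, so the output has the same dimensions as the input.  Codes depend
#' only on intensity differences, hence are invariant under adding a
#' constant and, more generally, under any strictly increasing remap.
#'
#' @param roi Numeric matrix, at least 3 x 3.
#' @return Integer matrix of codes in 0..255, same dimensions as `roi`.
#' @export
lbp_image <- function(roi) {
  stopifnot(is.matrix(roi))
  if (nrow(roi) < 3L || ncol(roi) < 3L)
    stop("LBP requires an image of at least 3 x 3 pixels")
  p <- pad_replicate(roi, 1L)
  nr <- nrow(roi); nc <- ncol(roi)
  ctr <- p[2:(nr + 1), 2:(nc + 1), drop = FALSE]
  # clockwise from top-left: TL, T, TR, R, BR, B, BL, L
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  code <- matrix(0L, nr, nc)
  for (b in seq_along(offs)) {
    o <- offs[[b]]
    nb <- p[(2:(nr + 1)) + o[1], (2:(nc + 1)) + o[2], drop = FALSE]
    code <- code + (nb >= ctr) * 2L^(b - 1L)
  }
  storage.mode(code) <- "integer"
  code
}
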