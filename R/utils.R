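# Shared internal helpers: padding, convolution, box filtering, seeding.
# Coordinate convention throughout the package: matrices are (row, column),
# row 1 at the top (shallow tissue), 1-based indexing.

GROUP_LEVELS <- c("A-MTrP", "L-MTrP", "healthy")
STAT_NAMES <- c("entropy", "contrast", "correlation", "homogeneity",
                "energy", "mean", "variance")
GLCM_DIRECTIONS <- c(0L, 45L, 90L, 135L, 180L, 225L, 270L, 315L)

#' @keywords internal
pad_replicate <- function(m, k) {
  if (k == 0L) return(m)
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

# Cross-correlation with 'same' output and replicate border handling,
# computed through zero-padded FFTs.  `kern` must have odd dimensions.
#' @keywords internal
xcorr2_same <- function(img, kern) {
  kh <- (nrow(kern) - 1L) %/% 2L
  kw <- (ncol(kern) - 1L) %/% 2L
  p <- pad_replicate(img, max(kh, kw))
  # trim padding to exactly (kh, kw) per axis
  p <- p[(max(kh, kw) - kh + 1L):(max(kh, kw) + nrow(img) + kh),
         (max(kh, kw) - kw + 1L):(max(kh, kw) + ncol(img) + kw), drop = FALSE]
  # correlation = convolution with the rotated kernel
  kr <- kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))), drop = FALSE]
  n1 <- stats::nextn(nrow(p) + nrow(kern) - 1L, c(2, 3, 5))
  n2 <- stats::nextn(ncol(p) + ncol(kern) - 1L, c(2, 3, 5))
  P <- matrix(0 + 0i, n1, n2); P[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  K <- matrix(0 + 0i, n1, n2); K[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kr
  full <- stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE) / (n1 * n2)
  full[(nrow(kern)):(nrow(kern) + nrow(img) - 1L),
       (ncol(kern)):(ncol(kern) + ncol(img) - 1L), drop = FALSE]
}

# w x w box (mean) filter with replicate borders via a summed-area table.
#' @keywords internal
box_mean <- function(m, w) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  if (w == 1L) return(m)
  h <- (w - 1L) %/% 2L
  p <- pad_replicate(m, h)
  sat <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  nr <- nrow(m); nc <- ncol(m)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  (sat[r1 + w, c1 + w, drop = FALSE] - sat[r1, c1 + w, drop = FALSE] -
     sat[r1 + w, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]) / (w * w)
}

# Deterministic seed fan-out; all derived seeds stay below 2^31 - 1.
#' @keywords internal
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ix) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

#' @keywords internal
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs[rs + dr >= 1 & rs + dr <= nr]
  cdst <- cs[cs + dc >= 1 & cs + dc <= nc]
  if (length(rdst) && length(cdst))
    out[rdst, cdst] <- m[rdst + dr, cdst + dc, drop = FALSE]
  out
}
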