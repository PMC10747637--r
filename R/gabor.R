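# Multi-scale, multi-orientation Gabor filter bank and energy responses.
#
# Each kernel is a Gaussian envelope modulated by a complex sinusoidal plane
# wave:
#   G(x, y) = exp(-(x'^2/sigma1^2 + y'^2/sigma2^2)/2) * exp(i(2 pi f x' + phi))
#   x' = x sin(theta) + y cos(theta),  y' = -x cos(theta) + y sin(theta)
# with x the column offset and y the row offset from the kernel center.
# Frequencies follow a geometric ladder f_s = f_max / sqrt(2)^s and the
# envelope scales with the wavelength (sigma1 = sigma2 = 0.56 / f).

#' Build a Gabor filter bank
#'
#' Constructs `n_scales * n_orientations` complex kernels (default 5 x 8 =
#' 40), ordered scale-major (all orientations of scale 0, then scale 1, ...).
#' Orientations cover the full circle (0, 45, ..., 315 degrees for the
#' default 8); filters at `theta` and `theta + 180` are complex conjugates
#' and therefore yield identical response magnitudes, but all printed
#' orientations are kept so the bank and feature layout have the declared
#' size.
#'
#' @param n_scales,n_orientations Bank dimensions (defaults 5 and 8).
#' @param f_max Highest spatial frequency in cycles/pixel (default 0.25).
#' @param sigma_factor Envelope width as a multiple of the wavelength;
#'   `sigma1 = sigma2 = sigma_factor / f` (default 0.56).
#' @param phase Phase `phi` in radians (default 0).
#' @return A list of class `gabor_bank`; each element is a complex kernel
#'   matrix with attributes `f`, `theta` (degrees), `sigma`, `scale`,
#'   `orientation_index`.
#' @export
gabor_bank <- function(n_scales = 5L, n_orientations = 8L,
                       f_max = 0.25, sigma_factor = 0.56, phase = 0) {
  stopifnot(n_scales >= 1L, n_orientations >= 1L, f_max > 0, sigma_factor > 0)
  thetas <- seq(0, 360, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  bank <- list()
  for (s in seq_len(n_scales) - 1L) {
    f <- f_max / sqrt(2)^s
    sigma <- sigma_factor / f
    h <- ceiling(3 * sigma)
    x <- matrix(rep(-h:h, each = 2L * h + 1L), 2L * h + 1L)   # column offset
    y <- matrix(rep(-h:h, times = 2L * h + 1L), 2L * h + 1L)  # row offset
    for (o in seq_len(n_orientations)) {
      th <- thetas[o] * pi / 180
      xp <- x * sin(th) + y * cos(th)
      yp <- -x * cos(th) + y * sin(th)
      env <- exp(-0.5 * (xp^2 + yp^2) / sigma^2)
      kern <- env * exp(1i * (2 * pi * f * xp + phase))
      attr(kern, "f") <- f
      attr(kern, "theta") <- thetas[o]
      attr(kern, "sigma") <- sigma
      attr(kern, "scale") <- s
      attr(kern, "orientation_index") <- o
      bank[[length(bank) + 1L]] <- kern
    }
  }
  names(bank) <- vapply(bank, function(k)
    sprintf("s%d_o%d", attr(k, "scale"), as.integer(attr(k, "theta"))), "")
  structure(bank, class = "gabor_bank")
}

#' Gabor energy responses
#'
#' Filters the ROI with every kernel of the bank (replicate border
#' handling), takes the magnitude of the complex response, and smooths it
#' with a `w x w` local mean window ("energy" around each pixel).  Responses
#' are returned in bank order and have the dimensions of `roi`.  The
#' operation is linear up to the magnitude, so scaling the image by `c`
#' scales every response by `c`.
#'
#' @param roi Numeric matrix, at least as large as the largest kernel.
#' @param bank A [gabor_bank()].
#' @param energy_window Odd window size `w` for mean-energy smoothing.
#' @return Named list of response matrices.
#' @export
gabor_responses <- function(roi, bank = gabor_bank(), energy_window = 5L) {
  stopifnot(is.matrix(roi))
  kmax <- max(vapply(bank, nrow, 0L))
  if (nrow(roi) < kmax || ncol(roi) < kmax)
    stop("ROI (", nrow(roi), " x ", ncol(roi),
         ") is smaller than the largest Gabor kernel (", kmax, " x ", kmax, ")")
  lapply(bank, function(kern) {
    resp <- Mod(xcorr2_same(roi, kern))
    box_mean(resp, as.integer(energy_window))
  })
}
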