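# The seven statistical texture features and the four feature approaches.
#
# The seven statistics (entropy, contrast, correlation, homogeneity, energy,
# mean, variance) are applied literally to the sum-normalized input matrix
# P, with 0-based index grids (i = row index, j = column index):
#   entropy     a1 = -sum_ij ln(P_ij) P_ij            (0 ln 0 = 0)
#   contrast    a2 =  sum_ij P_ij (i - j)^2
#   correlation a3 =  sum_ij P_ij (i - mu)(j - mu) / sigma^2
#   homogeneity a4 =  sum_ij P_ij / (1 + (i - j)^2)
#   energy      a5 =  sum_ij P_ij^2
#   mean        a6 =  sum_ij i P_ij
#   variance    a7 =  sum_ij P_ij (i - mu)^2
# where mu and sigma^2 are the mean and (population) variance of the entries
# of P.  The same formulas are applied whatever matrix enters (B-mode ROI,
# LBP code image, Gabor energy response, or a binary edge image), which is
# the one reading that covers all four approaches uniformly; a3 is defined
# as 0 when sigma^2 = 0.

#' Seven statistical features of a nonnegative matrix
#'
#' @param M Nonnegative matrix with a positive sum.
#' @return Named numeric vector `entropy`, `contrast`, `correlation`,
#'   `homogeneity`, `energy`, `mean`, `variance`.
#' @export
stats7 <- function(M) {
  stopifnot(is.matrix(M))
  if (any(!is.finite(M)) || any(M < 0)) stop("M must be finite and nonnegative")
  s <- sum(M)
  if (s == 0) stop("cannot normalize an all-zero matrix")
  P <- M / s
  I <- row(P) - 1
  J <- col(P) - 1
  mu <- mean(P)
  s2 <- mean((P - mu)^2)
  pos <- P > 0
  c(entropy = -sum(P[pos] * log(P[pos])),
    contrast = sum(P * (I - J)^2),
    correlation = if (s2 == 0) 0 else sum(P * (I - mu) * (J - mu)) / s2,
    homogeneity = sum(P / (1 + (I - J)^2)),
    energy = sum(P^2),
    mean = sum(I * P),
    variance = sum(P * (I - mu)^2))
}

#' B-mode statistical features (approach IV)
#'
#' [stats7()] applied directly to the ROI intensity matrix.
#'
#' @param roi Numeric matrix.
#' @return Named 7-vector with prefix `bmode_`.
#' @export
features_bmode <- function(roi) {
  v <- stats7(roi)
  names(v) <- paste0("bmode_", STAT_NAMES)
  v
}

#' LBP statistical features (approach I)
#'
#' [stats7()] applied to the LBP code image of the ROI.  Inherits the LBP
#' invariance to monotone intensity remaps.
#'
#' @param roi Numeric matrix, at least 3 x 3.
#' @return Named 7-vector with prefix `lbp_`.
#' @export
features_lbp <- function(roi) {
  v <- stats7(lbp_image(roi))
  names(v) <- paste0("lbp_", STAT_NAMES)
  v
}

#' Gabor statistical features (approach II)
#'
#' [stats7()] applied to each of the 40 Gabor energy responses, concatenated
#' in bank order (scale-major, then orientation): 280 features.
#'
#' @param roi Numeric matrix.
#' @param bank A [gabor_bank()].
#' @param energy_window Mean-energy window size.
#' @return Named 280-vector, names like `gabor_s2_o45_contrast`.
#' @export
features_gabor <- function(roi, bank = gabor_bank(), energy_window = 5L) {
  resp <- gabor_responses(roi, bank, energy_window)
  out <- unlist(lapply(names(resp), function(nm) {
    v <- stats7(resp[[nm]])
    names(v) <- paste0("gabor_", nm, "_", STAT_NAMES)
    v
  }))
  out
}

#' SEGL composite features (approach III)
#'
#' The composite statistical/edge/GLCM/LBP chain: the LBP code image is
#' computed from the ROI; for each of the 8 compass directions the GLCM of
#' the LBP image (offset 1, 256 levels) is rendered as an intensity matrix
#' (min-max rescaled to 0..255), Canny edges are detected on it, and the
#' seven statistics are computed on the binary edge matrix.  Concatenation
#' over the fixed direction order 0, 45, ..., 315 gives 8 x 7 = 56 features.
#' If a direction yields no edge pixels its statistics are those of the
#' uniform matrix, with a warning.
#'
#' The `variant = "lbp_edges"` alternative applies Canny to the LBP image
#' first and computes the per-direction GLCMs (2 levels) of the edge image,
#' then the statistics of each GLCM.
#'
#' @param roi Numeric matrix, at least 3 x 3.
#' @param sigma,low_frac,high_frac Canny parameters.
#' @param variant Chain ordering; `"glcm_edges"` (default) detects edges on
#'   the rendered GLCM, `"lbp_edges"` detects edges on the LBP image.
#' @return Named 56-vector, names like `segl_d135_entropy`.
#' @export
features_segl <- function(roi, sigma = 1.0, low_frac = 0.1, high_frac = 0.2,
                          variant = c("glcm_edges", "lbp_edges")) {
  variant <- match.arg(variant)
  L <- lbp_image(roi)
  out <- numeric(0)
  if (variant == "glcm_edges") {
    for (d in GLCM_DIRECTIONS) {
      G <- glcm(L, d, offset = 1L, n_levels = 256L)
      E <- canny_edges(rescale_255(unclass(G)), sigma, low_frac, high_frac)
      out <- c(out, edge_stats(E, d))
    }
  } else {
    E <- canny_edges(L, sigma, low_frac, high_frac)
    for (d in GLCM_DIRECTIONS) {
      G <- glcm(E, d, offset = 1L, n_levels = 2L)
      v <- stats7(unclass(G))
      names(v) <- paste0("segl_d", d, "_", STAT_NAMES)
      out <- c(out, v)
    }
  }
  out
}

# Statistics of one direction's binary edge matrix; an edge-free direction
# falls back to the uniform-matrix statistics with a warning.
#' @keywords internal
edge_stats <- function(E, d) {
  if (sum(E) == 0L) {
    warning("no edges for direction ", d, "; using uniform-matrix statistics")
    v <- stats7(matrix(1, nrow(E), ncol(E)))
  } else v <- stats7(E)
  names(v) <- paste0("segl_d", d, "_", STAT_NAMES)
  v
}

#' Feature table for a cohort
#'
#' One row per selected image (ROI-cropped through the site's mask), columns
#' `site_id`, `group`, and the named features of the chosen approach
#' (7 / 7 / 280 / 56 for bmode / lbp / gabor / segl).
#'
#' @param cohort Output of [generate_cohort()].
#' @param approach One of `"bmode"`, `"lbp"`, `"gabor"`, `"segl"`.
#' @param ... Passed to the approach's feature function.
#' @return A `data.frame` of class `feature_table`.
#' @export
feature_table <- function(cohort, approach = c("bmode", "lbp", "gabor", "segl"),
                          ...) {
  approach <- match.arg(approach)
  fun <- switch(approach, bmode = features_bmode, lbp = features_lbp,
                gabor = features_gabor, segl = features_segl)
  rows <- list()
  meta <- list()
  for (site in cohort) {
    if (!length(site$frames)) stop("cohort has unrendered sites")
    for (fr in site$frames) {
      roi <- extract_roi(fr, site$roi_mask)
      rows[[length(rows) + 1L]] <- fun(roi, ...)
      meta[[length(meta) + 1L]] <- c(site$site_id, site$group)
    }
  }
  feats <- do.call(rbind, rows)
  md <- do.call(rbind, meta)
  out <- data.frame(site_id = md[, 1],
                    group = factor(md[, 2], levels = GROUP_LEVELS),
                    feats, check.names = FALSE)
  if (anyNA(out)) stop("feature table contains missing values")
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @keywords internal
feature_columns <- function(table) {
  setdiff(colnames(table), c("site_id", "group"))
}
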