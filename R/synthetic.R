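# Synthetic B-mode cohort generator.
#
# Emulates the acquisition design the downstream analysis assumes: three
# balanced groups of muscle sites (active trigger point, latent trigger
# point, healthy), a 10 s sweep at 30 frames/s per site (300 frames), and a
# muscle region of interest between two bright fascia bands.  Trigger-point
# lesions are rendered as large hypoechoic elliptical contracture knots that
# may contain small hyperechoic speckle dots; the knot drifts laterally
# across the sweep so that frames sampled along the sweep view different
# sections of it.
#
# Image model: a smooth depth-attenuated background, multiplied by
# low-contrast oriented fiber striations and the lesion's echogenicity
# factor, plus additive fascia bands, all multiplied by fully developed
# speckle (i.i.d. Rayleigh with unit mean) and quantized to 8 bits.

#' Cohort configuration
#'
#' Builds the configuration object for [generate_cohort()].  Defaults encode
#' the acquisition design of the emulated study: 30 sites per group, a
#' 300-frame sweep per site of which 4 frames are selected, and 256 x 384
#' 8-bit frames.
#'
#' @param n_sites_per_group Number of sites per group (3 groups).
#' @param frames_per_site Number of frames in the simulated sweep.
#' @param frames_selected Number of frames kept for analysis per site.
#' @param image_height,image_width Frame dimensions in pixels.
#' @param seed Integer seed; together with the configuration it fully
#'   determines every pixel of the cohort.
#' @param echogenicity_drop_active,echogenicity_drop_latent Fractional
#'   multiplicative darkening of the hypoechoic knot for the active and
#'   latent groups; must lie in `[0, 1)`.  Setting both to 0 (and
#'   `speckle_count = 0`) yields a null cohort in which the three groups are
#'   exchangeable.
#' @param speckle_count Number of hyperechoic dots inside each knot.
#' @param speckle_gain Multiplicative brightening of the dots (>= 1).
#' @param background_level Mean echo level (8-bit scale) at the transducer.
#' @param depth_attenuation Fractional intensity loss from top to bottom.
#' @param fascia_amplitude Additive brightness of the fascia bands.
#' @param striation_amplitude Relative amplitude of fiber striations.
#' @param site_gain_sd Standard deviation (log scale) of the per-site
#'   overall gain jitter.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_sites_per_group = 30L,
                          frames_per_site = 300L,
                          frames_selected = 4L,
                          image_height = 256L,
                          image_width = 384L,
                          seed = 1L,
                          echogenicity_drop_active = 0.5,
                          echogenicity_drop_latent = 0.25,
                          speckle_count = 6L,
                          speckle_gain = 1.8,
                          background_level = 100,
                          depth_attenuation = 0.35,
                          fascia_amplitude = 80,
                          striation_amplitude = 0.06,
                          site_gain_sd = 0.015) {
  cfg <- list(n_sites_per_group = as.integer(n_sites_per_group),
              frames_per_site = as.integer(frames_per_site),
              frames_selected = as.integer(frames_selected),
              image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              seed = as.integer(seed),
              echogenicity_drop_active = echogenicity_drop_active,
              echogenicity_drop_latent = echogenicity_drop_latent,
              speckle_count = as.integer(speckle_count),
              speckle_gain = speckle_gain,
              background_level = background_level,
              depth_attenuation = depth_attenuation,
              fascia_amplitude = fascia_amplitude,
              striation_amplitude = striation_amplitude,
              site_gain_sd = site_gain_sd)
  with(cfg, {
    if (n_sites_per_group < 1L || frames_per_site < 1L || frames_selected < 1L)
      stop("all counts must be >= 1")
    if (frames_selected > frames_per_site)
      stop("frames_selected must not exceed frames_per_site")
    if (echogenicity_drop_active < 0 || echogenicity_drop_active >= 1 ||
        echogenicity_drop_latent < 0 || echogenicity_drop_latent >= 1)
      stop("echogenicity drops must lie in [0, 1)")
    if (speckle_count < 0L || speckle_gain < 1)
      stop("speckle_count must be >= 0 and speckle_gain >= 1")
  })
  geom <- cohort_geometry(cfg)
  if (geom$roi_height < 32L)
    stop("configuration error: muscle ROI is shorter than 32 pixels; ",
         "increase image_height")
  if (2L * geom$lesion_semi_r + 3L > geom$roi_height)
    stop("configuration error: lesion does not fit inside the ROI")
  structure(cfg, class = "cohort_config")
}

# Fixed geometry derived from a configuration: fascia band centers, the ROI
# row range between them, and default lesion semi-axes.
#' @keywords internal
cohort_geometry <- function(cfg) {
  h <- cfg$image_height; w <- cfg$image_width
  thick <- max(2L, round(h / 42))
  top_c <- round(0.15 * h); bot_c <- round(0.85 * h)
  roi_top <- top_c + thick + 2L
  roi_bot <- bot_c - thick - 2L
  roi_h <- roi_bot - roi_top + 1L
  list(fascia_top = top_c, fascia_bottom = bot_c, fascia_thick = thick,
       roi_top = roi_top, roi_bottom = roi_bot, roi_height = roi_h,
       lesion_semi_r = max(2L, round(0.30 * roi_h)),
       lesion_semi_c = max(2L, round(0.16 * w)))
}

# Unit-mean Rayleigh multiplicative speckle field.
#' @keywords internal
speckle_field <- function(nr, nc) {
  sigma <- 1 / sqrt(pi / 2)
  matrix(sigma * sqrt(-2 * log(stats::runif(nr * nc))), nr, nc)
}

# Draws the per-site latent parameters (gain jitter, fascia jitter, fiber
# striation phase/orientation, lesion placement) from the site's own seed.
#' @keywords internal
make_site <- function(cfg, group, index) {
  geom <- cohort_geometry(cfg)
  site_seed <- derive_seed(cfg$seed, index)
  set.seed(site_seed)
  h <- cfg$image_height; w <- cfg$image_width
  jit <- max(1, h / 64)
  params <- list(
    gain = exp(stats::rnorm(1, 0, cfg$site_gain_sd)),
    fascia_top = geom$fascia_top + stats::runif(1, -jit, jit),
    fascia_bottom = geom$fascia_bottom + stats::runif(1, -jit, jit),
    fascia_thick = geom$fascia_thick,
    striation_angle = stats::runif(1, -0.15, 0.15),
    striation_period = stats::runif(1, 10, 14),
    striation_phase = stats::runif(1, 0, 2 * pi))
  lesion <- NULL
  if (group != "healthy") {
    drop <- if (group == "A-MTrP") cfg$echogenicity_drop_active
            else cfg$echogenicity_drop_latent
    sr <- geom$lesion_semi_r; sc <- geom$lesion_semi_c
    center_row <- round(stats::runif(1, geom$roi_top + sr + 1,
                                     geom$roi_bottom - sr - 1))
    center_col <- stats::runif(1, 1, w)
    dots <- NULL
    if (cfg$speckle_count > 0L) {
      # uniform points inside the ellipse (polar sampling)
      u <- sqrt(stats::runif(cfg$speckle_count))
      a <- stats::runif(cfg$speckle_count, 0, 2 * pi)
      dots <- cbind(dr = 0.8 * u * sr * sin(a), dc = 0.8 * u * sc * cos(a))
    }
    lesion <- list(center_row = center_row, center_col = center_col,
                   semi_r = sr, semi_c = sc,
                   echogenicity_drop = drop,
                   speckle_count = cfg$speckle_count,
                   speckle_gain = cfg$speckle_gain,
                   dots = dots)
  }
  roi_mask <- matrix(FALSE, h, w)
  roi_mask[geom$roi_top:geom$roi_bottom, ] <- TRUE
  structure(list(site_id = sprintf("%s%02d",
                                   c("A-MTrP" = "A", "L-MTrP" = "L",
                                     "healthy" = "H")[group],
                                   ((index - 1L) %% cfg$n_sites_per_group) + 1L),
                 group = group,
                 index = index,
                 seed = site_seed,
                 params = params,
                 lesion = lesion,
                 roi_mask = roi_mask,
                 frames = list(),
                 frame_indices = integer(0),
                 config = cfg),
            class = "site_record")
}

#' Render one frame of a site's sweep
#'
#' Renders the `frame_index`-th frame (1-based) of the simulated transducer
#' sweep for a site produced by [generate_cohort()].  The lesion drifts
#' laterally by `image_width / frames_per_site` pixels per frame (wrapping
#' at the frame edge), emulating the ~1 cm/s probe motion, so frames sampled
#' across the sweep view different sections of the knot.  Rendering a frame
#' depends only on the site parameters and the frame index, so any subset of
#' frames can be rendered reproducibly.
#'
#' @param site A `site_record`.
#' @param frame_index Frame number in `1:frames_per_site`.
#' @param lesion Optional lesion override; `NULL` renders the site without
#'   its lesion (used for matched healthy-reference rendering).
#' @return An integer matrix with values in 0..255.
#' @export
render_frame <- function(site, frame_index,
                         lesion = if (is.null(site$lesion)) NULL else site$lesion) {
  cfg <- site$config
  if (frame_index < 1L || frame_index > cfg$frames_per_site)
    stop("frame_index out of range")
  h <- cfg$image_height; w <- cfg$image_width
  p <- site$params
  rows <- seq_len(h); cols <- seq_len(w)

  depth <- cfg$background_level *
    (1 - cfg$depth_attenuation * (rows - 1) / (h - 1))
  echo <- matrix(depth, h, w) * p$gain

  stri <- 1 + cfg$striation_amplitude *
    sin(2 * pi * outer(rows * cos(p$striation_angle),
                       cols * sin(p$striation_angle), "+") /
          p$striation_period + p$striation_phase)
  echo <- echo * stri

  if (!is.null(lesion)) {
    drift <- (frame_index - 1) * w / cfg$frames_per_site
    cc <- ((lesion$center_col - 1 + drift) %% w) + 1
    dr <- (rows - lesion$center_row) / lesion$semi_r
    dcpix <- ((cols - cc + w / 2) %% w) - w / 2
    dc <- dcpix / lesion$semi_c
    inside <- outer(dr^2, dc^2, "+") <= 1
    factor <- matrix(1, h, w)
    if (lesion$echogenicity_drop > 0)
      factor[inside] <- 1 - lesion$echogenicity_drop
    if (!is.null(lesion$dots) && lesion$speckle_gain > 1) {
      for (k in seq_len(nrow(lesion$dots))) {
        d2 <- outer((rows - lesion$center_row - lesion$dots[k, "dr"])^2,
                    (dcpix - lesion$dots[k, "dc"])^2, "+")
        factor <- factor * (1 + (lesion$speckle_gain - 1) * exp(-d2 / (2 * 1.5^2)))
      }
    }
    echo <- echo * factor
  }

  fth <- p$fascia_thick / 2
  fascia <- cfg$fascia_amplitude *
    (exp(-(rows - p$fascia_top)^2 / (2 * fth^2)) +
       exp(-(rows - p$fascia_bottom)^2 / (2 * fth^2)))
  echo <- echo + matrix(fascia, h, w)

  set.seed(derive_seed(site$seed, 1000L + frame_index))
  img <- echo * speckle_field(h, w)
  storage.mode(img) <- "double"
  m <- pmin(pmax(round(img), 0), 255)
  storage.mode(m) <- "integer"
  m
}

#' Evenly spaced frame selection
#'
#' Deterministically selects `k` frame indices spanning the sweep, endpoints
#' included, emulating the selection of frames that view different sections
#' of the muscle.  Indices are 1-based.
#'
#' @param frames A list of frames (or a single integer giving their count).
#' @param k Number of frames to select.
#' @return If `frames` is a count, the integer indices; otherwise the
#'   selected frames.
#' @export
select_frames <- function(frames, k) {
  n <- if (is.numeric(frames) && length(frames) == 1L) as.integer(frames)
       else length(frames)
  if (k > n) stop("cannot select ", k, " frames out of ", n)
  if (k < 1L) stop("k must be >= 1")
  idx <- if (k == 1L) 1L else as.integer(ceiling(seq(0, n - 1, length.out = k))) + 1L
  if (is.numeric(frames) && length(frames) == 1L) idx else frames[idx]
}

#' Crop an image to the bounding rectangle of a region-of-interest mask
#'
#' Returns the tight bounding rectangle of the mask; pixels inside the
#' rectangle but outside the mask are retained as-is (rectangular crop).
#'
#' @param image Numeric matrix.
#' @param roi_mask Logical matrix of the same dimensions.
#' @return The cropped matrix.
#' @export
extract_roi <- function(image, roi_mask) {
  stopifnot(is.matrix(image), is.matrix(roi_mask),
            all(dim(image) == dim(roi_mask)))
  if (!any(roi_mask)) stop("empty ROI mask")
  rr <- range(which(rowSums(roi_mask) > 0))
  cr <- range(which(colSums(roi_mask) > 0))
  out <- image[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  if (nrow(out) < 32L || ncol(out) < 32L)
    stop("ROI crop smaller than 32 x 32 pixels")
  out
}

#' Generate a synthetic cohort
#'
#' Generates `3 * n_sites_per_group` site records with exactly balanced
#' group assignment and full ground truth.  With `render = "selected"`
#' (default) only the [select_frames()] subset of each sweep is rendered;
#' `"all"` renders the full sweep; `"none"` renders nothing (parameters
#' only).  Rendering is per-frame deterministic, so the selected subset is
#' bit-identical to the corresponding frames of a fully rendered sweep.
#'
#' @param config A [cohort_config()].
#' @param render One of `"selected"`, `"all"`, `"none"`.
#' @return A list of `site_record` objects, with attribute `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            render = c("selected", "all", "none")) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  render <- match.arg(render)
  n <- config$n_sites_per_group
  groups <- rep(GROUP_LEVELS, each = n)
  sites <- vector("list", 3L * n)
  sel <- select_frames(config$frames_per_site, config$frames_selected)
  for (i in seq_along(groups)) {
    site <- make_site(config, groups[i], i)
    idx <- switch(render,
                  selected = sel,
                  all = seq_len(config$frames_per_site),
                  none = integer(0))
    site$frame_indices <- idx
    site$frames <- lapply(idx, function(k) render_frame(site, k))
    names(site$frames) <- as.character(idx)
    sites[[i]] <- site
  }
  structure(sites, config = config, class = "mtrptex_cohort")
}

#' Null-cohort configuration
#'
#' Convenience wrapper: a configuration whose lesion parameters equal the
#' healthy values (no echogenicity drop, no internal dots), making the three
#' groups statistically exchangeable.
#'
#' @param ... Passed on to [cohort_config()].
#' @export
null_cohort_config <- function(...) {
  cohort_config(echogenicity_drop_active = 0,
                echogenicity_drop_latent = 0,
                speckle_count = 0L, ...)
}
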