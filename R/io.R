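# Image and cohort I/O: 8-bit grayscale PNG/TIFF, cohort directory trees
# with a manifest and config file.

#' Read an 8-bit grayscale image
#'
#' Reads PNG or TIFF.  Multi-channel input is refused unless all color
#' channels are identical, in which case it is collapsed to one channel
#' with a warning (a trailing constant alpha channel is ignored).  Higher
#' bit depths are rescaled max-preserving to 8 bits.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Integer matrix with values in 0..255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    ch <- if (nch %in% c(2L, 4L)) nch - 1L else nch  # drop alpha if present
    for (k in seq_len(ch)[-1])
      if (!isTRUE(all.equal(a[, , 1], a[, , k])))
        stop("multi-channel image with differing channels")
    warning("collapsing ", nch, "-channel image to grayscale")
    a <- a[, , 1]
  }
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write an 8-bit grayscale image
#'
#' @param image Matrix with values in 0..255.
#' @param path Destination path (`.png`, `.tif` or `.tiff`).
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 255)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image / 255, path),
         tif = ,
         tiff = tiff::writeTIFF(image / 255, path, bits.per.sample = 8L),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Write a cohort as a directory tree
#'
#' Layout: `dir/<group>/<site_id>/frame_<k>.png`, plus `manifest.csv`
#' (site id, group, frame paths, ROI row range, lesion ground truth) and
#' `config.yaml`.
#'
#' @param cohort Output of [generate_cohort()] (frames rendered).
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  cfg <- attr(cohort, "config")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (site in cohort) {
    sdir <- file.path(dir, site$group, site$site_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (k in seq_along(site$frames)) {
      p <- file.path(sdir, sprintf("frame_%03d.png",
                                   site$frame_indices[k]))
      write_image(site$frames[[k]], p)
      paths <- c(paths, p)
    }
    rr <- range(which(rowSums(site$roi_mask) > 0))
    les <- site$lesion
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = site$site_id, group = site$group,
      frame_indices = paste(site$frame_indices, collapse = ";"),
      frame_paths = paste(paths, collapse = ";"),
      roi_top = rr[1], roi_bottom = rr[2],
      lesion_center_row = if (is.null(les)) NA else les$center_row,
      lesion_center_col = if (is.null(les)) NA else les$center_col,
      lesion_semi_r = if (is.null(les)) NA else les$semi_r,
      lesion_semi_c = if (is.null(les)) NA else les$semi_c,
      echogenicity_drop = if (is.null(les)) 0 else les$echogenicity_drop)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list of `site_record`-like objects with frames, ROI masks,
#'   group labels, and lesion ground truth; attribute `config`.
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  cfg <- do.call(cohort_config, yaml::read_yaml(file.path(dir, "config.yaml")))
  sites <- lapply(seq_len(nrow(man)), function(i) {
    paths <- strsplit(man$frame_paths[i], ";")[[1]]
    frames <- lapply(paths, read_image)
    idx <- as.integer(strsplit(man$frame_indices[i], ";")[[1]])
    names(frames) <- as.character(idx)
    mask <- matrix(FALSE, cfg$image_height, cfg$image_width)
    mask[man$roi_top[i]:man$roi_bottom[i], ] <- TRUE
    lesion <- NULL
    if (!is.na(man$lesion_center_row[i]))
      lesion <- list(center_row = man$lesion_center_row[i],
                     center_col = man$lesion_center_col[i],
                     semi_r = man$lesion_semi_r[i],
                     semi_c = man$lesion_semi_c[i],
                     echogenicity_drop = man$echogenicity_drop[i])
    structure(list(site_id = man$site_id[i], group = man$group[i],
                   frames = frames, frame_indices = idx,
                   roi_mask = mask, lesion = lesion, config = cfg),
              class = "site_record")
  })
  structure(sites, config = cfg, class = "mtrptex_cohort")
}
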