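# Synthetic cohort generator: balance, determinism, geometry, image model.

test_that("cohort generation is balanced and sized as configured", {
  co <- small_cohort(n = 2L)
  expect_length(co, 6L)
  expect_equal(as.vector(table(vapply(co, `[[`, "", "group"))),
               c(2L, 2L, 2L))
  co1 <- generate_cohort(cohort_config(n_sites_per_group = 1L,
                                       frames_per_site = 4L,
                                       frames_selected = 1L,
                                       image_height = 128L,
                                       image_width = 128L), render = "none")
  expect_length(co1, 3L)
  # healthy sites have no lesion; trigger-point sites do
  expect_true(all(vapply(co, function(s)
    is.null(s$lesion) == (s$group == "healthy"), TRUE)))
})

test_that("identical configuration and seed give bit-identical cohorts", {
  a <- small_cohort(seed = 99L)
  b <- small_cohort(seed = 99L)
  expect_identical(lapply(a, `[[`, "frames"), lapply(b, `[[`, "frames"))
  c2 <- small_cohort(seed = 100L)
  expect_false(identical(a[[1]]$frames[[1]], c2[[1]]$frames[[1]]))
})

test_that("rendering a frame subset matches the full sweep", {
  cfg <- cohort_config(n_sites_per_group = 1L, frames_per_site = 10L,
                       frames_selected = 3L, image_height = 128L,
                       image_width = 128L, seed = 4L)
  sel <- generate_cohort(cfg, render = "selected")
  all_ <- generate_cohort(cfg, render = "all")
  for (i in seq_along(sel))
    for (k in names(sel[[i]]$frames))
      expect_identical(sel[[i]]$frames[[k]], all_[[i]]$frames[[k]])
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(frames_selected = 10L, frames_per_site = 4L),
               "frames_selected")
  expect_error(cohort_config(n_sites_per_group = 0L), "counts")
  expect_error(cohort_config(image_height = 40L), "configuration error|ROI")
  expect_error(cohort_config(echogenicity_drop_active = 1), "drops")
})

test_that("frame selection spans the sweep with even spacing", {
  expect_equal(select_frames(300L, 4L), c(0L, 100L, 200L, 299L) + 1L)
  expect_equal(select_frames(10L, 2L), c(1L, 10L))
  frames <- as.list(letters[1:5])
  expect_identical(select_frames(frames, 5L), frames)
  expect_error(select_frames(3L, 4L), "cannot select")
})

test_that("ROI extraction crops to the mask bounding box", {
  img <- matrix(seq_len(64 * 64), 64, 64)
  full <- matrix(TRUE, 64, 64)
  expect_identical(extract_roi(img, full), img)
  m <- matrix(FALSE, 64, 64); m[8:57, 10:59] <- TRUE
  crop <- extract_roi(img, m)
  expect_equal(dim(crop), c(50L, 50L))
  expect_identical(crop, img[8:57, 10:59])
  # idempotence
  expect_identical(extract_roi(crop, matrix(TRUE, 50, 50)), crop)
  expect_error(extract_roi(img, matrix(FALSE, 64, 64)), "empty")
  small <- matrix(FALSE, 64, 64); small[1:10, 1:10] <- TRUE
  expect_error(extract_roi(img, small), "32")
})

test_that("lesion darkening matches the configured echogenicity drop", {
  cfg <- cohort_config(n_sites_per_group = 1L, frames_per_site = 100L,
                       image_height = 128L, image_width = 192L,
                       speckle_count = 0L, seed = 42L)
  site <- generate_cohort(cfg, render = "none")[[1]]  # active, drop 0.5
  les <- site$lesion
  ratios <- vapply(seq_len(100L), function(k) {
    with_l <- render_frame(site, k)
    without <- render_frame(site, k, lesion = NULL)
    cc <- ((les$center_col - 1 + (k - 1) * cfg$image_width / cfg$frames_per_site) %%
             cfg$image_width) + 1
    dr <- (seq_len(cfg$image_height) - les$center_row) / les$semi_r
    dcp <- ((seq_len(cfg$image_width) - cc + cfg$image_width / 2) %%
              cfg$image_width) - cfg$image_width / 2
    inside <- outer(dr^2, (dcp / les$semi_c)^2, "+") <= 1
    mean(with_l[inside]) / mean(without[inside])
  }, 0)
  expect_equal(mean(ratios), 1 - les$echogenicity_drop, tolerance = 0.02)
})

test_that("healthy rendering is unaffected by the (absent) lesion", {
  cfg <- cohort_config(n_sites_per_group = 1L, frames_per_site = 5L,
                       image_height = 128L, image_width = 128L, seed = 8L)
  healthy <- generate_cohort(cfg, render = "none")[[3]]
  expect_null(healthy$lesion)
  expect_identical(render_frame(healthy, 2L),
                   render_frame(healthy, 2L, lesion = NULL))
})

test_that("speckle is multiplicative with unit mean", {
  set.seed(123)
  s <- mtrptex:::speckle_field(1000L, 1000L)
  expect_equal(mean(s), 1, tolerance = 2e-3)
  # Rayleigh: sd/mean = sqrt(4/pi - 1)
  expect_equal(stats::sd(s), sqrt(4 / pi - 1), tolerance = 5e-3)
})

test_that("ROI mean intensity orders healthy > latent > active", {
  cfg <- cohort_config(n_sites_per_group = 30L, frames_per_site = 4L,
                       frames_selected = 1L, image_height = 128L,
                       image_width = 192L, seed = 314L)
  co <- generate_cohort(cfg)
  means <- vapply(co, function(s)
    mean(extract_roi(s$frames[[1]], s$roi_mask)), 0)
  grp <- vapply(co, `[[`, "", "group")
  m <- tapply(means, grp, mean)
  expect_gt(m[["healthy"]], m[["L-MTrP"]])
  expect_gt(m[["L-MTrP"]], m[["A-MTrP"]])
})
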