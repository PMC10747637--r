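# Independent brute-force oracles (literal double loops / sums), kept free
# of any code path they are used to check.

stats7_oracle <- function(M) {
  P <- M / sum(M)
  n <- nrow(P); m <- ncol(P)
  mu <- mean(P)
  s2 <- sum((P - mu)^2) / (n * m)
  a <- numeric(7)
  for (r in seq_len(n)) for (cl in seq_len(m)) {
    p <- P[r, cl]; i <- r - 1; j <- cl - 1
    if (p > 0) a[1] <- a[1] - log(p) * p
    a[2] <- a[2] + p * (i - j)^2
    if (s2 > 0) a[3] <- a[3] + p * (i - mu) * (j - mu) / s2
    a[4] <- a[4] + p / (1 + (i - j)^2)
    a[5] <- a[5] + p^2
    a[6] <- a[6] + i * p
    a[7] <- a[7] + p * (i - mu)^2
  }
  names(a) <- c("entropy", "contrast", "correlation", "homogeneity",
                "energy", "mean", "variance")
  a
}

lbp_oracle <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, cl) img[min(max(r, 1), nr), min(max(cl, 1), nc)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    code <- 0L
    for (b in seq_along(offs))
      if (at(r + offs[[b]][1], cl + offs[[b]][2]) >= img[r, cl])
        code <- code + as.integer(2^(b - 1))
    out[r, cl] <- code
  }
  out
}

glcm_oracle <- function(img, direction, offset = 1, n_levels) {
  th <- direction * pi / 180
  dr <- round(-sin(th)) * offset; dc <- round(cos(th)) * offset
  cnt <- matrix(0L, n_levels, n_levels)
  for (r in seq_len(nrow(img))) for (cl in seq_len(ncol(img))) {
    r2 <- r + dr; c2 <- cl + dc
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img))
      cnt[img[r, cl] + 1, img[r2, c2] + 1] <- cnt[img[r, cl] + 1, img[r2, c2] + 1] + 1L
  }
  list(counts = cnt, P = cnt / sum(cnt))
}

anova_oracle <- function(groups) {
  y <- unlist(groups); gm <- mean(y); k <- length(groups); n <- length(y)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = stats::pf(F, k - 1, n - k, lower.tail = FALSE))
}

# Small cohorts and feature tables used across test files.
small_cohort <- function(n = 2L, seed = 11L, frames = 20L, selected = 2L, ...) {
  generate_cohort(cohort_config(n_sites_per_group = n, frames_per_site = frames,
                                frames_selected = selected, image_height = 128L,
                                image_width = 192L, seed = seed, ...))
}

# A deterministic toy feature table: each group sits at one vertex of a
# simplex (sep = vertex distance from origin); `site_sd` adds a per-site
# random offset so sites have identity without class information when
# sep = 0 (the permutation-null configuration).
blob_table <- function(n_sites_per_group = 4L, images_per_site = 4L,
                       sep = 6, seed = 5L, noise = 1, site_sd = 0) {
  set.seed(seed)
  rows <- list()
  for (g in seq_along(mtrptex:::GROUP_LEVELS)) {
    for (s in seq_len(n_sites_per_group)) {
      id <- sprintf("%s%02d", c("A", "L", "H")[g], s)
      ctr <- sep * (seq_len(3) == g) + rnorm(3, 0, site_sd)
      for (im in seq_len(images_per_site)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = id, group = mtrptex:::GROUP_LEVELS[g],
          f1 = ctr[1] + rnorm(1, 0, noise),
          f2 = ctr[2] + rnorm(1, 0, noise),
          f3 = ctr[3] + rnorm(1, 0, noise))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = mtrptex:::GROUP_LEVELS)
  class(out) <- c("feature_table", "data.frame")
  out
}
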