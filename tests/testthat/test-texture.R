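# Texture primitives: LBP, Gabor bank, GLCM, Canny, the seven statistics,
# and the four feature approaches.

test_that("LBP codes match the clockwise-from-top-left weighting", {
  patch <- matrix(c(5, 9, 1,
                    4, 6, 7,
                    2, 3, 8), 3, 3, byrow = TRUE)
  expect_equal(lbp_image(patch)[2, 2], 26L)
  const <- matrix(7, 5, 5)
  expect_true(all(lbp_image(const) == 255L))
  expect_error(lbp_image(matrix(1, 2, 2)), "3 x 3")
})

test_that("LBP is invariant to monotone intensity remaps", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 12 * 15, TRUE), 12, 15)
    expect_identical(lbp_image(img), lbp_image(img + 17))
    expect_identical(lbp_image(img), lbp_image(3 * img^2 + img))  # increasing
  }
})

test_that("LBP agrees with a literal per-pixel oracle", {
  set.seed(31)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 10 * 11, TRUE), 10, 11)
    expect_identical(lbp_image(img), lbp_oracle(img))
  }
})

test_that("the Gabor bank has 40 kernels with the declared parameters", {
  b <- gabor_bank()
  expect_length(b, 40L)
  expect_equal(unname(vapply(b, attr, 0, "f"))[1:8], rep(0.25, 8))
  expect_equal(attr(b[[9]], "f"), 0.25 / sqrt(2))
  expect_equal(unname(vapply(b[1:8], attr, 0, "theta")), seq(0, 315, by = 45))
  # center value with zero phase
  for (k in b[c(1, 15, 40)]) {
    ctr <- (nrow(k) + 1L) %/% 2L
    expect_equal(Mod(k[ctr, ctr]), 1, tolerance = 1e-12)
  }
})

test_that("each kernel's spectral peak sits at its configured frequency", {
  b <- gabor_bank()
  n <- 128L
  for (k in b) {
    K <- matrix(0 + 0i, n, n)
    K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
    S <- Mod(stats::fft(K))
    ix <- which(S == max(S), arr.ind = TRUE)[1, ]
    fr <- ifelse(ix - 1 > n / 2, ix - 1 - n, ix - 1) / n
    expect_lt(abs(sqrt(sum(fr^2)) - attr(k, "f")), 1 / n)  # within one bin
  }
})

test_that("Gabor responses are homogeneous and orientation selective", {
  b <- gabor_bank()
  z <- matrix(0, 64, 64)
  expect_true(all(vapply(gabor_responses(z, b), function(r) all(r == 0), TRUE)))
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  r1 <- gabor_responses(img, b)
  r3 <- gabor_responses(3 * img, b)
  expect_equal(r3[[7]], 3 * r1[[7]], tolerance = 1e-10)
  # grating at a bank frequency/orientation is best matched by that filter
  for (case in list(c(s = 2, theta = 90), c(s = 0, theta = 45))) {
    f <- 0.25 / sqrt(2)^case[["s"]]
    th <- case[["theta"]] * pi / 180
    x <- col(matrix(0, 80, 80)); y <- row(matrix(0, 80, 80))
    gr <- 100 + 80 * cos(2 * pi * f * (x * sin(th) + y * cos(th)))
    sc <- vapply(gabor_responses(gr, b), sum, 0)
    best <- names(which.max(sc))
    expect_equal(as.integer(sub("s(\\d+)_o\\d+", "\\1", best)), case[["s"]])
    expect_equal(as.integer(sub("s\\d+_o(\\d+)", "\\1", best)) %% 180,
                 case[["theta"]] %% 180)
  }
  expect_error(gabor_responses(matrix(0, 20, 20), b), "smaller")
})

test_that("GLCM counts co-occurrences along each compass direction", {
  img <- matrix(c(0, 0,
                  0, 1), 2, 2, byrow = TRUE)
  g <- glcm(img, 0, n_levels = 2L)
  expect_equal(unclass(g)[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(sum(unclass(g)), 1)
  const <- matrix(3L, 4, 4)
  gc <- glcm(const, 45, n_levels = 8L)
  expect_equal(unclass(gc)[4, 4], 1)
  # reversing the direction transposes the matrix
  set.seed(9)
  im <- matrix(sample(0:7, 30, TRUE), 5, 6)
  expect_equal(unclass(glcm(im, 180, n_levels = 8L)),
               t(unclass(glcm(im, 0, n_levels = 8L))), ignore_attr = TRUE)
  expect_error(glcm(im, 0, offset = 10L), "larger")
})

test_that("GLCM agrees with a literal pair-count oracle and conserves pairs", {
  set.seed(41)
  for (rep in 1:20) {
    im <- matrix(sample(0:15, 9 * 8, TRUE), 9, 8)
    d <- sample(mtrptex:::GLCM_DIRECTIONS, 1)
    g <- glcm(im, d, n_levels = 16L)
    o <- glcm_oracle(im, d, 1, 16L)
    expect_equal(unclass(g), o$P, ignore_attr = TRUE, tolerance = 1e-14)
    # raw counts equal the number of in-bounds displaced pairs
    step <- mtrptex:::direction_step(d)
    n_pairs <- (nrow(im) - abs(step["dr"])) * (ncol(im) - abs(step["dc"]))
    expect_equal(sum(attr(g, "counts")), as.integer(n_pairs),
                 ignore_attr = TRUE)
  }
})

test_that("Canny finds thin edges and ignores constant or inverted input", {
  expect_true(all(canny_edges(matrix(5, 32, 32)) == 0L))
  step <- matrix(0, 32, 32); step[, 17:32] <- 100
  e <- canny_edges(step)
  cols <- unique(which(e == 1L, arr.ind = TRUE)[, 2])
  expect_length(cols, 1L)             # one-pixel-wide vertical line
  expect_equal(sum(rowSums(e) > 0), 32L)
  expect_identical(canny_edges(100 - step), e)  # gradient magnitude only
  expect_error(canny_edges(step, low_frac = 0.3, high_frac = 0.2),
               "degenerate")
})

test_that("the seven statistics match closed forms and the literal oracle", {
  u <- stats7(matrix(1, 4, 4))
  expect_equal(u[["entropy"]], log(16))
  expect_equal(u[["contrast"]], 2.5)   # sum (i-j)^2 = 40 over 0..3 x 0..3
  expect_equal(u[["energy"]], 1 / 16)
  expect_equal(u[["homogeneity"]], 0.5)
  expect_equal(u[["mean"]], 1.5)
  expect_equal(u[["correlation"]], 0)  # uniform P has zero entry variance
  onehot <- matrix(0, 4, 4); onehot[1, 1] <- 1
  expect_equal(stats7(onehot), stats7_oracle(onehot), tolerance = 1e-14)
  expect_equal(stats7(onehot)[["entropy"]], 0)
  expect_equal(stats7(onehot)[["energy"]], 1)
  expect_equal(stats7(onehot)[["mean"]], 0)
  set.seed(51)
  for (rep in 1:25) {
    M <- matrix(stats::rexp(42), 6, 7)
    expect_equal(stats7(M), stats7_oracle(M), tolerance = 1e-12)
  }
  expect_error(stats7(matrix(0, 3, 3)), "all-zero")
})

test_that("homogeneity is at most 1 with equality only on the diagonal", {
  set.seed(61)
  for (rep in 1:10) {
    M <- matrix(stats::rexp(25), 5, 5)
    expect_lte(stats7(M)[["homogeneity"]], 1)
  }
  D <- diag(stats::rexp(5))
  expect_equal(stats7(D)[["homogeneity"]], 1)
})

test_that("the four approaches have the declared dimensionalities", {
  set.seed(71)
  roi <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  fb <- features_bmode(roi); fl <- features_lbp(roi)
  fg <- features_gabor(roi); fs <- features_segl(roi)
  expect_length(fb, 7L); expect_length(fl, 7L)
  expect_length(fg, 280L); expect_length(fs, 56L)
  expect_equal(unname(fb), unname(stats7(roi)))
  expect_equal(unname(fl), unname(stats7_oracle(lbp_oracle(roi))),
               tolerance = 1e-12)
  # shift invariance inherited from LBP
  expect_equal(features_lbp(roi), features_lbp(roi + 9))
  # first 7 Gabor entries are the statistics of the first response
  b <- gabor_bank()
  r1 <- gabor_responses(roi, b)[[1]]
  expect_equal(unname(fg[1:7]), unname(stats7(r1)))
  expect_error(features_gabor(matrix(0, 64, 64)), "all-zero")
})

test_that("the SEGL chain matches its step-by-step composition", {
  set.seed(81)
  roi <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  fs <- features_segl(roi)
  L <- lbp_oracle(roi)
  manual <- numeric(0)
  for (d in mtrptex:::GLCM_DIRECTIONS) {
    P <- glcm_oracle(L, d, 1, 256L)$P
    rng <- range(P)
    M <- round((P - rng[1]) / (rng[2] - rng[1]) * 255)
    E <- canny_edges(M)
    v <- if (sum(E) == 0) stats7(matrix(1, 256, 256)) else stats7(E)
    manual <- c(manual, unname(v))
  }
  expect_equal(unname(fs), manual, tolerance = 1e-12)
})

test_that("edge-free SEGL directions fall back to uniform statistics", {
  expect_warning(v <- mtrptex:::edge_stats(matrix(0L, 6, 6), 45L), "no edges")
  expect_equal(unname(v), unname(stats7(matrix(1, 6, 6))))
  # a constant ROI exercises the degenerate chain end to end
  fs <- suppressWarnings(features_segl(matrix(100, 16, 16)))
  expect_length(fs, 56L)
  expect_true(all(is.finite(fs)))
})

test_that("feature tables have one row per selected image and no gaps", {
  co <- small_cohort(n = 2L, selected = 2L)
  tb <- feature_table(co, "bmode")
  expect_s3_class(tb, "feature_table")
  expect_equal(nrow(tb), 6L * 2L)
  expect_equal(ncol(tb), 2L + 7L)
  expect_false(anyNA(tb))
  tb2 <- feature_table(co, "bmode")
  expect_identical(tb, tb2)  # deterministic
})
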