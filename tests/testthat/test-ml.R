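# Leave-one-site-out evaluation: folds, splits, classifiers, metrics.

test_that("LOSO folds partition the table with one site per fold", {
  tb <- blob_table(n_sites_per_group = 2L)
  folds <- loso_folds(tb)
  expect_length(folds, 6L)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 4L))
  expect_true(all(vapply(folds, function(f) length(f$train), 0L) == 20L))
  # partition: every row is tested exactly once; train/test sites disjoint
  tested <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tested, seq_len(nrow(tb)))
  for (f in folds)
    expect_length(intersect(tb$site_id[f$train], tb$site_id[f$test]), 0L)
})

test_that("the NN site-level split reproduces the 67/22 design", {
  sites <- sprintf("S%03d", 1:89)
  tb <- data.frame(site_id = rep(sites, each = 4L),
                   group = factor(rep(mtrptex:::GROUP_LEVELS, length.out = 356),
                                  levels = mtrptex:::GROUP_LEVELS),
                   f1 = rnorm(356))
  sp <- nn_split(tb, seed = 3L)
  expect_length(unique(sp$train$site_id), 67L)
  expect_length(unique(sp$val$site_id), 22L)
  expect_equal(nrow(sp$train), 268L)
  expect_equal(nrow(sp$val), 88L)
  expect_length(intersect(sp$train$site_id, sp$val$site_id), 0L)
  # 4 sites -> 3/1
  tb4 <- tb[tb$site_id %in% sites[1:4], ]
  sp4 <- nn_split(tb4, seed = 3L)
  expect_length(unique(sp4$train$site_id), 3L)
  expect_length(unique(sp4$val$site_id), 1L)
})

test_that("every technique separates well-separated blobs perfectly", {
  tb <- blob_table(n_sites_per_group = 5L, sep = 12, noise = 0.2)
  params <- c(kNN = "3", DT = "gini", RF = "gini", LR = "10", NB = "1e-09",
              SVM = "10", NN = "default")
  for (tech in names(params)) {
    r <- evaluate_loso(tb, tech, params[[tech]], seed = 7L, hidden = 64L)
    expect_equal(r$metrics$accuracy, 100,
                 label = paste(tech, "accuracy"))
  }
})

test_that("site-permuted labels give chance-level accuracy", {
  # sites have feature identity (site_sd) but labels carry no information
  tb <- blob_table(n_sites_per_group = 5L, sep = 0, noise = 1, site_sd = 2,
                   seed = 77L)
  n <- nrow(tb)
  band <- 2.576 * sqrt((1 / 3) * (2 / 3) / n)
  params <- c(kNN = "3", NB = "1e-09", SVM = "10", LR = "10")
  for (tech in names(params)) {
    acc <- evaluate_loso(tb, tech, params[[tech]],
                         seed = 13L)$metrics$accuracy / 100
    expect_lt(abs(acc - 1 / 3), band + 1e-12,
              label = paste(tech, "null accuracy"))
  }
})

test_that("fit_predict is deterministic and standardizes on the train fold", {
  tb <- blob_table(n_sites_per_group = 3L)
  folds <- loso_folds(tb)
  f <- folds[[1]]
  p1 <- fit_predict("RF", "gini", tb[f$train, ], tb[f$test, ], seed = 5L)
  p2 <- fit_predict("RF", "gini", tb[f$train, ], tb[f$test, ], seed = 5L)
  expect_identical(p1, p2)
  # zero-variance feature triggers a warning and is dropped
  tb0 <- tb; tb0$f3 <- 1
  expect_warning(fit_predict("kNN", "3", tb0[f$train, ], tb0[f$test, ],
                             seed = 5L),
                 "zero-variance")
})

test_that("the network has the declared architecture and trains to fit", {
  tb <- blob_table(n_sites_per_group = 4L, sep = 8, noise = 0.5)
  sp <- nn_split(tb, seed = 2L)
  fc <- c("f1", "f2", "f3")
  xt <- scale(as.matrix(sp$train[, fc]))
  xv <- scale(as.matrix(sp$val[, fc]),
              attr(xt, "scaled:center"), attr(xt, "scaled:scale"))
  fit <- train_nn(xt, sp$train$group, xv, sp$val$group,
                  seed = 9L, hidden = 512L)
  expect_equal(dim(fit$W1), c(3L, 512L))
  expect_equal(dim(fit$W2), c(512L, 3L))
  P <- predict_nn_prob(fit, xv)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  h <- fit$history$train
  expect_lt(h[length(h)], h[1])  # loss decreased on a separable toy set
  expect_error(train_nn(xt, sp$train$group,
                        matrix(0, 0, 3), factor(character(),
                                                levels = levels(tb$group))),
               "validation")
})

test_that("confusion counts aggregate predictions correctly", {
  g <- factor(rep(mtrptex:::GROUP_LEVELS, each = 4L),
              levels = mtrptex:::GROUP_LEVELS)
  cm <- confusion_counts(g, g)
  expect_equal(diag(cm), c(4L, 4L, 4L), ignore_attr = TRUE)
  expect_equal(sum(cm), 12L)
  p <- g; p[1] <- "healthy"
  cm2 <- confusion_counts(g, p)
  expect_equal(sum(cm2 * upper.tri(cm2)), 1L)
  expect_equal(sum(cm2), 12L)
})

test_that("micro-averaged metrics satisfy the balanced-class identities", {
  idm <- diag(c(10L, 10L, 10L))
  m <- classification_metrics(idm)
  expect_equal(m$accuracy, 100)
  expect_true(all(unlist(m[c("f1", "sensitivity", "specificity",
                             "ppv", "npv")]) == 1))
  unif <- matrix(5L, 3, 3)
  mu <- classification_metrics(unif)
  expect_equal(mu$accuracy, 100 / 3)
  expect_equal(mu$sensitivity, 1 / 3)
  expect_equal(mu$specificity, 2 / 3)
  expect_error(classification_metrics(matrix(0L, 3, 3)), "empty")
})

test_that("grid selection maximizes mean accuracy with first-value ties", {
  mk <- function(acc) data.frame(
    approach = rep(c("bmode", "lbp"), each = 3),
    technique = "kNN", param = rep(c("3", "5", "7"), 2),
    accuracy = acc)
  grid <- classifier_grid()[1:3, ]
  # strict maximum at k = 5
  sel <- grid_select(mk(c(40, 60, 50, 42, 58, 48)), grid)
  expect_equal(sel$param, "5")
  expect_equal(sel$mean_accuracy, 59)
  # exact tie -> first grid value
  sel2 <- grid_select(mk(rep(45, 6)), grid)
  expect_equal(sel2$param, "3")
  # single candidate -> itself
  sel3 <- grid_select(mk(c(40, 60, 50, 42, 58, 48))[c(1, 4), ], grid[1, ])
  expect_equal(sel3$param, "3")
})
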