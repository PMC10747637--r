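# Leave-one-site-out evaluation, micro-averaged metrics, and grid selection.

#' Leave-one-site-out folds
#'
#' One fold per site: the fold's test rows are that site's images, the train
#' rows all other sites' images.  The test sets partition the table.
#'
#' @param table A [feature_table()] (`site_id`, `group`, features).
#' @return List of folds, each `list(train, test)` of integer row indices.
#' @export
loso_folds <- function(table) {
  sites <- unique(table$site_id)
  if (!length(sites)) stop("no sites in table")
  counts <- table(table$site_id)
  if (any(counts == 0)) stop("site with 0 rows")
  lapply(sites, function(s) {
    test <- which(table$site_id == s)
    list(site = s, train = setdiff(seq_len(nrow(table)), test), test = test)
  })
}

#' Site-level train/validation split for the neural network
#'
#' Splits the training rows at the site level into 75% training and 25%
#' validation sites (validation count rounded to the nearest integer; 89
#' sites give 67/22, i.e. 268/88 images at 4 images per site), using a
#' seeded shuffle.  Site-level splitting prevents images of one site from
#' appearing on both sides.
#'
#' @param train_rows Data frame of training rows.
#' @param seed Integer seed for the shuffle.
#' @param val_frac Validation fraction of sites (default 0.25).
#' @return `list(train, val)` of data frames with disjoint site sets.
#' @export
nn_split <- function(train_rows, seed = 1L, val_frac = 0.25) {
  sites <- unique(train_rows$site_id)
  n_val <- round(val_frac * length(sites))
  n_val <- max(1L, min(length(sites) - 1L, n_val))
  set.seed(seed)
  val_sites <- sample(sites, n_val)
  list(train = train_rows[!train_rows$site_id %in% val_sites, , drop = FALSE],
       val = train_rows[train_rows$site_id %in% val_sites, , drop = FALSE])
}

# Train-fold z-scoring; zero-variance features are dropped with a warning.
#' @keywords internal
standardize_fold <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sd_ <- apply(train_x, 2, stats::sd)
  keep <- sd_ > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " zero-variance feature(s)")
  if (!any(keep)) stop("all features are degenerate in this training fold")
  list(train = scale(train_x[, keep, drop = FALSE], mu[keep], sd_[keep]),
       test = scale(test_x[, keep, drop = FALSE], mu[keep], sd_[keep]))
}

#' Fit one classifier on a training fold and predict the test fold
#'
#' Features are standardized (z-score) using training-fold statistics only.
#' `technique` is one of `"kNN"`, `"DT"`, `"RF"`, `"LR"`, `"NB"`, `"SVM"`,
#' `"NN"` with `param` from [classifier_grid()].  Results are deterministic
#' given `seed`.
#'
#' @param technique,param Classifier family and hyperparameter value.
#' @param train,test Data frames with `site_id`, `group`, and features.
#' @param seed Integer seed.
#' @param hidden NN hidden width (ignored by other techniques).
#' @return Factor of predicted groups for the test rows.
#' @export
fit_predict <- function(technique, param, train, test, seed = 1L,
                        hidden = 512L) {
  fc <- feature_columns(train)
  xz <- standardize_fold(as.matrix(train[, fc, drop = FALSE]),
                         as.matrix(test[, fc, drop = FALSE]))
  xtr <- xz$train; xte <- xz$test
  ytr <- factor(train$group, levels = GROUP_LEVELS)
  set.seed(seed)
  pred <- switch(
    technique,
    kNN = class::knn(xtr, xte, ytr, k = as.integer(param)),
    DT = {
      crit <- if (param == "gini") "gini" else "information"
      df <- data.frame(.y = ytr, xtr, check.names = TRUE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = crit),
                          control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                         minbucket = 2,
                                                         xval = 0))
      nd <- data.frame(xte, check.names = TRUE)
      colnames(nd) <- colnames(df)[-1]
      factor(predict(fit, nd, type = "class"), levels = GROUP_LEVELS)
    },
    RF = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 100L)
      factor(predict(fit, xte), levels = GROUP_LEVELS)
    },
    LR = {
      C <- as.numeric(param)
      lam <- 1 / (C * nrow(xtr))
      fit <- glmnet::glmnet(xtr, ytr, family = "multinomial", alpha = 0,
                            lambda = lam)
      factor(as.vector(predict(fit, xte, type = "class", s = lam)),
             levels = GROUP_LEVELS)
    },
    NB = gaussian_nb_predict(gaussian_nb_fit(xtr, ytr, as.numeric(param)), xte),
    SVM = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = as.numeric(param),
                        scale = FALSE)
      factor(predict(fit, xte), levels = GROUP_LEVELS)
    },
    NN = {
      sp <- nn_split(train, seed = derive_seed(seed, 17L))
      fitted <- train_nn(as.matrix(sp$train[, fc, drop = FALSE]) |>
                           scale_like(xz),
                         factor(sp$train$group, levels = GROUP_LEVELS),
                         as.matrix(sp$val[, fc, drop = FALSE]) |>
                           scale_like(xz),
                         factor(sp$val$group, levels = GROUP_LEVELS),
                         seed = derive_seed(seed, 29L), hidden = hidden)
      P <- predict_nn_prob(fitted, xte)
      factor(colnames(P)[max.col(P, ties.method = "first")],
             levels = GROUP_LEVELS)
    },
    stop("unknown technique: ", technique))
  factor(pred, levels = GROUP_LEVELS)
}

# Re-applies the training-fold standardization (including the dropped
# zero-variance columns) to another matrix.
#' @keywords internal
scale_like <- function(x, xz) {
  ctr <- attr(xz$train, "scaled:center")
  scl <- attr(xz$train, "scaled:scale")
  scale(x[, colnames(xz$train), drop = FALSE], ctr, scl)
}

#' Confusion counts over fold predictions
#'
#' @param truth,pred Factors over the three groups (or a data frame with
#'   columns `group` and `pred` as first argument).
#' @return 3 x 3 integer matrix, rows = true class, columns = predicted.
#' @export
confusion_counts <- function(truth, pred = NULL) {
  if (is.data.frame(truth)) {
    pred <- truth$pred; truth <- truth$group
  }
  truth <- factor(truth, levels = GROUP_LEVELS)
  pred <- factor(pred, levels = GROUP_LEVELS)
  m <- table(truth = truth, pred = pred)
  m <- matrix(as.integer(m), length(GROUP_LEVELS), length(GROUP_LEVELS),
              dimnames = dimnames(m))
  m
}

#' Micro-averaged performance metrics
#'
#' Pools per-class true/false positives and negatives over all classes
#' (micro-averaging) before computing the six metrics.  With balanced
#' classes this yields the identities sensitivity = accuracy/100 and
#' specificity = (1 + accuracy/100)/2.
#'
#' @param cm Confusion matrix (true x predicted).
#' @return Named list: `accuracy` (percent), `f1`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (fractions).
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  tp_c <- diag(cm)
  fp_c <- colSums(cm) - tp_c
  fn_c <- rowSums(cm) - tp_c
  tn_c <- n - rowSums(cm) - colSums(cm) + tp_c
  TP <- sum(tp_c); FP <- sum(fp_c); FN <- sum(fn_c); TN <- sum(tn_c)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  ppv <- TP / (TP + FP)
  npv <- TN / (TN + FN)
  f1 <- 2 * ppv * sens / (ppv + sens)
  list(accuracy = 100 * TP / n, f1 = f1, sensitivity = sens,
       specificity = spec, ppv = ppv, npv = npv)
}

#' Leave-one-site-out evaluation of one classifier
#'
#' Runs [fit_predict()] over every LOSO fold (per-fold seeds derived from
#' `seed`), aggregates the predictions, and computes the confusion counts
#' and micro-averaged metrics.
#'
#' @param table A [feature_table()].
#' @param technique,param Classifier family and hyperparameter.
#' @param seed Master seed.
#' @param hidden NN hidden width.
#' @return `list(predictions, confusion, metrics)`; `predictions` has one
#'   row per image in table order with `site_id`, `group`, `pred`.
#' @export
evaluate_loso <- function(table, technique, param, seed = 1L, hidden = 512L) {
  folds <- loso_folds(table)
  pred <- factor(rep(NA, nrow(table)), levels = GROUP_LEVELS)
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    p <- fit_predict(technique, param,
                     table[f$train, , drop = FALSE],
                     table[f$test, , drop = FALSE],
                     seed = derive_seed(seed, fi))
    pred[f$test] <- p
  }
  predictions <- data.frame(site_id = table$site_id, group = table$group,
                            pred = pred)
  cm <- confusion_counts(predictions)
  list(predictions = predictions, confusion = cm,
       metrics = classification_metrics(cm))
}

#' Evaluate the full classifier grid over several approaches
#'
#' @param tables Named list of [feature_table()]s (one per approach).
#' @param grid Classifier grid (default [classifier_grid()]).
#' @param seed Master seed.
#' @param hidden NN hidden width.
#' @return `list(results, metrics)`: `results` is a nested list
#'   `[[approach]][[technique:param]]` of [evaluate_loso()] outputs and
#'   `metrics` a long data frame (approach, technique, param, six metrics).
#' @export
evaluate_grid <- function(tables, grid = classifier_grid(), seed = 1L,
                          hidden = 512L) {
  results <- list()
  rows <- list()
  for (ap in names(tables)) {
    results[[ap]] <- list()
    for (gi in seq_len(nrow(grid))) {
      tech <- grid$technique[gi]; par <- grid$param[gi]
      r <- evaluate_loso(tables[[ap]], tech, par,
                         seed = derive_seed(seed, gi), hidden = hidden)
      results[[ap]][[paste(tech, par, sep = ":")]] <- r
      rows[[length(rows) + 1L]] <-
        data.frame(approach = ap, technique = tech, param = par,
                   as.data.frame(r$metrics))
    }
  }
  list(results = results, metrics = do.call(rbind, rows))
}

#' Select the best hyperparameter per technique
#'
#' For each technique, picks the hyperparameter value with the highest mean
#' accuracy across the evaluated approaches; ties are broken by the first
#' value in grid order.
#'
#' @param metrics Long metrics data frame from [evaluate_grid()] (columns
#'   `approach`, `technique`, `param`, `accuracy`).
#' @param grid Grid defining the declared order.
#' @return Data frame with one row per technique: `technique`, `param`,
#'   `mean_accuracy`.
#' @export
grid_select <- function(metrics, grid = classifier_grid()) {
  out <- list()
  for (tech in unique(grid$technique)) {
    pars <- grid$param[grid$technique == tech]
    means <- vapply(pars, function(p) {
      m <- metrics$accuracy[metrics$technique == tech & metrics$param == p]
      if (!length(m)) stop("no metrics for ", tech, " param ", p)
      mean(m)
    }, 0)
    best <- pars[which.max(means)]  # which.max takes the first maximum
    out[[tech]] <- data.frame(technique = tech, param = best,
                              mean_accuracy = max(means))
  }
  do.call(rbind, out)
}
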