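# Classifier families and their hyperparameter grids.
#
# The seven techniques and grids follow the evaluated design: kNN
# (n_neighbors 3/5/7), decision tree and random forest (split criterion
# gini/entropy/log_loss), multinomial logistic regression (C 0.1/1/10, L2),
# Gaussian naive Bayes (var_smoothing 1.0/1e-5/1e-9), RBF SVM (C 0.1/1/10),
# and a single-hidden-layer neural network.  The frozen parameter sheet
# (methods vignette) pins every remaining default so behavior does not
# drift with library versions: entropy and log_loss are the same split
# criterion and map to rpart's "information"; randomForest supports Gini
# splitting only, so entropy/log_loss fall back to Gini there; glmnet's
# ridge penalty is lambda = 1/(C n); the SVM uses the RBF kernel with
# gamma = 1/p on standardized features.

#' Classifier grid
#'
#' The full technique x hyperparameter grid, in declared order (used for
#' deterministic tie-breaking in [grid_select()]).
#'
#' @return A `data.frame` with columns `technique` and `param`.
#' @export
classifier_grid <- function() {
  data.frame(
    technique = c(rep("kNN", 3), rep("DT", 3), rep("RF", 3), rep("LR", 3),
                  rep("NB", 3), rep("SVM", 3), "NN"),
    param = c("3", "5", "7",
              "gini", "entropy", "log_loss",
              "gini", "entropy", "log_loss",
              "0.1", "1", "10",
              "1.0", "1e-05", "1e-09",
              "0.1", "1", "10",
              "default"),
    stringsAsFactors = FALSE)
}

# Gaussian naive Bayes with additive variance smoothing: every per-class
# feature variance is inflated by var_smoothing * max_j Var(x_j) computed on
# the pooled training data.
#' @keywords internal
gaussian_nb_fit <- function(x, y, var_smoothing) {
  lv <- levels(droplevels(y))  # only classes present in the training fold
  eps <- var_smoothing * max(apply(x, 2, stats::var) * (nrow(x) - 1) / nrow(x))
  mods <- lapply(lv, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(prior = mean(y == cl),
         mu = colMeans(xc),
         v = apply(xc, 2, stats::var) * (nrow(xc) - 1) / nrow(xc) + eps)
  })
  names(mods) <- lv
  mods
}

#' @keywords internal
gaussian_nb_predict <- function(mods, x) {
  ll <- sapply(mods, function(m) {
    rowSums(sweep(-0.5 * sweep(x, 2, m$mu)^2, 2, m$v, "/")) -
      0.5 * sum(log(2 * pi * m$v)) + log(m$prior)
  })
  factor(names(mods)[max.col(ll, ties.method = "first")], levels = names(mods))
}

# --- Single-hidden-layer neural network -------------------------------------
# Architecture: input -> dense(hidden, ReLU) -> dropout(rate) -> dense(K,
# softmax).  Trained with Adam (lr 1e-3, batch 32), at most `epochs` epochs,
# early stopping on validation loss (patience 7, best weights restored) and
# learning-rate reduction on plateau (factor 0.1, patience 3, floor 1e-5).

#' Train the single-hidden-layer network
#'
#' @param x_train,y_train Training features (matrix) and labels (factor).
#' @param x_val,y_val Validation features and labels (must be non-empty).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @param hidden Hidden-layer width (default 512).
#' @param dropout Dropout rate (default 0.5).
#' @param epochs Maximum epochs (default 250).
#' @param patience Early-stopping patience on validation loss (default 7).
#' @param lr,lr_factor,lr_patience,lr_min Learning-rate schedule: initial
#'   rate, plateau reduction factor, plateau patience, floor.
#' @param batch_size Minibatch size (default 32).
#' @return A fitted model of class `mtrptex_nn` with the weight matrices,
#'   class levels, and the per-epoch training/validation loss history.
#' @export
train_nn <- function(x_train, y_train, x_val, y_val, seed = 1L,
                     hidden = 512L, dropout = 0.5, epochs = 250L,
                     patience = 7L, lr = 1e-3, lr_factor = 0.1,
                     lr_patience = 3L, lr_min = 1e-5, batch_size = 32L) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  if (nrow(x_val) == 0L) stop("empty validation set")
  stopifnot(is.factor(y_train), is.factor(y_val))
  lv <- levels(y_train)
  K <- length(lv); d <- ncol(x_train)
  set.seed(seed)
  W1 <- matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * K, 0, sqrt(2 / hidden)), hidden, K)
  b2 <- numeric(K)
  adam <- list(); for (nm in c("W1", "b1", "W2", "b2"))
    adam[[nm]] <- list(m = 0, v = 0)
  b1_ <- 0.9; b2_ <- 0.999; eps <- 1e-7; tstep <- 0

  onehot <- function(y) {
    m <- matrix(0, length(y), K); m[cbind(seq_along(y), as.integer(y))] <- 1; m
  }
  Yt <- onehot(y_train); Yv <- onehot(y_val)
  fwd <- function(X) {
    H <- pmax(X %*% W1 + matrix(b1, nrow(X), hidden, byrow = TRUE), 0)
    Z <- H %*% W2 + matrix(b2, nrow(X), K, byrow = TRUE)
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    list(H = H, P = E / rowSums(E))
  }
  ce_loss <- function(P, Y) -mean(log(rowSums(P * Y) + 1e-12))

  best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  wait <- 0L; lr_wait <- 0L
  hist_tr <- numeric(0); hist_val <- numeric(0)
  n <- nrow(x_train)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      X <- x_train[ix, , drop = FALSE]; Y <- Yt[ix, , drop = FALSE]
      H <- pmax(X %*% W1 + matrix(b1, nrow(X), hidden, byrow = TRUE), 0)
      mask <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H)) /
        (1 - dropout)
      Hd <- H * mask
      Z <- Hd %*% W2 + matrix(b2, nrow(X), K, byrow = TRUE)
      Z <- Z - apply(Z, 1, max); E <- exp(Z); P <- E / rowSums(E)
      dZ <- (P - Y) / nrow(X)
      grads <- list(W2 = t(Hd) %*% dZ, b2 = colSums(dZ))
      dH <- (dZ %*% t(W2)) * mask * (H > 0)
      grads$W1 <- t(X) %*% dH; grads$b1 <- colSums(dH)
      tstep <- tstep + 1
      for (nm in names(grads)) {
        g <- grads[[nm]]
        adam[[nm]]$m <- b1_ * adam[[nm]]$m + (1 - b1_) * g
        adam[[nm]]$v <- b2_ * adam[[nm]]$v + (1 - b2_) * g^2
        mhat <- adam[[nm]]$m / (1 - b1_^tstep)
        vhat <- adam[[nm]]$v / (1 - b2_^tstep)
        upd <- lr * mhat / (sqrt(vhat) + eps)
        if (nm == "W1") W1 <- W1 - upd else if (nm == "b1") b1 <- b1 - upd
        else if (nm == "W2") W2 <- W2 - upd else b2 <- b2 - upd
      }
    }
    hist_tr <- c(hist_tr, ce_loss(fwd(x_train)$P, Yt))
    vl <- ce_loss(fwd(x_val)$P, Yv)
    hist_val <- c(hist_val, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L; lr_wait <- lr_wait + 1L
      if (lr_wait >= lr_patience && lr > lr_min) {
        lr <- max(lr * lr_factor, lr_min); lr_wait <- 0L
      }
      if (wait >= patience) break
    }
  }
  structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                 levels = lv, hidden = hidden,
                 history = list(train = hist_tr, val = hist_val)),
            class = "mtrptex_nn")
}

#' Predict class probabilities from a fitted network
#'
#' @param object A fitted `mtrptex_nn`.
#' @param x Feature matrix.
#' @param ... Unused.
#' @return Matrix of softmax probabilities (rows sum to 1).
#' @export
predict_nn_prob <- function(object, x, ...) {
  x <- as.matrix(x)
  H <- pmax(x %*% object$W1 +
              matrix(object$b1, nrow(x), object$hidden, byrow = TRUE), 0)
  Z <- H %*% object$W2 +
    matrix(object$b2, nrow(x), length(object$levels), byrow = TRUE)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  colnames(P) <- object$levels
  P
}
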