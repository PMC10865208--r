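#' Train a triage classifier
#'
#' Fits one of three classifier families on a (typically SMOTE-balanced,
#' feature-selected) training table:
#' \describe{
#'   \item{knn}{k-nearest neighbours (`k = knn_k`, default 5) via
#'     \pkg{class}; the training data are memorised and voting happens at
#'     prediction time.}
#'   \item{svm}{C-classification support vector machine via \pkg{e1071}
#'     (default RBF kernel, cost 1).}
#'   \item{mlp}{a multilayer perceptron implemented in the package: one
#'     hidden layer of `mlp_hidden` rectified-linear units, softmax output,
#'     cross-entropy loss, minibatch Adam optimisation, and early stopping
#'     on one fold of a `cv_folds`-fold partition of the training rows
#'     (best-validation weights are restored).}
#' }
#' All three families share one interface; swapping `model` changes no
#' pipeline code. Training is fully reproducible given `seed`.
#'
#' @param ft A `feature_table` with no missing values (rows with missing
#'   features are dropped with a message).
#' @param model `"knn"`, `"svm"` or `"mlp"`.
#' @param knn_k Neighbours for kNN.
#' @param svm_kernel `"radial"` or `"linear"`.
#' @param svm_cost SVM regularisation constant.
#' @param mlp_hidden Hidden-layer width.
#' @param mlp_epochs Maximum training epochs.
#' @param mlp_batch Minibatch size.
#' @param mlp_lr Adam learning rate.
#' @param mlp_patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param cv_folds Folds of the internal partition; fold 1 serves as the
#'   MLP's early-stopping validation set.
#' @param seed Integer seed controlling initialisation, batching and kNN
#'   tie-breaking.
#' @return An object of class `triage_model`.
#' @export
train_triage_model <- function(ft, model = c("knn", "svm", "mlp"),
                               knn_k = 5, svm_kernel = c("radial", "linear"),
                               svm_cost = 1, mlp_hidden = 64,
                               mlp_epochs = 60, mlp_batch = 32,
                               mlp_lr = 1e-3, mlp_patience = 8,
                               cv_folds = 4, seed = 1L) {
  model <- match.arg(model)
  svm_kernel <- match.arg(svm_kernel)
  stopifnot(inherits(ft, "feature_table"))
  if (ncol(ft$x) == 0L) stop("empty feature list", call. = FALSE)
  keep <- stats::complete.cases(ft$x)
  if (!all(keep)) {
    message("train_triage_model: dropping ", sum(!keep),
            " rows with missing features")
    ft <- ft_rows(ft, keep)
  }
  x <- as.matrix(ft$x)
  y <- ft$labels
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  fit <- switch(model,
    knn = list(train = x, y = y, k = knn_k),
    svm = withr::with_seed(as.integer(seed),
      e1071::svm(x, factor(y, levels = classes), type = "C-classification",
                 kernel = svm_kernel, cost = svm_cost, scale = FALSE)),
    mlp = mlp_fit(x, y, hidden = mlp_hidden, epochs = mlp_epochs,
                  batch = mlp_batch, lr = mlp_lr, patience = mlp_patience,
                  val_frac = 1 / cv_folds, seed = seed))
  structure(
    list(model = model, fit = fit, features = colnames(x), classes = classes,
         condition = ft$condition, seed = as.integer(seed),
         config = list(knn_k = knn_k, svm_kernel = svm_kernel,
                       svm_cost = svm_cost, mlp_hidden = mlp_hidden,
                       mlp_epochs = mlp_epochs, cv_folds = cv_folds)),
    class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cat(sprintf("<triage_model %s [%s]> %d features, classes %s\n", x$model,
              x$condition %||% "?", length(x$features),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict triage classes
#'
#' @param object A `triage_model`.
#' @param newdata A `feature_table`, data frame or matrix holding the
#'   model's features (extra columns are ignored, missing columns are an
#'   error); rows must be complete.
#' @param ... Unused.
#' @return Integer vector of predicted classes (empty input gives an empty
#'   vector).
#' @export
predict.triage_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else
    as.data.frame(newdata)
  missing_cols <- setdiff(object$features, names(x))
  if (length(missing_cols)) {
    stop("newdata lacks model features: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(x[, object$features, drop = FALSE])
  if (nrow(x) == 0L) return(integer(0))
  if (anyNA(x)) {
    stop("newdata contains missing values; fill or drop them first",
         call. = FALSE)
  }
  out <- switch(object$model,
    knn = withr::with_seed(object$seed, {
      as.integer(as.character(class::knn(
        object$fit$train, x,
        factor(object$fit$y, levels = object$classes), k = object$fit$k)))
    }),
    svm = as.integer(as.character(stats::predict(object$fit, x))),
    mlp = object$classes[max.col(mlp_forward(object$fit, x),
                                 ties.method = "first")])
  as.integer(out)
}

# ---- minimal MLP: 1 hidden ReLU layer, softmax + cross-entropy, Adam ----

mlp_fit <- function(x, y, hidden, epochs, batch, lr, patience, val_frac,
                    seed) {
  classes <- sort(unique(y))
  n <- nrow(x); p <- ncol(x); K <- length(classes)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), match(y, classes))] <- 1
  withr::with_seed(as.integer(seed), {
    n_val <- max(1L, floor(n * val_frac))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) < 2L) { tr_idx <- seq_len(n); val_idx <- seq_len(n) }
    W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(stats::rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K)
    b2 <- rep(0, K)
    adam <- list()
    for (nm in c("W1", "b1", "W2", "b2")) {
      adam[[nm]] <- list(m = 0, v = 0)
    }
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    stale <- 0L
    history <- numeric(0)
    for (epoch in seq_len(epochs)) {
      perm <- sample(tr_idx)
      starts <- seq(1L, length(perm), by = batch)
      for (s in starts) {
        bi <- perm[s:min(s + batch - 1L, length(perm))]
        xb <- x[bi, , drop = FALSE]; yb <- Y[bi, , drop = FALSE]
        nb <- nrow(xb)
        h_pre <- sweep(xb %*% W1, 2, b1, "+")
        h <- pmax(h_pre, 0)
        logits <- sweep(h %*% W2, 2, b2, "+")
        pr <- softmax_rows(logits)
        dlogits <- (pr - yb) / nb
        gW2 <- crossprod(h, dlogits); gb2 <- colSums(dlogits)
        dh <- dlogits %*% t(W2) * (h_pre > 0)
        gW1 <- crossprod(xb, dh); gb1 <- colSums(dh)
        t_step <- t_step + 1
        upd <- function(param, grad, state) {
          state$m <- beta1 * state$m + (1 - beta1) * grad
          state$v <- beta2 * state$v + (1 - beta2) * grad^2
          mhat <- state$m / (1 - beta1^t_step)
          vhat <- state$v / (1 - beta2^t_step)
          list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
        }
        r <- upd(W1, gW1, adam$W1); W1 <- r$param; adam$W1 <- r$state
        r <- upd(b1, gb1, adam$b1); b1 <- r$param; adam$b1 <- r$state
        r <- upd(W2, gW2, adam$W2); W2 <- r$param; adam$W2 <- r$state
        r <- upd(b2, gb2, adam$b2); b2 <- r$param; adam$b2 <- r$state
      }
      fitpar <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = classes)
      val_pr <- mlp_forward(fitpar, x[val_idx, , drop = FALSE])
      val_loss <- -mean(log(pmax(
        val_pr[cbind(seq_along(val_idx), match(y[val_idx], classes))],
        1e-12)))
      history <- c(history, val_loss)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  })
  list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
       classes = classes, val_history = history)
}

mlp_forward <- function(fit, x) {
  h <- pmax(sweep(x %*% fit$W1, 2, fit$b1, "+"), 0)
  softmax_rows(sweep(h %*% fit$W2, 2, fit$b2, "+"))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Cross-validated macro-F1 of a model family on a training table
#'
#' Reporting mode that scores a model family by k-fold cross-validation on
#' the training rows instead of the fixed evaluation split: each fold is
#' held out once, the model is trained on the rest, and the fold's macro F1
#' is returned.
#'
#' @param ft A complete-case `feature_table`.
#' @param model Model family, as in [train_triage_model()].
#' @param cv_folds Number of folds (default 4).
#' @param seed Integer seed (fold assignment and training).
#' @param ... Passed to [train_triage_model()].
#' @return Numeric vector of per-fold macro-F1 values.
#' @export
cv_fold_scores <- function(ft, model, cv_folds = 4, seed = 1L, ...) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$x)
  folds <- withr::with_seed(as.integer(seed),
                            sample(rep_len(seq_len(cv_folds), n)))
  vapply(seq_len(cv_folds), function(fd) {
    tr <- ft_rows(ft, folds != fd)
    te <- ft_rows(ft, folds == fd)
    fit <- train_triage_model(tr, model = model,
                              seed = as.integer(seed) + fd, ...)
    pred <- predict(fit, te)
    cm <- confusion(te$labels, pred, classes = sort(unique(ft$labels)))
    f1_from_confusion(cm)$macro_f1
  }, numeric(1))
}
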