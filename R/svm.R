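#' RBF-SVM hyperparameters
#'
#' @param C Penalty factor (> 0): the cost of margin violations.
#' @param g RBF kernel width parameter (> 0): the kernel is
#'   `exp(-g * ||x - x'||^2)`, i.e. `g = 1/sigma^2`.
#' @return An `svm_spec` object.
#' @export
svm_spec <- function(C = 1, g = 1) {
  stopifnot(C > 0, g > 0)
  structure(list(C = C, g = g), class = "svm_spec")
}

#' Train a binary soft-margin RBF SVM
#'
#' Solves the dual problem (box constraint `0 <= alpha_i <= C`, equality
#' `sum alpha_i y_i = 0`) by sequential minimal optimization.  Features are
#' standardized with the training-set mean and SD before kernel evaluation,
#' since reaction time (seconds) and ratio indices live on different scales.
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Labels in `{-1, +1}` (or coercible logical), both classes
#'   present.
#' @param spec An [svm_spec()].
#' @param standardize Standardize columns before the kernel (default TRUE).
#' @param tol KKT violation tolerance for the solver.
#' @return A `binary_svm`: the training inputs (standardized), labels, dual
#'   coefficients `alpha`, threshold `b`, spec, and standardization stats.
#' @export
train_binary_svm <- function(X, y, spec = svm_spec(), standardize = TRUE,
                             tol = 1e-3) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (!all(is.finite(X))) stop("non-finite feature values")
  if (standardize) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    sdev[sdev == 0] <- 1
  } else {
    mu <- rep(0, ncol(X)); sdev <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  K <- rbf_kernel(Xs, Xs, spec$g)
  fit <- smo_train(K, y, spec$C, tol = tol)
  structure(list(X = Xs, y = y, alpha = fit$alpha, b = fit$b,
                 spec = spec, center = mu, scale = sdev,
                 converged = fit$converged),
            class = "binary_svm")
}

#' @export
predict.binary_svm <- function(object, newdata, decision = FALSE, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != ncol(object$X)) stop("feature count mismatch")
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  f <- drop(rbf_kernel(Xs, object$X, object$spec$g) %*%
              (object$alpha * object$y)) + object$b
  if (decision) f else ifelse(f >= 0, 1, -1)
}

#' Stratified K-fold cross-validated accuracy
#'
#' Folds are stratified by class; the reported value is the mean of the
#' per-fold accuracies, the usual performance index for K-CV.  If some class
#' has fewer members than folds, assignment falls back to unstratified with
#' a warning.  Deterministic given `seed`.
#'
#' @param X Feature matrix; `y` labels in `{-1, +1}`.
#' @param spec An [svm_spec()].
#' @param K Number of folds (>= 2).
#' @param seed Integer seed controlling the fold assignment.
#' @return Mean fold accuracy in `[0, 1]`.
#' @export
kfold_cv_accuracy <- function(X, y, spec = svm_spec(), K = 10, seed = 1L) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  n <- nrow(X)
  stopifnot(K >= 2, K <= n, length(y) == n)
  set.seed(seed)
  folds <- integer(n)
  if (min(table(y)) >= K) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep(seq_len(K), length.out = length(idx))
    }
  } else {
    warning("class smaller than K: unstratified folds")
    folds[sample(n)] <- rep(seq_len(K), length.out = n)
  }
  accs <- vapply(seq_len(K), function(k) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) {
      pred <- rep(unique(y[tr]), sum(!tr))
    } else {
      m <- train_binary_svm(X[tr, , drop = FALSE], y[tr], spec)
      pred <- predict(m, X[!tr, , drop = FALSE])
    }
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}
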