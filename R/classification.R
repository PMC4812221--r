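#' Radial basis function kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`, the similarity the multiclass SVM
#' uses; it equips the classifier with an implicit nonlinear feature map.
#' Values lie in (0, 1], with 1 exactly when `x == y`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Kernel width parameter, strictly positive.
#' @return The kernel value, a scalar in (0, 1].
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  exp(-gamma * sum((x - y)^2))
}

#' Size of the one-vs-one ensemble
#'
#' A one-vs-one multiclass SVM trains one binary classifier per unordered
#' class pair: `M(M-1)/2` of them for M classes; predictions are combined
#' by majority voting.
#'
#' @param M Number of classes, at least 2.
#' @return Integer `M(M-1)/2`.
#' @examples
#' num_binary_classifiers(18)  # 153
#' @export
num_binary_classifiers <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop("M must be an integer >= 2", call. = FALSE)
  (M * (M - 1L)) %/% 2L
}

#' Hyperparameter grid for SVM model selection
#'
#' The soft-margin penalty C and kernel width gamma are chosen by
#' cross-validated grid search on the training split. The default grid is
#' the conventional coarse log2 lattice for RBF SVMs: C over 2^-5..2^15 and
#' gamma over 2^-15..2^3, both in steps of 2 in the exponent, with 5-fold
#' stratified CV. Ties in CV accuracy are broken toward smaller C, then
#' smaller gamma (preferring the smoother model).
#'
#' @param C_values Positive penalty candidates.
#' @param gamma_values Positive kernel width candidates.
#' @param cv_folds Number of stratified CV folds (>= 2).
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(C_values = 2^seq(-5, 15, by = 2),
                       gamma_values = 2^seq(-15, 3, by = 2),
                       cv_folds = 5L) {
  stopifnot(length(C_values) >= 1L, all(C_values > 0),
            length(gamma_values) >= 1L, all(gamma_values > 0),
            cv_folds >= 2L)
  structure(list(C_values = sort(as.numeric(C_values)),
                 gamma_values = sort(as.numeric(gamma_values)),
                 cv_folds = as.integer(cv_folds)),
            class = "hyper_grid")
}

# per-dimension standardization fitted on training data only;
# constant dimensions get scale 1 so they map to 0 rather than NaN
.fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

.apply_scaler <- function(scaler, x) {
  out <- scale(x, center = scaler$center, scale = scaler$scale)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# seeded stratified fold assignment; every class is spread over the folds
.stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train the one-vs-one multiclass SVM
#'
#' Fits the activity classifier: per-dimension standardization (fitted on
#' the training data only), cross-validated grid search for (C, gamma), and
#' a final one-vs-one soft-margin SVM with RBF kernel on the full training
#' set. The underlying binary problems and voting are handled by LIBSVM
#' (via \pkg{e1071}); voting ties are resolved by LIBSVM's aggregate
#' decision-value convention. The whole procedure is deterministic given
#' `seed`.
#'
#' @param x Numeric matrix of activity feature vectors (rows = sequences),
#'   or a list of `activity_vector` objects.
#' @param labels Character/factor vector of activity labels, one per row;
#'   at least two distinct classes are required.
#' @param grid A [hyper_grid()]; a 1x1 grid skips the search.
#' @param seed Integer seed controlling the CV fold assignment.
#' @param scale_features Standardize dimensions before the kernel
#'   (recommended for RBF; exposed so unscaled runs remain possible).
#' @return An object of class `trained_classifier` with elements
#'   `class_labels`, `C`, `gamma`, `cv_accuracy`, `scaler`, `n_binary`,
#'   and the fitted `model`.
#' @export
train_classifier <- function(x, labels, grid = hyper_grid(), seed = 1L,
                             scale_features = TRUE) {
  if (is.list(x) && !is.matrix(x)) x <- stack_activity_vectors(x)
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels))
    stop("length of labels must match rows of x", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("training requires at least two distinct classes", call. = FALSE)
  stopifnot(inherits(grid, "hyper_grid"))

  scaler <- if (scale_features) .fit_scaler(x) else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- .apply_scaler(scaler, x)
  y <- factor(labels, levels = classes)

  n_grid <- length(grid$C_values) * length(grid$gamma_values)
  if (n_grid == 1L) {
    best <- list(C = grid$C_values, gamma = grid$gamma_values, acc = NA_real_)
  } else {
    k <- max(2L, min(grid$cv_folds, min(table(y))))
    fold <- .stratified_folds(labels, k, seed)
    best <- list(C = NA_real_, gamma = NA_real_, acc = -Inf)
    for (C in grid$C_values) {
      for (g in grid$gamma_values) {
        correct <- 0L
        for (f in seq_len(k)) {
          tr <- fold != f
          if (length(unique(labels[tr])) < 2L) next
          fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], type = "C-classification",
                            kernel = "radial", cost = C, gamma = g, scale = FALSE)
          pred <- stats::predict(fit, xs[!tr, , drop = FALSE])
          correct <- correct + sum(as.character(pred) == labels[!tr])
        }
        acc <- correct / length(labels)
        if (acc > best$acc + 1e-12) best <- list(C = C, gamma = g, acc = acc)
      }
    }
  }

  model <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                      cost = best$C, gamma = best$gamma, scale = FALSE)
  structure(list(class_labels = classes, C = best$C, gamma = best$gamma,
                 cv_accuracy = best$acc, scaler = scaler,
                 n_binary = num_binary_classifiers(length(classes)),
                 n_features = ncol(x), model = model),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier: %d classes, %d one-vs-one SVMs, C=%g, gamma=%g>\n",
              length(x$class_labels), x$n_binary, x$C, x$gamma))
  invisible(x)
}

#' Predict activity labels
#'
#' Applies the training-time standardization to new activity vectors and
#' returns the majority-vote label of the one-vs-one ensemble. Predictions
#' are always drawn from the training classes: a genuinely novel activity
#' is still mapped to the most similar known one (closed-world behaviour, a
#' documented limitation of the voting SVM).
#'
#' @param object A [train_classifier()] result.
#' @param newdata Numeric matrix/vector of activity features, or a list of
#'   `activity_vector` objects; width must match training.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata))
    newdata <- stack_activity_vectors(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature length ", ncol(newdata), " does not match training length ",
         object$n_features, call. = FALSE)
  xs <- .apply_scaler(object$scaler, newdata)
  as.character(stats::predict(object$model, xs))
}
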