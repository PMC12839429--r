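# Multi-class RBF-kernel C-SVM, one-vs-rest, on top of the SMO dual solver in
# src/svm_smo.cpp. One-vs-rest (rather than pairwise voting) keeps the
# decision scores and the predicted labels coherent: prediction is the argmax
# of the same score matrix the one-vs-rest AUC is computed from.

svm_binary_fit <- function(K, ybin, cost) {
  fit <- .svm_smo_cpp(K, as.numeric(ybin), cost)
  list(coef = as.numeric(fit$coef), b = fit$b)
}

#' Fit a one-vs-rest RBF-kernel SVM
#'
#' Trains one binary C-SVC per class (class c vs. rest) on a shared training
#' kernel. Fixed hyperparameters `cost = 100`, `gamma = 0.01` are the
#' pipeline defaults used both inside the wrapper fitness and for the final
#' classifier.
#'
#' @param X numeric training matrix.
#' @param y integer labels `0..C-1` (at least two classes).
#' @param cost soft-margin penalty C.
#' @param gamma RBF kernel width.
#' @param classes optional integer vector of all class ids (defaults to the
#'   classes present in `y`).
#' @return object of class `hfsof_svm`.
#' @export
svm_rbf_fit <- function(X, y, cost = 100, gamma = 0.01, classes = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(unique(y)) < 2L) stop("need at least two classes in training labels")
  K <- rbf_kernel(X, X, gamma)
  models <- lapply(classes, function(c) {
    svm_binary_fit(K, ifelse(y == c, 1, -1), cost)
  })
  structure(list(X = X, classes = classes, models = models,
                 cost = cost, gamma = gamma),
            class = "hfsof_svm")
}

#' Decision scores and predictions for a fitted SVM
#'
#' @param object an `hfsof_svm`.
#' @param newdata matrix of samples to score.
#' @param type `"class"` for predicted labels (argmax of the per-class
#'   decision scores, row by row) or `"scores"` for the N x C score matrix.
#' @param ... unused.
#' @return integer labels or a numeric score matrix with one column per class.
#' @export
predict.hfsof_svm <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Kn <- rbf_kernel(as.matrix(newdata), object$X, object$gamma)
  S <- vapply(object$models, function(m) as.numeric(Kn %*% m$coef + m$b),
              numeric(nrow(Kn)))
  S <- matrix(S, nrow = nrow(Kn))
  colnames(S) <- as.character(object$classes)
  if (type == "scores") return(S)
  object$classes[max.col(S, ties.method = "first")]
}

#' Fit the final classifier on the selected feature subset
#'
#' Thin wrapper of [svm_rbf_fit()] matching the end-of-pipeline contract.
#'
#' @param Z_train embedded training matrix restricted to the selected subset.
#' @param y_train training labels.
#' @param cost,gamma SVM hyperparameters (defaults 100 and 0.01).
#' @return an `hfsof_svm`.
#' @export
fit_final_svm <- function(Z_train, y_train, cost = 100, gamma = 0.01) {
  svm_rbf_fit(Z_train, y_train, cost = cost, gamma = gamma)
}
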