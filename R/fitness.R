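# Wrapper fitness: mean over fixed stratified K folds of the macro-F1 of an
# RBF-kernel SVM trained on the masked feature columns. The fold assignment
# is drawn once per fitness spec and reused for every evaluation; results are
# memoized by mask bits so the optimizers never pay twice for one subset.

#' Stratified k-fold assignment
#'
#' Per class, indices are shuffled (seeded) and dealt round-robin into `k`
#' folds, so every fold contains every class. Errors if any class has fewer
#' than `k` samples.
#'
#' @param y integer labels.
#' @param k fold count (default 3).
#' @param seed integer seed.
#' @param class_names optional names used in error messages.
#' @return integer vector of fold ids `1..k`, one per sample.
#' @export
make_stratified_folds <- function(y, k = 3L, seed = 1L, class_names = NULL) {
  counts <- table(y)
  if (any(counts < k)) {
    bad <- as.integer(names(counts))[counts < k]
    lab <- if (!is.null(class_names)) class_names[bad + 1L] else as.character(bad)
    stop("cannot build ", k, "-fold stratified folds; classes with < ", k,
         " samples: ", paste(lab, collapse = ", "))
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (c in sort(unique(y))) {
      idx <- sample(which(y == c))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Build a wrapper fitness specification
#'
#' Captures everything a fitness evaluation needs: the embedded training
#' features restricted to the MSDLDA survivors `S0`, the labels, the fixed
#' SVM hyperparameters, and a stratified fold assignment drawn once.
#'
#' @param Z numeric matrix (training rows x |S0| candidate features).
#' @param y integer training labels.
#' @param cost,gamma SVM hyperparameters (defaults 100 and 0.01).
#' @param k_fold cross-validation folds (default 3).
#' @param seed seed for the fold assignment.
#' @param cache enable mask-keyed memoization (default TRUE).
#' @return object of class `hfsof_fitness_spec`.
#' @export
fitness_spec <- function(Z, y, cost = 100, gamma = 0.01, k_fold = 3L,
                         seed = 1L, cache = TRUE) {
  Z <- as.matrix(Z)
  y <- as.integer(y)
  folds <- make_stratified_folds(y, k_fold, seed)
  structure(list(Z = Z, y = y, cost = cost, gamma = gamma, k_fold = k_fold,
                 folds = folds, classes = sort(unique(y)),
                 cache = if (cache) new.env(parent = emptyenv()) else NULL,
                 n_eval = new.env(parent = emptyenv())),
            class = "hfsof_fitness_spec")
}

#' Evaluate a feature mask
#'
#' Mean over the spec's fixed stratified folds of the macro-F1 of an RBF SVM
#' trained on the masked columns. Memoized: re-evaluating the same mask
#' returns the identical cached value.
#'
#' @param mask binary (0/1) vector of length `ncol(spec$Z)` with >= 2 ones.
#' @param spec an `hfsof_fitness_spec`.
#' @return fitness in \[0, 1\].
#' @export
evaluate_fitness <- function(mask, spec) {
  mask <- as.integer(mask)
  if (sum(mask) < 2L) stop("mask must select at least 2 features")
  key <- paste(mask, collapse = "")
  if (!is.null(spec$cache) && !is.null(spec$cache[[key]])) {
    spec$n_eval$hits <- (spec$n_eval$hits %||% 0L) + 1L
    return(spec$cache[[key]])
  }
  cols <- which(mask == 1L)
  C <- length(spec$classes)
  f1s <- vapply(seq_len(spec$k_fold), function(f) {
    tr <- spec$folds != f
    fit <- svm_rbf_fit(spec$Z[tr, cols, drop = FALSE], spec$y[tr],
                       cost = spec$cost, gamma = spec$gamma,
                       classes = spec$classes)
    pred <- predict(fit, spec$Z[!tr, cols, drop = FALSE])
    macro_f1(spec$y[!tr], pred, C)
  }, numeric(1))
  val <- mean(f1s)
  spec$n_eval$count <- (spec$n_eval$count %||% 0L) + 1L
  if (!is.null(spec$cache)) spec$cache[[key]] <- val
  val
}
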