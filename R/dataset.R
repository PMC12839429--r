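#' Construct a feature dataset
#'
#' The core container used throughout the pipeline: a numeric feature matrix
#' `X` (samples in rows), integer class labels `y` in `0..C-1`, and the
#' feature/class name bookkeeping needed for readable reports.
#'
#' @param X numeric matrix, N x M, no missing values.
#' @param y integer vector of length N with labels in `0..C-1`.
#' @param feature_names optional character vector of length M.
#' @param class_names optional character vector of length C.
#' @return an object of class `hfsof_dataset` with elements `X`, `y`,
#'   `feature_names`, `class_names`.
#' @export
hfsof_dataset <- function(X, y, feature_names = NULL, class_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing or non-finite values")
  if (any(y < 0L)) stop("labels must be non-negative integers")
  C <- max(y) + 1L
  if (C < 2L) stop("need at least 2 classes")
  if (nrow(X) < C) stop("need at least one sample per class (N >= C)")
  if (!all(0:(C - 1L) %in% y)) stop("every class in 0..C-1 must have >= 1 sample")
  if (is.null(feature_names)) {
    feature_names <- colnames(X) %||% sprintf("f%04d", seq_len(ncol(X)))
  }
  if (is.null(class_names)) class_names <- sprintf("class_%d", 0:(C - 1L))
  if (length(feature_names) != ncol(X)) stop("feature_names length mismatch")
  if (length(class_names) != C) stop("class_names length mismatch")
  colnames(X) <- feature_names
  structure(list(X = X, y = y, feature_names = as.character(feature_names),
                 class_names = as.character(class_names)),
            class = "hfsof_dataset")
}

#' @export
print.hfsof_dataset <- function(x, ...) {
  cat(sprintf("<hfsof_dataset> %d samples x %d features, %d classes\n",
              nrow(x$X), ncol(x$X), length(x$class_names)))
  tab <- table(factor(x$y, levels = seq_along(x$class_names) - 1L))
  names(tab) <- x$class_names
  print(tab)
  invisible(x)
}

#' Read a delimited feature table
#'
#' Expects a header, one column named `label` (integer class ids or class-name
#' strings), all remaining columns numeric features.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return an [hfsof_dataset].
#' @export
read_feature_table <- function(path, sep = ",") {
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature table must contain a 'label' column")
  lab <- df[["label"]]
  df[["label"]] <- NULL
  if (is.character(lab) || is.factor(lab)) {
    f <- factor(lab)
    y <- as.integer(f) - 1L
    class_names <- levels(f)
  } else {
    y <- as.integer(lab)
    class_names <- NULL
  }
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("all non-label columns must be numeric")
  hfsof_dataset(X, y, feature_names = names(df), class_names = class_names)
}

#' Write a dataset as a delimited feature table
#'
#' @param ds an [hfsof_dataset].
#' @param path output path.
#' @param sep field separator.
#' @export
write_feature_table <- function(ds, path, sep = ",") {
  df <- as.data.frame(ds$X)
  df$label <- ds$y
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

subset_dataset <- function(ds, idx) {
  structure(list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx],
                 feature_names = ds$feature_names, class_names = ds$class_names),
            class = "hfsof_dataset")
}

#' Stratified train/test split
#'
#' Per-class allocation: `round(n_c * test_fraction)` samples of each class go
#' to the test partition (clamped so both partitions keep at least one sample
#' per class). Deterministic given `seed`.
#'
#' @param ds an [hfsof_dataset].
#' @param test_fraction fraction in (0, 1), default 0.3.
#' @param seed integer seed.
#' @return list with elements `train`, `test` ([hfsof_dataset]s) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(ds, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  counts <- table(ds$y)
  if (any(counts < 2L)) {
    bad <- ds$class_names[as.integer(names(counts))[counts < 2L] + 1L]
    stop("classes with a single sample cannot be split: ",
         paste(bad, collapse = ", "))
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(sort(unique(ds$y)), function(c) {
      idx <- which(ds$y == c)
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(ds$y), test_idx)
  list(train = subset_dataset(ds, train_idx),
       test = subset_dataset(ds, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Fit a per-feature standardizer (zero mean, unit variance)
#'
#' Uses the population standard deviation (divide by N). Constant columns get
#' their SD floored at `eps` so they standardize to exactly zero.
#'
#' @param train an [hfsof_dataset] (fit on training rows only; applying the
#'   same model to the test partition avoids leakage).
#' @param eps SD floor for constant columns.
#' @return object of class `hfsof_standardizer` with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(train, eps = 1e-12) {
  X <- train$X
  if (nrow(X) < 1L) stop("cannot fit a standardizer on an empty dataset")
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  s[s < eps] <- eps
  structure(list(mean = mu, sd = s, eps = eps), class = "hfsof_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param model an `hfsof_standardizer` from [fit_standardizer()].
#' @param ds an [hfsof_dataset] with matching feature count.
#' @return the standardized [hfsof_dataset].
#' @export
apply_standardizer <- function(model, ds) {
  if (ncol(ds$X) != length(model$mean)) stop("feature count mismatch")
  Xs <- sweep(sweep(ds$X, 2L, model$mean), 2L, model$sd, "/")
  out <- ds
  out$X <- Xs
  out
}
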