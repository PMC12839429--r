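#' RBF kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||a_i - b_j||^2)` for rows of `A` and `B`.
#'
#' @param A,B numeric matrices with the same column count.
#' @param gamma kernel width, > 0. The pipeline default is `1/d` where d is
#'   the (standardized) feature count.
#' @return an `nrow(A) x nrow(B)` kernel matrix with entries in (0, 1].
#' @export
rbf_kernel <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must share column count")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (any(!is.finite(A)) || any(!is.finite(B))) stop("non-finite input")
  .rbf_kernel_cpp(A, B, gamma)
}

#' Fit kernel PCA with an RBF kernel
#'
#' Builds the training kernel `K`, double-centers it (`K_c = H K H` with
#' `H = I - 11'/N`), eigendecomposes, keeps only strictly positive eigenvalues
#' (tolerance `1e-10 * lambda_max`), and retains
#' `p = min(p_requested, n_positive)` components. Centering statistics are
#' stored for out-of-sample projection. Eigenvector columns are sign-fixed so
#' their largest-magnitude entry is positive.
#'
#' @param X_train standardized training matrix (N x d).
#' @param p_requested number of components to retain (default 1000; silently
#'   capped at the positive-eigenvalue count, which is < N).
#' @param gamma kernel width; default `1/ncol(X_train)`. Ignored for the
#'   linear kernel.
#' @param kernel `"rbf"` (the method's kernel) or `"linear"` (`K = XX'`),
#'   the latter mainly as an oracle hook: linear kernel PCA scores equal
#'   classical PCA scores up to column sign.
#' @return object of class `hfsof_kpca` with `X_train`, `gamma`, `lambda`,
#'   `U`, `p`, `k_colmeans`, `k_grandmean`, and training scores `Z`
#'   (`Z = K_c U Lambda^{-1/2}`, so `Z'Z = Lambda`).
#' @export
fit_kpca <- function(X_train, p_requested = 1000L, gamma = NULL,
                     kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < 2L) stop("need at least 2 training samples")
  if (p_requested < 1L) stop("p_requested must be >= 1")
  if (is.null(gamma)) gamma <- 1 / ncol(X_train)
  K <- if (kernel == "linear") tcrossprod(X_train) else
    rbf_kernel(X_train, X_train, gamma)
  cm <- colMeans(K)
  gm <- mean(K)
  Kc <- K - matrix(rowMeans(K), n, n) - matrix(cm, n, n, byrow = TRUE) + gm
  eig <- eigen(Kc, symmetric = TRUE)
  pos <- eig$values > 1e-10 * max(eig$values, 0)
  if (!any(pos)) stop("degenerate kernel: no positive eigenvalues")
  lambda <- eig$values[pos]
  U <- eig$vectors[, pos, drop = FALSE]
  p <- min(as.integer(p_requested), length(lambda))
  lambda <- lambda[seq_len(p)]
  U <- U[, seq_len(p), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(p)) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) U[, j] <- -U[, j]
  }
  Z <- Kc %*% U %*% diag(1 / sqrt(lambda), p)
  colnames(Z) <- sprintf("kpc_%04d", seq_len(p))
  structure(list(X_train = X_train, kernel = kernel, gamma = gamma,
                 lambda = lambda, U = U, p = p, k_colmeans = cm,
                 k_grandmean = gm, Z = Z),
            class = "hfsof_kpca")
}

#' Project new samples onto fitted kernel principal components
#'
#' Computes the cross-kernel against the training rows, double-centers it with
#' the stored training statistics, and projects:
#' `Z_new = K_c_new U Lambda^{-1/2}`. Projecting the training matrix itself
#' reproduces the stored training scores.
#'
#' @param model an `hfsof_kpca` from [fit_kpca()].
#' @param X_new m x d matrix (d must match training).
#' @return m x p score matrix.
#' @export
transform_kpca <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$X_train)) stop("feature dimension mismatch")
  m <- nrow(X_new)
  if (m == 0L) {
    Z <- matrix(numeric(0), 0L, model$p)
    colnames(Z) <- sprintf("kpc_%04d", seq_len(model$p))
    return(Z)
  }
  n <- nrow(model$X_train)
  Kn <- if (identical(model$kernel, "linear")) tcrossprod(X_new, model$X_train)
    else rbf_kernel(X_new, model$X_train, model$gamma)
  Kc <- Kn - matrix(rowMeans(Kn), m, n) -
    matrix(model$k_colmeans, m, n, byrow = TRUE) + model$k_grandmean
  Z <- Kc %*% model$U %*% diag(1 / sqrt(model$lambda), model$p)
  colnames(Z) <- sprintf("kpc_%04d", seq_len(model$p))
  Z
}
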