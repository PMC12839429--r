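test_that("rbf_kernel evaluates the Gaussian kernel", {
  expect_equal(rbf_kernel(matrix(c(0, 0), 1), matrix(c(0, 0), 1), 1)[1, 1], 1)
  expect_equal(rbf_kernel(matrix(c(0, 0), 1), matrix(c(1, 0), 1), 1)[1, 1],
               exp(-1), tolerance = 1e-12)
  # gamma -> 0+ limit
  K <- rbf_kernel(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2), 1e-12)
  expect_true(all(abs(K - 1) < 1e-9))
  expect_error(rbf_kernel(matrix(NaN, 1, 1), matrix(1, 1, 1), 1), "non-finite")
  expect_error(rbf_kernel(matrix(1, 1, 2), matrix(1, 1, 3), 1), "column count")
})

test_that("fit_kpca satisfies the spectral identity and centering on random data", {
  withr::with_seed(50, X <- matrix(rnorm(500), 50, 10))
  km <- fit_kpca(X, p_requested = 1000)
  expect_lte(km$p, 49)  # rank bound of the centered kernel
  # Z'Z = diag(lambda), relative error 1e-6
  err <- max(abs(crossprod(km$Z) - diag(km$lambda))) / max(km$lambda)
  expect_lt(err, 1e-6)
  expect_true(all(diff(km$lambda) <= 1e-12))
  expect_true(all(km$lambda > 0))
  # U orthonormal
  expect_lt(max(abs(crossprod(km$U) - diag(km$p))), 1e-8)
  # centered kernel annihilates constants: reconstruct and check row sums
  K <- rbf_kernel(X, X, km$gamma)
  Kc <- K - matrix(rowMeans(K), 50, 50) -
    matrix(colMeans(K), 50, 50, byrow = TRUE) + mean(K)
  expect_lt(max(abs(rowSums(Kc))), 1e-8)
  expect_lt(max(abs(colSums(Kc))), 1e-8)
})

test_that("out-of-sample projection reproduces in-sample scores", {
  withr::with_seed(51, X <- matrix(rnorm(300), 30, 10))
  km <- fit_kpca(X, 10)
  Z <- transform_kpca(km, X)
  expect_lt(max(abs(Z - km$Z)), 1e-8)
  # a single training point reproduces its row
  z1 <- transform_kpca(km, X[7, , drop = FALSE])
  expect_lt(max(abs(z1 - km$Z[7, ])), 1e-8)
  # empty input
  z0 <- transform_kpca(km, X[0, , drop = FALSE])
  expect_equal(dim(z0), c(0L, km$p))
  expect_error(transform_kpca(km, X[, 1:3]), "mismatch")
})

test_that("sample permutation permutes scores identically", {
  withr::with_seed(52, X <- matrix(rnorm(200), 20, 10))
  perm <- sample(20)
  km <- fit_kpca(X, 5)
  kmp <- fit_kpca(X[perm, ], 5)
  expect_equal(abs(kmp$Z), abs(km$Z[perm, ]), tolerance = 1e-6)
})

test_that("linear-kernel variant matches classical PCA scores up to column sign", {
  withr::with_seed(53, X <- matrix(rnorm(240), 24, 10))
  km <- fit_kpca(X, 5, kernel = "linear")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:5) {
    agree <- min(max(abs(km$Z[, j] - pc$x[, j])),
                 max(abs(km$Z[, j] + pc$x[, j])))
    expect_lt(agree, 1e-6)
  }
})

test_that("degenerate kernels are refused", {
  X <- matrix(1, 5, 3)  # identical rows -> centered kernel is zero
  expect_error(fit_kpca(X, 2), "degenerate")
})
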