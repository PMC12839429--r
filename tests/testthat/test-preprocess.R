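test_that("dataset constructor enforces its invariants", {
  X <- matrix(rnorm(20), 10, 2)
  ds <- hfsof_dataset(X, rep(0:1, 5))
  expect_s3_class(ds, "hfsof_dataset")
  expect_equal(ds$class_names, c("class_0", "class_1"))
  expect_error(hfsof_dataset(X, rep(0L, 10)), "2 classes")
  expect_error(hfsof_dataset(X, c(rep(0:1, 4), 3L, 3L)), "every class")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(hfsof_dataset(Xna, rep(0:1, 5)), "missing")
})

test_that("feature table round-trips through delimited text", {
  ds <- hfsof_dataset(matrix(round(rnorm(24), 6), 8, 3), rep(0:1, 4),
                      feature_names = c("u", "v", "w"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds, path)
  back <- read_feature_table(path)
  expect_equal(back$X, ds$X, ignore_attr = TRUE)
  expect_equal(back$y, ds$y)
  expect_equal(back$feature_names, ds$feature_names)
  expect_error(read_feature_table(withr::local_tempfile(lines = "a,b\n1,2")),
               "label")
})

test_that("stratified split allocates round(n_c * fraction) per class and partitions", {
  y <- c(rep(0L, 10), rep(1L, 20))
  ds <- hfsof_dataset(matrix(rnorm(60), 30, 2), y)
  sp <- stratified_split(ds, 0.3, seed = 5)
  expect_equal(as.integer(table(sp$test$y)), c(3L, 6L))
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:30)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # determinism
  sp2 <- stratified_split(ds, 0.3, seed = 5)
  expect_identical(sp$test_idx, sp2$test_idx)
  # imbalance profile preserved within +/- 1
  yb <- c(rep(0L, 238), rep(1L, 3464))
  big <- hfsof_dataset(matrix(0, 3702, 1) + rnorm(3702), yb)
  spb <- stratified_split(big, 0.3, seed = 1)
  counts <- as.integer(table(spb$test$y))
  expect_true(all(abs(counts - round(c(238, 3464) * 0.3)) <= 1))
  # single-sample class errors with the class named
  y1 <- c(0L, 0L, 1L)
  ds1 <- hfsof_dataset(matrix(rnorm(6), 3, 2), y1, class_names = c("big", "lone"))
  expect_error(stratified_split(ds1, 0.3), "lone")
})

test_that("standardizer uses the population SD convention and guards constants", {
  tr <- hfsof_dataset(cbind(c(1, 3), c(5, 5)), c(0L, 1L))
  std <- fit_standardizer(tr)
  expect_equal(unname(std$mean), c(2, 5))
  expect_equal(unname(std$sd[1]), 1)  # population SD of {1,3}
  out <- apply_standardizer(std, tr)
  expect_equal(unname(out$X[, 1]), c(-1, 1))
  expect_equal(unname(out$X[, 2]), c(0, 0))  # constant column -> 0 via floor
})

test_that("standardize-then-apply on training data recenters and rescales", {
  withr::with_seed(7, {
    ds <- hfsof_dataset(matrix(rnorm(200, 5, 3), 20, 10), rep(0:1, 10))
  })
  std <- fit_standardizer(ds)
  out <- apply_standardizer(std, ds)
  expect_lt(max(abs(colMeans(out$X))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(sweep(out$X, 2, colMeans(out$X))^2)) - 1)),
            1e-10)
})
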