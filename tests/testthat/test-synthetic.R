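test_that("phantom generation honors counts, range, and determinism", {
  spec <- phantom_spec(counts = rep(10L, 6), size = c(32L, 32L), seed = 3)
  raw <- generate_phantoms(spec)
  expect_length(raw$images, 60)
  expect_equal(sort(unique(raw$labels)), 0:5)
  expect_true(all(vapply(raw$images, function(m) all(m >= 0 & m <= 1), logical(1))))
  expect_true(all(vapply(raw$images, function(m) all(dim(m) == 32L), logical(1))))
  raw2 <- generate_phantoms(spec)
  expect_identical(raw$images, raw2$images)
})

test_that("zero-contrast phantoms have class-indistinguishable expectations", {
  spec0 <- phantom_spec(counts = rep(25L, 3), n_class = 3, contrast = 0, seed = 4)
  raw <- generate_phantoms(spec0)
  means <- vapply(0:2, function(c) {
    mean(vapply(raw$images[raw$labels == c], mean, numeric(1)))
  }, numeric(1))
  expect_lt(diff(range(means)), 0.02)
})

test_that("default phantom supports mimic the scaled imbalance profile", {
  spec <- phantom_spec(scale = 0.1)
  expect_equal(spec$counts, as.integer(round(c(1183, 660, 238, 1392, 743, 3464) * 0.1)))
})

test_that("planted features: truth recorded, imbalance honored, null is null", {
  g <- generate_planted_features(n = 100, d = 20, k = 3, delta = 2,
                                 n_class = 4, proportions = c(4, 3, 2, 1),
                                 seed = 5)
  expect_equal(g$truth, 1:3)
  counts <- as.integer(table(g$dataset$y))
  expect_true(all(abs(counts - c(40, 30, 20, 10)) <= 1))
  expect_identical(g$dataset$X,
                   generate_planted_features(n = 100, d = 20, k = 3, delta = 2,
                                             n_class = 4,
                                             proportions = c(4, 3, 2, 1),
                                             seed = 5)$dataset$X)
  expect_error(generate_planted_features(d = 5, k = 5), "k must be < d")
})

test_that("planted columns dominate fused ranks at delta = 3 but not at 0", {
  g <- generate_planted_features(n = 300, d = 50, k = 5, delta = 3,
                                 n_class = 4, seed = 6)
  rt <- filter_rank_table(g$dataset$X, g$dataset$y)
  expect_setequal(order(rt$r_fused)[1:5], g$truth)
  g0 <- generate_planted_features(n = 300, d = 50, k = 5, delta = 0,
                                  n_class = 4, seed = 6)
  rt0 <- filter_rank_table(g0$dataset$X, g0$dataset$y)
  # at delta = 0 the "planted" columns are ordinary noise: their mean fused
  # rank sits near the middle of 1..50
  expect_gt(mean(rt0$r_fused[g0$truth]), 10)
})

test_that("phantom image sets round-trip through the directory layout", {
  spec <- phantom_spec(counts = rep(3L, 2), n_class = 2, size = c(16L, 16L),
                       seed = 7)
  raw <- generate_phantoms(spec)
  root <- withr::local_tempdir()
  write_image_dataset(raw, root)
  back <- load_image_dataset(root, image_size = c(16L, 16L))
  expect_equal(back$class_names, raw$class_names)
  expect_equal(back$labels, raw$labels)
  # 8-bit quantization bounds the absolute error at half a gray level
  expect_lt(max(abs(back$images[[1]] - raw$images[[1]])), 0.5 / 255 + 1e-9)
})
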