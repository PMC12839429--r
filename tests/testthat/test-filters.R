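test_that("equal-width discretizer bins, clamps, and handles constants", {
  m <- fit_discretizer(matrix(c(0, 1, 2, 3), 4, 1), B = 2)
  expect_equal(as.integer(discretize(m, matrix(c(0, 1, 2, 3), 4, 1))),
               c(0L, 0L, 1L, 1L))
  # out-of-range values clamp to boundary bins
  expect_equal(as.integer(discretize(m, matrix(c(-5, 99), 2, 1))), c(0L, 1L))
  mc <- fit_discretizer(matrix(5, 4, 1), B = 4)
  expect_equal(as.integer(discretize(mc, matrix(c(5, 7), 2, 1))), c(0L, 0L))
})

test_that("filter scores hit their closed-form oracles", {
  y <- rep(0:1, each = 10)
  D <- cbind(ident = y, const = rep(0L, 20))
  ig <- information_gain_scores(D, y)
  su <- symmetrical_uncertainty_scores(D, y)
  cs <- chi_square_scores(D, y)
  # deterministic relation, balanced classes: I(X;Y) = H(Y) = ln 2
  expect_equal(unname(ig["ident"]), log(2), tolerance = 1e-12)
  expect_equal(unname(su["ident"]), 1, tolerance = 1e-12)
  # [[10,0],[0,10]] table: all E = 5, chi2 = 4 * 25/5 = 20
  expect_equal(unname(cs["ident"]), 20, tolerance = 1e-12)
  # constant feature carries no information
  expect_equal(unname(ig["const"]), 0)
  expect_equal(unname(su["const"]), 0)
  expect_equal(unname(cs["const"]), 0)
})

test_that("score bounds and homogeneity hold on random contingency structure", {
  withr::with_seed(60, {
    y <- sample(0:2, 90, replace = TRUE)
    D <- matrix(sample(0:4, 90 * 5, replace = TRUE), 90, 5)
  })
  ig <- information_gain_scores(D, y)
  su <- symmetrical_uncertainty_scores(D, y)
  hy <- -sum(prop.table(table(y)) * log(prop.table(table(y))))
  expect_true(all(ig >= 0 & ig <= hy + 1e-12))
  expect_true(all(su >= 0 & su <= 1))
  # doubling all counts doubles chi-square
  cs1 <- chi_square_scores(D, y)
  cs2 <- chi_square_scores(rbind(D, D), c(y, y))
  expect_equal(cs2, 2 * cs1, tolerance = 1e-9)
  # monotone relabeling of bins leaves scores unchanged
  ig2 <- information_gain_scores(D * 10L + 3L, y)
  expect_equal(ig2, ig, tolerance = 1e-12)
})

test_that("ranking follows the average-tie convention and conserves rank sums", {
  expect_equal(rank_features(c(0.9, 0.1, 0.5)), c(1, 3, 2))
  expect_equal(rank_features(c(0.5, 0.5, 0.1)), c(1.5, 1.5, 3))
  expect_equal(rank_features(rep(2, 5)), rep(3, 5))
  withr::with_seed(61, s <- rnorm(40))
  expect_equal(sum(rank_features(s)), 40 * 41 / 2)
})

test_that("fusion operators implement elementwise median / mean", {
  expect_equal(median_fuse(3, 7, 4), 4)
  expect_equal(mean_fuse(3, 7, 4), 14 / 3)
  expect_equal(median_fuse(c(1, 2), c(1, 2), c(1, 2)), c(1, 2))
  # order invariance of the median
  expect_equal(median_fuse(c(5, 1), c(2, 9), c(3, 3)),
               median_fuse(c(3, 3), c(5, 1), c(2, 9)))
  expect_equal(median_fuse(1, 1, 10), 1)
  expect_equal(mean_fuse(1, 1, 10), 4)
  expect_error(median_fuse(1:2, 1:3, 1:3), "length")
})

test_that("candidate pool takes the m smallest fused ranks, ties by index", {
  expect_equal(select_candidate_pool(c(5, 1, 3, 2), 2), c(2L, 4L))
  expect_equal(select_candidate_pool(c(5, 1, 3, 2), 4), c(2L, 4L, 3L, 1L))
  expect_equal(select_candidate_pool(c(2, 1, 2), 2), c(2L, 1L))  # tie -> lower index
  expect_error(select_candidate_pool(c(1, 2), 3), "pool size")
})

test_that("a label-deterministic feature ranks first under every filter and fusion", {
  withr::with_seed(62, {
    y <- rep(0:2, each = 30)
    Z <- cbind(planted = y + rnorm(90, 0, 0.01), matrix(rnorm(90 * 9), 90, 9))
  })
  rt <- filter_rank_table(Z, y, B = 5)
  expect_equal(which.min(rt$r_ig), 1L)
  expect_equal(which.min(rt$r_cs), 1L)
  expect_equal(which.min(rt$r_su), 1L)
  expect_equal(which.min(rt$r_fused), 1L)
  # rank columns are permutations up to tie-averaging
  for (col in c("r_ig", "r_cs", "r_su")) {
    expect_equal(sum(rt[[col]]), 10 * 11 / 2)
  }
})

test_that("single-filter ablation modes bypass fusion exactly", {
  withr::with_seed(63, {
    y <- rep(0:1, 25)
    Z <- matrix(rnorm(50 * 6), 50, 6)
  })
  full <- filter_rank_table(Z, y, mode = "fusion_median")
  for (mode in c("ig_only", "cs_only", "su_only")) {
    rt <- filter_rank_table(Z, y, mode = mode)
    ref <- switch(mode, ig_only = full$r_ig, cs_only = full$r_cs,
                  su_only = full$r_su)
    expect_equal(rt$r_fused, ref)
  }
  mean_rt <- filter_rank_table(Z, y, mode = "fusion_mean")
  expect_equal(mean_rt$r_fused, mean_fuse(full$r_ig, full$r_cs, full$r_su))
})
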