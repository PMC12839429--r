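test_that("confusion matrix counts with rows = true classes", {
  cm <- confusion(c(0L, 0L, 1L), c(0L, 1L, 1L), 2)
  expect_equal(unclass(cm)[1, 2], 1L)
  expect_equal(sum(unclass(cm)), 3L)
  expect_equal(rowSums(unclass(cm)), c(2, 1), ignore_attr = TRUE)
  cmd <- confusion(0:2, 0:2, 3)
  expect_equal(unclass(cmd), diag(3L), ignore_attr = TRUE)
  expect_error(confusion(c(0L, 3L), c(0L, 0L), 2), "out of range")
})

test_that("per-class metrics match direct evaluation and the 0/0 convention", {
  pm <- per_class_metrics(matrix(c(8, 1, 2, 9), 2, 2))
  expect_equal(pm$precision[1], 8 / 9)
  expect_equal(pm$recall[1], 0.8)
  expect_equal(pm$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  # class never predicted: P = 0 by convention
  pm2 <- per_class_metrics(matrix(c(5, 3, 0, 0), 2, 2))
  expect_equal(pm2$precision[2], 0)
  expect_equal(pm2$recall[2], 0)
  expect_equal(pm2$f1[2], 0)
  # harmonic-mean bound
  withr::with_seed(90, {
    for (i in 1:20) {
      pm3 <- per_class_metrics(random_confusion(4))
      ok <- pm3$precision + pm3$recall > 0
      expect_true(all(pm3$f1[ok] >= pmin(pm3$precision, pm3$recall)[ok] - 1e-12))
      expect_true(all(pm3$f1[ok] <= pmax(pm3$precision, pm3$recall)[ok] + 1e-12))
    }
  })
})

test_that("macro and weighted aggregation match a naive loop oracle", {
  withr::with_seed(91, {
    v <- runif(6); n <- sample(10:500, 6)
  })
  agg <- aggregate_metrics(v, n)
  expect_equal(agg$macro, sum(v) / 6)
  expect_equal(agg$weighted, sum(v * n) / sum(n))
  expect_equal(aggregate_metrics(v, rep(7, 6))$macro,
               aggregate_metrics(v, rep(7, 6))$weighted)
})

test_that("one-vs-rest AUC matches the Mann-Whitney oracle and is rank-invariant", {
  withr::with_seed(92, {
    y <- sample(0:2, 40, replace = TRUE)
    S <- matrix(rnorm(120), 40, 3)
  })
  auc <- ovr_auc(y, S)
  # brute-force pairwise comparison oracle for class 0
  pos <- S[y == 0, 1]; neg <- S[y != 0, 1]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc$per_class[1], mean(cmp))
  # monotone transform invariance
  auc2 <- ovr_auc(y, exp(2 * S))
  expect_equal(auc2$per_class, auc$per_class, tolerance = 1e-12)
  # perfect ordering gives AUC 1
  Sp <- matrix(0, 40, 3); Sp[cbind(1:40, y + 1)] <- 1
  expect_equal(ovr_auc(y, Sp)$per_class, rep(1, 3))
  # absent class excluded with warning
  expect_warning(a3 <- ovr_auc(rep(c(0L, 1L), 10), matrix(rnorm(60), 20, 3)),
                 "absent")
  expect_true(is.na(a3$per_class[3]))
})

test_that("full report is internally consistent and serializes to JSON", {
  withr::with_seed(93, {
    y <- sample(0:2, 60, replace = TRUE)
    S <- matrix(rnorm(180), 60, 3) + 2 * sapply(0:2, function(c) y == c)
  })
  pred <- max.col(S) - 1L
  rep <- metrics_report(y, pred, S)
  expect_equal(rep$weighted$recall, rep$accuracy)
  expect_equal(rep$macro$recall, mean(rep$per_class$recall))
  js <- jsonlite::fromJSON(write_metrics_json(rep))
  expect_equal(js$accuracy, round(rep$accuracy, 4))
  expect_length(js$per_class$class, 3)
})
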