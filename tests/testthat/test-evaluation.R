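test_that("train/test split is a deterministic disjoint partition", {
  s <- split_train_test(10, 0.9, seed = 1)
  expect_length(s$train, 9); expect_length(s$test, 1)
  expect_setequal(c(s$train, s$test), 1:10)
  s2 <- split_train_test(10, 0.9, seed = 1)
  expect_identical(s, s2)
  expect_false(identical(split_train_test(10, 0.9, seed = 2)$train, s$train))
  expect_error(split_train_test(5, 0.05), "empty side")
})

test_that("k-fold assignments are disjoint, exhaustive, and near-equal", {
  for (case in list(c(20, 10), c(23, 10), c(7, 3), c(100, 7))) {
    n <- case[1]; k <- case[2]
    folds <- kfold(n, k, seed = 1)
    expect_length(folds, k)
    expect_setequal(unlist(folds), seq_len(n))
    expect_equal(sum(lengths(folds)), n)
    expect_lte(diff(range(lengths(folds))), 1)
  }
  expect_equal(lengths(kfold(20, 10, seed = 3)), rep(2L, 10))
  expect_error(kfold(5, 10), "exceeds")
})

test_that("stratified folds keep class balance within one sample", {
  labels <- rep(0:3, each = 25)
  folds <- kfold(100, 10, seed = 2, stratify_labels = labels)
  expect_setequal(unlist(folds), 1:100)
  per_fold <- sapply(folds, function(f) tabulate(labels[f] + 1L, 4))
  expect_lte(max(abs(per_fold - 25 / 10)), 1)
})

test_that("perfect predictions yield an identity-patterned matrix and unit metrics", {
  y <- rep(0:3, times = c(5, 7, 3, 5))
  r <- evaluation_metrics(confusion(y, y))
  expect_equal(diag(r$confusion), c(`0` = 5, `1` = 7, `2` = 3, `3` = 5))
  expect_true(all(r$confusion[row(r$confusion) != col(r$confusion)] == 0))
  expect_equal(r$overall$accuracy, 1)
  expect_equal(r$per_class$f1, rep(1, 4))
})

test_that("a constant predictor on balanced input hits the closed form", {
  y <- rep(0:3, each = 10)
  r <- evaluation_metrics(confusion(y, rep(0L, 40)))
  expect_equal(r$per_class$recall[1], 1)
  expect_equal(r$per_class$precision[1], 0.25)
  expect_equal(r$overall$accuracy, 0.25)
  # undefined precision for never-predicted classes is 0 and flagged
  expect_equal(r$per_class$precision[-1], rep(0, 3))
  expect_true(all(r$per_class$undefined[-1]))
})

test_that("metrics equal an independent per-element recount", {
  set.seed(12)
  y_true <- sample(0:3, 200, replace = TRUE)
  y_pred <- sample(0:3, 200, replace = TRUE)
  r <- evaluation_metrics(confusion(y_true, y_pred))
  expect_equal(r$overall$accuracy, mean(y_true == y_pred))
  for (cls in 0:3) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    tn <- sum(y_true != cls & y_pred != cls)
    i <- cls + 1
    expect_equal(r$per_class$accuracy[i], (tp + tn) / 200)
    expect_equal(r$per_class$precision[i], if (tp + fp) tp / (tp + fp) else 0)
    expect_equal(r$per_class$recall[i], if (tp + fn) tp / (tp + fn) else 0)
    pr <- r$per_class$precision[i]; rc <- r$per_class$recall[i]
    expect_equal(r$per_class$f1[i],
                 if (pr + rc) 2 * pr * rc / (pr + rc) else 0)
    # one-vs-rest bookkeeping against the matrix margins
    expect_equal(tp + fn, sum(r$confusion[i, ]))
    expect_equal(tp + fp, sum(r$confusion[, i]))
  }
  expect_equal(sum(diag(r$confusion)) / sum(r$confusion),
               r$overall$accuracy)
})

test_that("macro F1 is invariant under class relabeling", {
  set.seed(21)
  y_true <- sample(0:3, 120, replace = TRUE)
  y_pred <- sample(0:3, 120, replace = TRUE)
  perm <- c(2L, 0L, 3L, 1L)
  r1 <- evaluation_metrics(confusion(y_true, y_pred))
  r2 <- evaluation_metrics(confusion(perm[y_true + 1], perm[y_pred + 1]))
  expect_equal(r1$overall$f1, r2$overall$f1)
  expect_equal(r1$overall$accuracy, r2$overall$accuracy)
})

test_that("labels outside the class range are rejected", {
  expect_error(confusion(c(0, 4), c(0, 1)), "labels must lie")
  expect_error(confusion(c(0, -1), c(0, 1)), "labels must lie")
})
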