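test_that("Sn, OA, and AA match hand arithmetic on a binary matrix", {
  conf <- confusion_matrix(rep(c("pos", "neg"), c(10, 10)),
                           c(rep("pos", 9), "neg", "pos", "pos", rep("neg", 8)),
                           levels = c("pos", "neg"))
  expect_equal(unname(conf["pos", ]), c(9L, 1L))
  expect_equal(unname(conf["neg", ]), c(2L, 8L))
  expect_equal(unname(sensitivity(conf)), c(90, 80))
  expect_equal(overall_accuracy(conf), 85)
  expect_equal(average_accuracy(conf), 85)
})

test_that("degenerate confusion matrices are handled as specified", {
  diag4 <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(diag4) <- c(5L, 3L, 2L, 7L)
  expect_equal(unname(sensitivity(diag4)), rep(100, 4))
  expect_equal(overall_accuracy(diag4), 100)
  expect_equal(average_accuracy(diag4), 100)

  # a majority-class-only predictor on a 90/10 binary dataset
  conf <- matrix(c(90L, 0L, 10L, 0L), 2, byrow = TRUE,
                 dimnames = list(c("maj", "min"), c("maj", "min")))
  expect_equal(unname(suppressWarnings(sensitivity(conf))), c(100, 0))
  expect_equal(overall_accuracy(conf), 90)
  expect_equal(average_accuracy(conf), 50)

  # empty row: Sn undefined, warned, excluded from AA
  conf <- matrix(c(5L, 0L, 0L, 0L), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(sn <- sensitivity(conf), "no evaluated instances")
  expect_true(is.na(sn["b"]))
  expect_equal(average_accuracy(conf), 100)
})

test_that("OA equals the row-total-weighted mean of Sn", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    conf <- matrix(rpois(n * n, 5) + diag(n), n,
                   dimnames = list(letters[1:n], letters[1:n]))
    rs <- rowSums(conf)
    if (any(rs == 0)) next
    sn <- sensitivity(conf)
    expect_equal(overall_accuracy(conf), sum(sn * rs / sum(rs)),
                 tolerance = 1e-12)
  }
})

test_that("stage training memorizes separable data and is deterministic", {
  blobs <- make_blobs(n_per = 12, seed = 3)
  for (backend in c("random-forest", "svm-rbf")) {
    model <- train_stage(blobs$x, blobs$y, backend = backend,
                         params = list(seed = 9))
    expect_equal(mean(predict(model, blobs$x) == blobs$y), 1)
    model2 <- train_stage(blobs$x, blobs$y, backend = backend,
                          params = list(seed = 9))
    expect_identical(predict(model, blobs$x), predict(model2, blobs$x))
  }
})

test_that("stage training and prediction enforce their contracts", {
  blobs <- make_blobs(n_per = 6)
  expect_error(train_stage(blobs$x[1:7, ], c(rep("a", 6), "lonely")),
               "lonely")
  model <- train_stage(blobs$x, blobs$y)
  wrong <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  expect_error(predict(model, wrong), "feature mismatch")
})

test_that("grid search is exhaustive with the documented tie rule", {
  blobs <- make_blobs(n_per = 10, seed = 8)
  one <- grid_search_svm(blobs$x, blobs$y, cost_grid = 4, gamma_grid = 0.5,
                         folds = 3)
  expect_equal(c(one$cost, one$gamma), c(4, 0.5))
  expect_error(grid_search_svm(blobs$x, blobs$y, cost_grid = numeric(0)),
               "empty")
  # widely separated blobs: every pair separates, tie resolves to smallest
  best <- grid_search_svm(blobs$x, blobs$y, cost_grid = c(1, 8),
                          gamma_grid = c(0.25, 1), folds = 3)
  expect_equal(best$oa, 100)
  expect_equal(c(best$cost, best$gamma), c(1, 0.25))
  expect_equal(nrow(best$grid), 4L)
})

test_that("cross-validation pools folds and is invariant to row order", {
  blobs <- make_blobs(n_per = 20, seed = 4)
  cv <- cross_validate(blobs$x, blobs$y, folds = 5, seed = 2)
  expect_equal(cv$metrics$oa, 100)
  expect_equal(cv$metrics$aa, 100)
  expect_equal(sum(cv$confusion), 40)
  perm <- sample(40)
  cv_perm <- cross_validate(blobs$x[perm, ], blobs$y[perm], folds = 5, seed = 2)
  expect_identical(cv$confusion, cv_perm$confusion)
  expect_error(cross_validate(blobs$x, blobs$y, folds = 1), "at least 2")
})

test_that("folds are reduced with a warning when a class is too small", {
  blobs <- make_blobs(n_per = 4, seed = 6)
  expect_warning(cv <- cross_validate(blobs$x, blobs$y, folds = 10, seed = 1),
                 "folds reduced")
  expect_equal(cv$folds, 4L)
})

test_that("per-fold preprocessing differs from a deliberately leaky variant", {
  # one coordinate carries the class signal at a tiny scale next to a huge
  # outlier: global min-max scaling squashes the signal, per-fold scaling
  # (with the outlier held out) does not
  set.seed(42)
  n <- 30
  x <- cbind(sig = c(rnorm(n / 2, 0, 0.001), rnorm(n / 2, 0.01, 0.001), 1000),
             pad = rnorm(n + 1))
  rownames(x) <- sprintf("s%02d", seq_len(n + 1))
  y <- c(rep(c("a", "b"), each = n / 2), "b")
  clean <- cross_validate(x, y, folds = 5, seed = 3, backend = "svm-rbf",
                          params = list(cost = 1, gamma = 1))
  x_leaky <- apply(x, 2, function(col) (col - min(col)) / diff(range(col)))
  rownames(x_leaky) <- rownames(x)
  leaky <- cross_validate(x_leaky, y, folds = 5, seed = 3, backend = "svm-rbf",
                          params = list(cost = 1, gamma = 1), scale = FALSE)
  expect_false(identical(clean$confusion, leaky$confusion))
  expect_gt(clean$metrics$oa, leaky$metrics$oa)
})

test_that("evaluation reports carry one Sn column per class plus OA and AA", {
  blobs <- make_blobs(n_per = 10, seed = 5)
  cv <- cross_validate(blobs$x, blobs$y, folds = 5, seed = 1)
  rep1 <- evaluation_report(cv, "random-forest (2D)")
  expect_equal(names(rep1), c("method", "Sn.a", "Sn.b", "OA", "AA"))
  expect_equal(rep1$OA, cv$metrics$oa)
})
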