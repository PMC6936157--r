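test_that("metrics on hand-computed 2x2 confusion matrices", {
  cm <- matrix(c(8, 3, 2, 7), 2, 2,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$OA, 15 / 20)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$Sn, 0.8)
  expect_equal(pos$Sp, 0.7)
  expect_equal(pos$MCC, (8 * 7 - 2 * 3) / sqrt(10 * 11 * 10 * 9))
})

test_that("diagonal confusion matrices give perfect scores", {
  cm <- diag(c(5, 3, 2))
  dimnames(cm) <- list(letters[1:3], letters[1:3])
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$OA, 1)
  expect_true(all(rep$per_class$Sn == 1))
  expect_true(all(rep$per_class$Sp == 1))
  expect_true(all(rep$per_class$MCC == 1))
})

test_that("MCC is zero when its denominator vanishes", {
  cm <- matrix(c(0, 0, 5, 5), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  rep <- metrics_from_confusion(cm)
  expect_identical(rep$per_class$MCC[1], 0)
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
  expect_error(metrics_from_confusion(matrix(1, 2, 3)), "square")
})

test_that("metrics are invariant under class permutation and TP/TN swap", {
  set.seed(5)
  cm <- matrix(sample(0:9, 16, replace = TRUE), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  rep <- metrics_from_confusion(cm)
  perm <- c(3, 1, 4, 2)
  rep_p <- metrics_from_confusion(cm[perm, perm])
  expect_equal(rep_p$OA, rep$OA)
  expect_equal(rep_p$per_class[match(rep$per_class$class,
                                     rep_p$per_class$class), -1],
               rep$per_class[, -1], ignore_attr = TRUE)
  # per-class one-vs-rest MCC of class i equals MCC of its complement view
  expect_equal(sum(diag(cm)) / sum(cm), rep$OA)
})

test_that("separable blobs are classified perfectly by the OVO RBF SVM", {
  bl <- make_blobs(n_per = 12, gap = 8, seed = 2)
  pred <- svm_ovo_fit_predict(bl$x, bl$y, bl$x, C = 1, gamma = 0.5)
  expect_identical(as.character(pred), bl$y)
  expect_error(svm_ovo_fit_predict(bl$x, rep("a", 24), bl$x), "two classes")
})

test_that("grid search scans 121 pairs and breaks ties toward small C, gamma", {
  cfg <- grid_config()
  expect_length(cfg$C_values, 11L)
  expect_length(cfg$gamma_values, 11L)
  # constant features: every pair ties, so the smallest pair wins
  x <- matrix(1, 20, 3)
  y <- rep(c("a", "b"), each = 10)
  gs <- grid_search(x, y, grid_config(folds = 5, seed = 4))
  expect_identical(nrow(gs$grid), 121L)
  expect_equal(gs$C, 2^-5)
  expect_equal(gs$gamma, 2^-5)
})

test_that("grid search finds perfect CV accuracy on separable data", {
  bl <- make_blobs(n_per = 15, gap = 8, seed = 3)
  gs <- grid_search(bl$x, bl$y, grid_config(C_values = 2^(0:2),
                                            gamma_values = 2^(-2:0),
                                            folds = 5, seed = 1))
  expect_equal(gs$cv_accuracy, 1)
})

test_that("fold count shrinks with a warning when N < folds", {
  bl <- make_blobs(n_per = 3, gap = 8, seed = 6)
  expect_warning(
    grid_search(bl$x, bl$y, grid_config(C_values = 1, gamma_values = 1,
                                        folds = 10, seed = 1)),
    "reducing fold count")
})

test_that("jackknife on separable classes reaches OA 1 and reports (C, gamma)", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20), ncol = 2), matrix(rnorm(20) + 7, ncol = 2),
             matrix(cbind(rnorm(10) + 7, rnorm(10)), ncol = 2))
  y <- rep(c("a", "b", "c"), each = 10)
  res <- jackknife_evaluate(x, y, grid_config(C_values = 2^(0:3),
                                              gamma_values = 2^(-3:0),
                                              folds = 5, seed = 2))
  expect_equal(res$report$OA, 1)
  expect_identical(sum(res$confusion), 30L)
  expect_true(res$report$C %in% 2^(0:3))
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion), res$report$OA)
})

test_that("a two-sample jackknife can never predict the held-out class", {
  x <- matrix(c(0, 0, 1, 1), 2, 2)
  y <- c("a", "b")
  expect_message(res <- jackknife_evaluate(x, y, params = list(C = 1, gamma = 1)),
                 "single member")
  expect_equal(res$report$OA, 0)
})
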