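# One-versus-one RBF SVM with grid search over C and gamma, jackknife
# (leave-one-out) evaluation, and per-class Sn/Sp/MCC plus overall accuracy.
# The SVM itself is libsvm via e1071, whose multiclass scheme is exactly
# one-versus-one: k(k-1)/2 pairwise classifiers with majority voting.

#' Grid-search configuration
#'
#' The default grid takes C and gamma over the integer powers of two in
#' \[2^-5, 2^5\] (11 x 11 = 121 candidate pairs), scored by stratified
#' 10-fold cross-validation accuracy.
#'
#' @param C_values candidate cost values (> 0).
#' @param gamma_values candidate RBF gamma values (> 0).
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @return an object of class `grid_config`.
#' @export
grid_config <- function(C_values = 2^(-5:5), gamma_values = 2^(-5:5),
                        folds = 10L, seed = 1L) {
  stopifnot(all(C_values > 0), all(gamma_values > 0), folds >= 2)
  structure(list(C_values = sort(C_values), gamma_values = sort(gamma_values),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "grid_config")
}

#' Fit an OVO RBF SVM and predict
#'
#' For a k-class problem, k(k-1)/2 pairwise radial-basis-function
#' classifiers are constructed and vote on each test point.  Features are
#' passed to the SVM unscaled; any normalization is done upstream.
#'
#' @param train_x numeric matrix of training features.
#' @param train_y training labels (coerced to factor).
#' @param test_x numeric matrix of test features (same columns).
#' @param C cost parameter.
#' @param gamma RBF kernel width parameter.
#' @return factor of predicted labels, levels = training classes.
#' @export
svm_ovo_fit_predict <- function(train_x, train_y, test_x, C = 1, gamma = 1) {
  train_y <- factor(train_y)
  train_y <- droplevels(train_y)
  if (nlevels(train_y) < 2L)
    stop("training set must contain at least two classes")
  if (ncol(train_x) != ncol(test_x))
    stop("train and test feature dimensions differ")
  fit <- e1071::svm(x = train_x, y = train_y, kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  stats::predict(fit, test_x)
}

# Stratified fold assignment: within each class, samples are shuffled with
# the given seed and dealt round-robin into folds.
make_stratified_folds <- function(y, folds, seed) {
  y <- factor(y)
  assign_ <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    assign_[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign_
}

#' Grid search for (C, gamma)
#'
#' Scores every candidate pair by mean stratified cross-validation accuracy
#' and returns the maximizer; ties are broken toward the smallest C, then
#' the smallest gamma.  If N < folds, the fold count is reduced to N with a
#' warning.
#'
#' @param x numeric feature matrix.
#' @param y labels.
#' @param config a [grid_config()].
#' @return list with `C`, `gamma`, `cv_accuracy`, and `grid` (a data frame
#'   of all pairs and their CV accuracies).
#' @export
grid_search <- function(x, y, config = grid_config()) {
  y <- factor(y)
  n <- length(y)
  folds <- config$folds
  if (n < folds) {
    warning(sprintf("N = %d < %d folds; reducing fold count to N", n, folds))
    folds <- n
  }
  fold_id <- make_stratified_folds(y, folds, config$seed)
  grid <- expand.grid(C = config$C_values, gamma = config$gamma_values,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(grid))
  for (j in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      te <- fold_id == f
      if (!any(te)) next
      ytr <- droplevels(y[!te])
      if (nlevels(ytr) < 2L) next
      pred <- svm_ovo_fit_predict(x[!te, , drop = FALSE], ytr,
                                  x[te, , drop = FALSE],
                                  C = grid$C[j], gamma = grid$gamma[j])
      correct <- correct + sum(as.character(pred) == as.character(y[te]))
    }
    acc[j] <- correct / n
  }
  grid$cv_accuracy <- acc
  # rows are ordered C-fastest within gamma; scan in (C, gamma) priority
  ord <- order(grid$C, grid$gamma)
  best <- ord[1]
  for (j in ord) if (grid$cv_accuracy[j] > grid$cv_accuracy[best]) best <- j
  # strict '>' keeps the earliest (smallest C, then gamma) among ties
  list(C = grid$C[best], gamma = grid$gamma[best],
       cv_accuracy = grid$cv_accuracy[best], grid = grid)
}

#' Jackknife (leave-one-out) evaluation of the OVO SVM
#'
#' Each sample is predicted by a model trained on the other N-1.  By
#' default (C, gamma) is selected once by [grid_search()] on the full
#' dataset and reused in every fold, mirroring a two-stage protocol; this is
#' optimistically biased because the held-out point participates in
#' parameter selection.  `nested = TRUE` repeats the grid search inside
#' every fold instead (slower, unbiased).
#'
#' A class with a single member can never be predicted correctly (its only
#' example is held out while that class is absent from training); this is
#' reported via `message()`.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y labels.
#' @param config a [grid_config()].
#' @param params optional list with fixed `C` and `gamma`, skipping grid
#'   search entirely.
#' @param nested logical; per-fold grid search.
#' @return list with `confusion` (square matrix, rows = true, columns =
#'   predicted) and `report` (an `eval_report`, see
#'   [metrics_from_confusion()], with `C` and `gamma` attached).
#' @export
jackknife_evaluate <- function(x, y, config = grid_config(), params = NULL,
                               nested = FALSE) {
  y <- factor(y)
  n <- length(y)
  if (n < 2L) stop("need at least two samples")
  if (nlevels(y) < 2L) stop("need at least two classes")
  singletons <- names(which(table(y) == 1L))
  if (length(singletons))
    message("class(es) with a single member can never be predicted correctly in a jackknife: ",
            paste(singletons, collapse = ", "))
  if (is.null(params) && !nested)
    params <- grid_search(x, y, config)[c("C", "gamma")]
  pred <- character(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) {
      # degenerate 2-sample case: only one class remains to vote
      pred[i] <- as.character(ytr[1])
      next
    }
    p <- if (nested) {
      gs <- grid_search(x[-i, , drop = FALSE], y[-i], config)
      svm_ovo_fit_predict(x[-i, , drop = FALSE], ytr, x[i, , drop = FALSE],
                          C = gs$C, gamma = gs$gamma)
    } else {
      svm_ovo_fit_predict(x[-i, , drop = FALSE], ytr, x[i, , drop = FALSE],
                          C = params$C, gamma = params$gamma)
    }
    pred[i] <- as.character(p)
  }
  lev <- union(levels(y), unique(pred))
  confusion <- table(true = factor(y, lev), predicted = factor(pred, lev))
  confusion <- unclass(confusion)
  report <- metrics_from_confusion(confusion)
  report$C <- if (!is.null(params)) params$C else NA_real_
  report$gamma <- if (!is.null(params)) params$gamma else NA_real_
  list(confusion = confusion, report = report)
}
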