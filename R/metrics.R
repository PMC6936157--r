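# Per-class evaluation metrics from a pooled multiclass confusion matrix.
# Each class is scored one-vs-rest: TP is its diagonal entry, FN the rest of
# its row, FP the rest of its column, TN everything else.
#
#   Sn  = TP / (TP + FN)
#   Sp  = TN / (TN + FP)
#   OA  = sum_i TP_i / N
#   MCC = (TP*TN - FP*FN) /
#         sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)),  0 when the denominator is 0.

#' Compute Sn, Sp, MCC and OA from a confusion matrix
#'
#' @param cm square numeric matrix of counts, rows = true classes, columns =
#'   predicted classes, with matching dimnames.
#' @return an object of class `eval_report`: data frame `per_class` with
#'   columns `class`, `Sn`, `Sp`, `MCC`, plus scalar `OA` and total `N`.
#' @examples
#' cm <- matrix(c(8, 3, 2, 7), 2, 2,
#'              dimnames = list(c("a", "b"), c("a", "b")))
#' metrics_from_confusion(cm)$OA  # 0.75
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0L || nrow(cm) != ncol(cm))
    stop("confusion matrix must be square and non-empty")
  if (any(cm < 0)) stop("confusion matrix entries must be non-negative")
  n <- sum(cm)
  if (n == 0) stop("confusion matrix is empty (N = 0)")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  per <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    sn <- if (tp + fn > 0) tp / (tp + fn) else 0
    sp <- if (tn + fp > 0) tn / (tn + fp) else 0
    den <- sqrt((tp + fn) * (tp + fp)) * sqrt((tn + fn) * (tn + fp))
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
    data.frame(class = classes[i], Sn = sn, Sp = sp, MCC = mcc,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_class = per, OA = sum(diag(cm)) / n, N = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Jackknife evaluation report (N = %d)\n", x$N))
  df <- x$per_class
  df$Sn <- round(df$Sn, digits); df$Sp <- round(df$Sp, digits)
  df$MCC <- round(df$MCC, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Overall accuracy (OA): %.4f\n", x$OA))
  if (!is.null(x$C) && !is.na(x$C))
    cat(sprintf("Selected parameters: C = %g, gamma = %g\n", x$C, x$gamma))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per class (Sn, Sp, MCC) followed by an `OA` footer row.
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  df <- report$per_class
  footer <- data.frame(class = "OA", Sn = report$OA, Sp = NA_real_,
                       MCC = NA_real_, stringsAsFactors = FALSE)
  utils::write.table(rbind(df, footer), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
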