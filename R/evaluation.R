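#' Shuffled train/test split
#'
#' Shuffles the indices and assigns the first `floor(n * train_fraction)`
#' to training, the rest to testing; disjoint, exhaustive, and
#' deterministic per seed.
#'
#' @param n Number of samples (`>= 2`).
#' @param train_fraction Fraction in training, in `(0, 1)` (default 0.9).
#' @param seed Integer seed.
#' @param shuffle Shuffle before splitting (default `TRUE`).
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' s <- split_train_test(7790, 0.9, seed = 1)
#' lengths(s)  # 7011 / 779
#' @export
split_train_test <- function(n, train_fraction = 0.9, seed = 1,
                             shuffle = TRUE) {
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n)
    stop("split leaves an empty side (n = ", n, ", fraction = ",
         train_fraction, ")")
  set.seed(seed)
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  list(train = idx[seq_len(n_train)], test = idx[(n_train + 1):n])
}

#' Disjoint k-fold assignment
#'
#' Folds are disjoint with union equal to all indices and sizes differing
#' by at most one. With `stratify_labels`, indices are dealt per class so
#' every fold's class proportions differ from the global ones by at most
#' one sample per class.
#'
#' @param n Number of samples.
#' @param k Number of folds (`<= n`).
#' @param seed Integer seed.
#' @param stratify_labels Optional length-`n` label vector.
#' @return List of `k` integer index vectors.
#' @export
kfold <- function(n, k = 10, seed = 1, stratify_labels = NULL) {
  stopifnot(k >= 2)
  if (k > n) stop("k = ", k, " exceeds n = ", n)
  set.seed(seed)
  if (is.null(stratify_labels)) {
    idx <- sample.int(n)
    fold_of <- rep(seq_len(k), length.out = n)
    return(unname(split(idx, fold_of)))
  }
  stopifnot(length(stratify_labels) == n)
  folds <- vector("list", k)
  offset <- 0L
  for (cls in unique(sort(stratify_labels))) {
    cls_idx <- sample(which(stratify_labels == cls))
    # rotate the starting fold per class so remainders spread evenly
    fold_of <- (offset + seq_along(cls_idx) - 1L) %% k + 1L
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], cls_idx[fold_of == f])
    offset <- (offset + length(cls_idx)) %% k
  }
  folds
}

#' Multiclass confusion matrix
#'
#' @param y_true,y_pred Equal-length label vectors with values in
#'   `0:(n_classes - 1)`; rows are true classes, columns predictions.
#' @param n_classes Number of classes (default 4).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, n_classes = 4) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= n_classes))
    stop("labels must lie in 0:", n_classes - 1)
  cm <- table(factor(y_true, levels = 0:(n_classes - 1)),
              factor(y_pred, levels = 0:(n_classes - 1)))
  structure(unclass(as.matrix(cm)), dimnames = dimnames(cm),
            class = "confusion_matrix")
}

#' Per-class and overall classification metrics
#'
#' Each class is scored one-vs-rest from the confusion matrix: with its
#' true/false positives/negatives,
#' accuracy = (TP + TN) / total, precision = TP / (TP + FP),
#' recall = TP / (TP + FN), and F1 the harmonic mean of precision and
#' recall. Ratios with zero denominator are reported as 0 and flagged.
#' Overall accuracy is the trace over the total; overall precision,
#' recall, and F1 are unweighted (macro) averages. Published per-class
#' "accuracy" tables are ambiguous between the one-vs-rest quantity and the
#' diagonal rate, so both `accuracy` and `recall` columns are reported.
#'
#' @param cm A [confusion()] matrix.
#' @return Object of class `evaluation_report`: `confusion`, `per_class`
#'   data frame (`class`, `accuracy`, `precision`, `recall`, `f1`,
#'   `undefined`), `overall` list (`accuracy`, `precision`, `recall`,
#'   `f1`, `macro_accuracy`), and `metadata`.
#' @export
evaluation_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") ||
              (is.matrix(cm) && nrow(cm) == ncol(cm)))
  cm <- unclass(cm)
  total <- sum(cm)
  stopifnot(total > 0)
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn

  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * recall * precision, recall + precision)
  acc <- (tp + tn) / total
  undefined <- (tp + fp == 0) | (tp + fn == 0) |
    (recall + precision == 0)

  per_class <- data.frame(
    class = 0:(k - 1), accuracy = acc, precision = precision,
    recall = recall, f1 = f1, undefined = undefined)
  overall <- list(
    accuracy = sum(tp) / total,
    precision = mean(precision), recall = mean(recall), f1 = mean(f1),
    macro_accuracy = mean(acc))
  structure(list(confusion = cm, per_class = per_class, overall = overall,
                 metadata = list()),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("Evaluation report\n")
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  pc <- x$per_class
  pc[2:5] <- lapply(pc[2:5], round, digits)
  cat("\nPer-class (one-vs-rest):\n")
  print(pc, row.names = FALSE)
  cat(sprintf(
    "\nOverall: accuracy %.4f | macro precision %.4f | macro recall %.4f | macro F1 %.4f\n",
    x$overall$accuracy, x$overall$precision, x$overall$recall, x$overall$f1))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`; `path` optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(confusion = unclass(report$confusion),
              per_class = report$per_class, overall = report$overall,
              metadata = report$metadata)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
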