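# Multiclass confusion matrix and the derived indicators: per-class
# precision/recall/F1, support-weighted F1, overall accuracy.

#' Build a multiclass confusion matrix
#'
#' Rows are inferred (predicted) classes, columns are actual classes, so
#' `counts[i, j]` is the number of instances predicted as class i whose
#' true class is j. Row sums SI give per-class predicted counts, column
#' sums ST give supports, and the diagonal holds the true positives.
#'
#' @param y_true integer vector of 0-based true class ids.
#' @param y_pred integer vector of 0-based predicted class ids.
#' @param p number of classes.
#' @return A `confusion_matrix`: list with `counts` (p x p), `TP`, `SI`,
#'   `ST` and `total`.
#' @export
confusion <- function(y_true, y_pred, p) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  p <- as.integer(p)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= p))
    stop("class ids must lie in 0..p-1")
  counts <- matrix(0L, p, p)
  for (i in seq_along(y_true))
    counts[y_pred[i] + 1L, y_true[i] + 1L] <-
      counts[y_pred[i] + 1L, y_true[i] + 1L] + 1L
  as_confusion(counts)
}

#' Wrap a count matrix as a confusion matrix
#'
#' For count tables produced elsewhere (e.g. published evaluation tables)
#' with the same orientation: rows inferred, columns actual.
#'
#' @param counts p x p non-negative integer matrix.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- NULL
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(counts = counts, TP = diag(counts),
                 SI = rowSums(counts), ST = colSums(counts),
                 total = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: %d classes, %d instances, accuracy %.4f\n",
              nrow(x$counts), x$total, overall_accuracy(x)))
  print(x$counts)
  invisible(x)
}

#' Per-class precision and recall
#'
#' `precision_i = TP_i / SI_i`, `recall_i = TP_i / ST_i`. A class never
#' predicted (SI = 0) gets precision 0 and a class with no true instances
#' (ST = 0) gets recall 0; either case raises a warning rather than an
#' error, since empty classes routinely occur on small held-out folds.
#'
#' @param cm a `confusion_matrix`.
#' @return List with numeric vectors `precision` and `recall` in `[0, 1]`.
#' @export
precision_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (any(cm$SI == 0))
    warning("class(es) ", paste(which(cm$SI == 0) - 1L, collapse = ", "),
            " never predicted; precision reported as 0")
  if (any(cm$ST == 0))
    warning("class(es) ", paste(which(cm$ST == 0) - 1L, collapse = ", "),
            " have no true instances; recall reported as 0")
  precision <- ifelse(cm$SI > 0, cm$TP / cm$SI, 0)
  recall <- ifelse(cm$ST > 0, cm$TP / cm$ST, 0)
  list(precision = precision, recall = recall)
}

#' Per-class F1 scores
#'
#' Harmonic mean of precision and recall per class; 0 when both are 0.
#'
#' @param cm a `confusion_matrix`.
#' @return Numeric vector of per-class F1 in `[0, 1]`.
#' @export
f1_per_class <- function(cm) {
  pr <- suppressWarnings(precision_recall(cm))
  with(pr, ifelse(precision + recall > 0,
                  2 * precision * recall / (precision + recall), 0))
}

#' Support-weighted F1
#'
#' Mean of per-class F1 weighted by support (the number of true instances
#' per class): `sum(ST_i * F1_i) / sum(ST_i)`.
#'
#' @param cm a `confusion_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(cm) {
  f1 <- f1_per_class(cm)
  sum(cm$ST * f1) / sum(cm$ST)
}

#' Overall accuracy
#'
#' Fraction of instances on the confusion-matrix diagonal; identical to
#' micro-averaged recall.
#'
#' @param cm a `confusion_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0) stop("empty confusion matrix")
  sum(cm$TP) / cm$total
}

#' Full metrics report for a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @param class_names optional class names for the per-class table.
#' @return List with `per_class` (data frame: class, support, precision,
#'   recall, f1, recall_pct — recall rounded half-up to integer percent,
#'   the convention of published per-activity accuracy rows),
#'   `weighted_f1`, `accuracy`.
#' @export
metrics_report <- function(cm, class_names = NULL) {
  pr <- suppressWarnings(precision_recall(cm))
  f1 <- f1_per_class(cm)
  p <- nrow(cm$counts)
  if (is.null(class_names)) class_names <- as.character(seq_len(p))
  list(per_class = data.frame(
         class = class_names, support = as.integer(cm$ST),
         precision = pr$precision, recall = pr$recall, f1 = f1,
         recall_pct = round_half_up(100 * pr$recall)),
       weighted_f1 = weighted_f1(cm),
       accuracy = overall_accuracy(cm))
}

# round half away from zero, the convention for integer-percent tables
round_half_up <- function(x) floor(x + 0.5)
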