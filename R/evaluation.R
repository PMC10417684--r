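#' Build a confusion matrix from true and predicted labels
#'
#' Rows index the true class, columns the predicted class, in the order
#' given by `class_names`.
#'
#' @param truth Character or factor vector of true class labels.
#' @param estimate Character or factor vector of predicted labels, same
#'   length as `truth`.
#' @param class_names Character vector of class names fixing row/column
#'   order. Defaults to the sorted union of observed labels.
#' @return An object of class `beetle_confusion`: an integer K x K matrix
#'   with `dimnames` `list(truth, estimate)`.
#' @examples
#' confusion_matrix(c("a", "b", "b"), c("a", "b", "a"), c("a", "b"))
#' @export
confusion_matrix <- function(truth, estimate, class_names = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length.")
  }
  if (length(truth) == 0L) {
    abort("Cannot build a confusion matrix from zero samples.")
  }
  if (is.null(class_names)) class_names <- sort(unique(c(truth, estimate)))
  unknown <- setdiff(unique(c(truth, estimate)), class_names)
  if (length(unknown)) {
    abort(paste0("Labels not in `class_names`: ", paste(unknown, collapse = ", ")))
  }
  counts <- table(
    factor(truth, levels = class_names),
    factor(estimate, levels = class_names)
  )
  m <- matrix(as.integer(counts), nrow = length(class_names),
              dimnames = list(truth = class_names, estimate = class_names))
  structure(m, class = c("beetle_confusion", "matrix", "array"))
}

#' Construct a confusion matrix directly from counts
#'
#' @param counts K x K numeric matrix of non-negative integers, rows = true
#'   class, columns = predicted class.
#' @param class_names Length-K character vector.
#' @return A `beetle_confusion` object.
#' @export
as_confusion_matrix <- function(counts, class_names = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("`counts` must be square.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must contain non-negative integers.")
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(nrow(counts)))
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = list(truth = class_names, estimate = class_names))
  structure(m, class = c("beetle_confusion", "matrix", "array"))
}

#' @export
print.beetle_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = prediction), n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' Each class is scored against the rest: accuracy (TP+TN)/N, precision
#' TP/(TP+FP), sensitivity TP/(TP+FN), specificity TN/(TN+FP) and the F
#' score 2*precision*sensitivity/(precision+sensitivity). All five are
#' percentages in \[0, 100\], kept at full precision; round only for
#' display.
#'
#' A class with no predicted positives has undefined precision (and hence
#' F score); those entries are `NA` with a warning and are excluded from
#' macro averages.
#'
#' @param cm A `beetle_confusion` object (or square count matrix).
#' @return A tibble with one row per class and columns `class`,
#'   `accuracy`, `precision`, `sensitivity`, `specificity`, `f_score`.
#' @examples
#' cm <- as_confusion_matrix(
#'   rbind(c(7, 0, 1), c(0, 5, 0), c(0, 0, 7)),
#'   c("normal", "benign", "malignant")
#' )
#' per_class_metrics(cm)
#' @export
per_class_metrics <- function(cm) {
  if (!inherits(cm, "beetle_confusion")) cm <- as_confusion_matrix(cm)
  n <- sum(cm)
  if (n == 0) abort("Confusion matrix has zero total count.")
  classes <- rownames(cm)
  rows <- purrr::map(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    precision <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
    sensitivity <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
    f_score <- if (is.na(precision) || is.na(sensitivity) ||
                   precision + sensitivity == 0) {
      NA_real_
    } else {
      2 * precision * sensitivity / (precision + sensitivity)
    }
    tibble::tibble(
      class = classes[k],
      accuracy = 100 * (tp + tn) / n,
      precision = precision,
      sensitivity = sensitivity,
      specificity = 100 * tn / (tn + fp),
      f_score = f_score
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$precision)) {
    warn("Some classes have no predicted positives; their precision/F score are NA and excluded from macro averages.")
  }
  out
}

#' Macro (unweighted) average of per-class metrics
#'
#' @param metrics Tibble from [per_class_metrics()].
#' @return One-row tibble with `class = "macro"` and the unweighted mean
#'   of each metric across classes (`NA` entries dropped).
#' @export
macro_average <- function(metrics) {
  dplyr::summarise(
    metrics,
    class = "macro",
    dplyr::across(
      c("accuracy", "precision", "sensitivity", "specificity", "f_score"),
      ~ mean(.x, na.rm = TRUE)
    )
  )
}

#' Classification error rate
#'
#' The percentage of misclassified samples, `100 * misclassified / total`.
#' This scalar is the fitness the hyperparameter tuner minimizes.
#'
#' @inheritParams confusion_matrix
#' @return A single percentage in \[0, 100\].
#' @export
classification_error_rate <- function(truth, estimate) {
  if (length(truth) == 0L) abort("Cannot compute an error rate on zero samples.")
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length.")
  }
  100 * mean(as.character(truth) != as.character(estimate))
}

#' Full evaluation report for a set of predictions
#'
#' Bundles the confusion matrix, the per-class one-vs-rest table and the
#' macro-average row.
#'
#' @inheritParams confusion_matrix
#' @return A `beetle_evaluation` object: list with `confusion` (a
#'   `beetle_confusion`), `per_class` and `macro` tibbles, and
#'   `error_rate`.
#' @export
evaluate_predictions <- function(truth, estimate, class_names = NULL) {
  cm <- confusion_matrix(truth, estimate, class_names)
  per_class <- per_class_metrics(cm)
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      macro = macro_average(per_class),
      error_rate = classification_error_rate(truth, estimate)
    ),
    class = "beetle_evaluation"
  )
}

#' Evaluation report straight from a confusion matrix
#'
#' @param cm A `beetle_confusion` or square count matrix.
#' @return A `beetle_evaluation` object (error rate derived from the
#'   off-diagonal mass).
#' @export
evaluate_confusion <- function(cm) {
  if (!inherits(cm, "beetle_confusion")) cm <- as_confusion_matrix(cm)
  per_class <- per_class_metrics(cm)
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      macro = macro_average(per_class),
      error_rate = 100 * (1 - sum(diag(cm)) / sum(cm))
    ),
    class = "beetle_evaluation"
  )
}

#' @export
print.beetle_evaluation <- function(x, ...) {
  print(x$confusion)
  tab <- dplyr::bind_rows(x$per_class, x$macro)
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric), ~ round_half_up(.x, 2)))
  cat("\nPer-class one-vs-rest metrics (%), macro = unweighted mean:\n")
  print(as.data.frame(tab), row.names = FALSE)
  cat("\nError rate:", format(round_half_up(x$error_rate, 2), nsmall = 2), "%\n")
  invisible(x)
}

#' Write an evaluation report as plain text files
#'
#' Produces `<stem>.txt` (human-readable table) and `<stem>.tsv`
#' (machine-readable: split label, per-class rows and macro row).
#'
#' @param x A `beetle_evaluation`.
#' @param stem File path stem (no extension).
#' @param split Label recorded in the machine-readable file, e.g.
#'   `"test_0.8"`.
#' @return `stem`, invisibly.
#' @export
write_evaluation <- function(x, stem, split = "test") {
  txt <- utils::capture.output(print(x))
  writeLines(txt, paste0(stem, ".txt"))
  tab <- dplyr::bind_rows(x$per_class, x$macro)
  tab <- dplyr::mutate(tab, split = split, .before = 1)
  utils::write.table(tab, paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}
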