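#' Worked-example confusion matrices for the lungdb study layout
#'
#' The lungdb benchmark has 100 CT images in three classes (35 normal, 32
#' benign, 33 malignant) evaluated under 80:20 and 70:30 train/test
#' splits. For each split and phase this function returns the confusion
#' matrix uniquely implied by the published per-class one-vs-rest metric
#' grid for that benchmark: the per-class sensitivities pin down the true
#' class counts and diagonal, the precisions pin down the off-diagonal
#' placement, and the specificity/accuracy values confirm the
#' reconstruction. Feeding these matrices to [per_class_metrics()] and
#' [macro_average()] reproduces the full 5-metric x 3-class x 4-split
#' grid to two decimals.
#'
#' @return A named list of four `beetle_confusion` matrices:
#'   `train_80`, `test_20`, `train_70`, `test_30`. Rows/columns are
#'   ordered normal, benign, malignant.
#' @examples
#' cms <- lungdb_confusion_matrices()
#' macro_average(per_class_metrics(cms$test_20))
#' @export
lungdb_confusion_matrices <- function() {
  cls <- c("normal", "benign", "malignant")
  list(
    train_80 = as_confusion_matrix(rbind(
      c(27, 0, 0),
      c(0, 27, 0),
      c(1, 0, 25)
    ), cls),
    test_20 = as_confusion_matrix(rbind(
      c(7, 0, 1),
      c(0, 5, 0),
      c(0, 0, 7)
    ), cls),
    train_70 = as_confusion_matrix(rbind(
      c(21, 0, 1),
      c(0, 23, 0),
      c(0, 0, 25)
    ), cls),
    test_30 = as_confusion_matrix(rbind(
      c(11, 1, 1),
      c(0, 9, 0),
      c(0, 0, 8)
    ), cls)
  )
}

#' Class counts of the lungdb benchmark layout
#'
#' @return Named integer vector `c(normal = 35, benign = 32, malignant = 33)`.
#' @export
lungdb_class_counts <- function() {
  c(normal = 35L, benign = 32L, malignant = 33L)
}
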