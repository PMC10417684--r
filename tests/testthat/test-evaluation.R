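test_that("confusion matrices count truth rows against prediction columns", {
  cls <- c("normal", "benign", "malignant")
  cm <- confusion_matrix(rep(cls, each = 2), rep(cls, each = 2), cls)
  expect_equal(unname(diag(cm)), c(2L, 2L, 2L))
  expect_equal(sum(cm), 6L)

  cm <- confusion_matrix(c("N", "B", "M"), c("M", "B", "M"), c("N", "B", "M"))
  expect_equal(unname(unclass(cm)),
               rbind(c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 0L, 1L)))

  expect_error(confusion_matrix(character(0), character(0)), "zero samples")
  expect_error(confusion_matrix("a", "z", class_names = "a"), "not in")
})

test_that("the published per-class rows fall out of the one-vs-rest formulas", {
  cls <- c("normal", "benign", "malignant")
  m20 <- per_class_metrics(as_confusion_matrix(
    rbind(c(7, 0, 1), c(0, 5, 0), c(0, 0, 7)), cls))
  normal <- m20[m20$class == "normal", ]
  expect_equal(normal$accuracy, 95, tolerance = 0.005)
  expect_equal(normal$precision, 100, tolerance = 0.005)
  expect_equal(normal$sensitivity, 87.5, tolerance = 0.005)
  expect_equal(normal$specificity, 100, tolerance = 0.005)
  expect_equal(normal$f_score, 93.33, tolerance = 0.005)

  m30 <- per_class_metrics(as_confusion_matrix(
    rbind(c(11, 1, 1), c(0, 9, 0), c(0, 0, 8)), cls))
  expect_equal(m30$precision[m30$class == "benign"], 90, tolerance = 0.005)
  expect_equal(m30$precision[m30$class == "malignant"], 88.89, tolerance = 0.005)

  ideal <- per_class_metrics(as_confusion_matrix(diag(c(4, 5, 6)), cls))
  expect_true(all(as.matrix(ideal[, -1]) == 100))
})

test_that("macro averages are unweighted means of the per-class values", {
  cls <- c("normal", "benign", "malignant")
  m <- tibble::tibble(class = cls, accuracy = c(98.75, 100, 98.75),
                      precision = 1, sensitivity = 1, specificity = 1, f_score = 1)
  expect_equal(macro_average(m)$accuracy, 99.1666667, tolerance = 1e-6)
  expect_equal(beetlefuse:::round_half_up(macro_average(m)$accuracy), 99.17)

  m30 <- per_class_metrics(as_confusion_matrix(
    rbind(c(11, 1, 1), c(0, 9, 0), c(0, 0, 8)), cls))
  expect_equal(macro_average(m30)$sensitivity, 94.87, tolerance = 0.005)

  same <- per_class_metrics(as_confusion_matrix(diag(c(3, 3, 3)), cls))
  expect_equal(macro_average(same)$f_score, same$f_score[1])
  # macro values sit between the per-class extremes
  mac <- macro_average(m30)
  for (col in c("accuracy", "precision", "sensitivity", "specificity", "f_score")) {
    expect_gte(mac[[col]], min(m30[[col]]))
    expect_lte(mac[[col]], max(m30[[col]]))
  }
})

test_that("classification error rate is the misclassified percentage", {
  expect_equal(classification_error_rate(c("a", "b"), c("a", "b")), 0)
  truth <- c(rep("n", 13), rep("b", 9), rep("m", 8))
  pred <- truth
  pred[1] <- "b"; pred[2] <- "m"
  expect_equal(classification_error_rate(truth, pred), 100 * 2 / 30)
  # identity with micro accuracy on random label vectors
  set.seed(11)
  for (i in 1:10) {
    t_ <- sample(letters[1:3], 40, TRUE)
    p_ <- sample(letters[1:3], 40, TRUE)
    expect_equal(classification_error_rate(t_, p_), 100 - 100 * mean(t_ == p_))
  }
  expect_error(classification_error_rate(character(0), character(0)), "zero")
})

test_that("metrics are invariant under a simultaneous class permutation", {
  cls <- c("normal", "benign", "malignant")
  counts <- rbind(c(11, 1, 1), c(0, 9, 0), c(0, 0, 8))
  m1 <- per_class_metrics(as_confusion_matrix(counts, cls))
  perm <- c(3, 1, 2)
  m2 <- per_class_metrics(as_confusion_matrix(counts[perm, perm], cls[perm]))
  m2 <- m2[match(m1$class, m2$class), ]
  expect_equal(as.matrix(m2[, -1]), as.matrix(m1[, -1]), ignore_attr = TRUE)
})

test_that("for two classes, sensitivity of one equals specificity of the other", {
  cm <- as_confusion_matrix(rbind(c(8, 2), c(3, 7)), c("A", "B"))
  m <- per_class_metrics(cm)
  expect_equal(m$sensitivity[m$class == "A"], m$specificity[m$class == "B"])
  expect_equal(m$sensitivity[m$class == "B"], m$specificity[m$class == "A"])
})

test_that("a class never predicted gets flagged NA precision, excluded from macro", {
  cm <- as_confusion_matrix(rbind(c(5, 0, 0), c(2, 0, 0), c(0, 0, 3)),
                            c("x", "y", "z"))
  expect_warning(m <- per_class_metrics(cm), "no predicted positives")
  expect_true(is.na(m$precision[m$class == "y"]))
  mac <- macro_average(m)
  expect_equal(mac$precision, mean(m$precision, na.rm = TRUE))
})

test_that("one-vs-rest metrics agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(21)
  cls <- c("benign", "malignant", "normal")
  truth <- factor(sample(cls, 60, TRUE), levels = cls)
  pred <- factor(ifelse(runif(60) < 0.7, as.character(truth),
                        sample(cls, 60, TRUE)), levels = cls)
  ours <- per_class_metrics(confusion_matrix(truth, pred, cls))
  ref <- caret::confusionMatrix(pred, truth)$byClass
  expect_equal(ours$sensitivity, unname(ref[, "Sensitivity"]) * 100, tolerance = 1e-8)
  expect_equal(ours$specificity, unname(ref[, "Specificity"]) * 100, tolerance = 1e-8)
  expect_equal(ours$precision, unname(ref[, "Precision"]) * 100, tolerance = 1e-8)
})

test_that("evaluation reports serialize to text and round-trip the macro row", {
  ev <- evaluate_confusion(lungdb_confusion_matrices()$test_20)
  stem <- file.path(withr::local_tempdir(), "report")
  write_evaluation(ev, stem, split = "test_0.2")
  expect_true(file.exists(paste0(stem, ".txt")))
  tab <- read.delim(paste0(stem, ".tsv"))
  expect_equal(tab$accuracy[tab$class == "macro"], ev$macro$accuracy, tolerance = 1e-8)
  expect_equal(unique(tab$split), "test_0.2")
})
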