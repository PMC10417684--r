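#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for optimizer results
#'
#' `tidy()` returns the per-iteration trace (iteration, best_fitness,
#' mean_fitness); `glance()` a one-row summary.
#'
#' @param x A `dbo_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dbo_result <- function(x, ...) x$history

#' @rdname tidy.dbo_result
#' @export
glance.dbo_result <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    evaluations = x$evaluations,
    iterations = x$config$max_iterations,
    population_size = x$config$population_size,
    dim = x$bounds$dim
  )
}

#' Tidiers for fitted LSTM classifiers
#'
#' `tidy()` returns the epoch-wise training loss trace; `glance()` the
#' hyperparameters and final loss.
#'
#' @param x An `lstm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lstm_fit <- function(x, ...) x$loss_trace

#' @rdname tidy.lstm_fit
#' @export
glance.lstm_fit <- function(x, ...) {
  tibble::tibble(
    hidden_size = x$params$hidden_size,
    chunk_count = x$encoding$chunk_count,
    learning_rate = x$hyperparams$learning_rate,
    batch_size = x$hyperparams$batch_size,
    epochs = nrow(x$loss_trace),
    final_loss = utils::tail(x$loss_trace$loss, 1)
  )
}

#' Tidiers for evaluation reports
#'
#' `tidy()` stacks the per-class rows and the macro row; `glance()`
#' returns the macro metrics plus the overall error rate.
#'
#' @param x A `beetle_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.beetle_evaluation <- function(x, ...) {
  dplyr::bind_rows(x$per_class, x$macro)
}

#' @rdname tidy.beetle_evaluation
#' @export
glance.beetle_evaluation <- function(x, ...) {
  dplyr::mutate(x$macro, error_rate = x$error_rate, class = NULL)
}

#' Tidy a confusion matrix into long form
#'
#' @param x A `beetle_confusion`.
#' @param ... Unused.
#' @return Tibble with columns `truth`, `estimate`, `n`.
#' @export
tidy.beetle_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "estimate", "n")
  tibble::as_tibble(df)
}

#' Tidiers for pipeline results
#'
#' `tidy()` returns the held-out test metrics (per class + macro);
#' `glance()` a one-row run summary.
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pipeline_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$reports$train), split = "train", .before = 1),
    dplyr::mutate(tidy(x$reports$test), split = "test", .before = 1)
  )
}

#' @rdname tidy.pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$labels),
    fused_dim = ncol(x$bundle$fused),
    split_fraction = x$config$split_fraction,
    tuned_error = x$tuning$best_fitness,
    test_error_rate = x$reports$test$error_rate,
    test_macro_accuracy = x$reports$test$macro$accuracy,
    test_macro_f_score = x$reports$test$macro$f_score,
    seed = x$config$seed
  )
}
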