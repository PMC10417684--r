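#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   geom_col labs theme_minimal scale_fill_gradient facet_wrap
#'   position_dodge
#' @export
ggplot2::autoplot

#' Plot an optimizer fitness trace
#'
#' Best-so-far and population-mean fitness against iteration.
#'
#' @param object A `dbo_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dbo_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("best_fitness", "mean_fitness"),
                              names_to = "series", values_to = "fitness")
  ggplot(long, aes(x = .data$iteration, y = .data$fitness,
                   colour = .data$series)) +
    geom_line() +
    labs(x = "Iteration", y = "Fitness (minimized)", colour = NULL,
         title = "Dung beetle optimizer trace") +
    theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param object A `beetle_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beetle_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$estimate, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "Predicted class", y = "True class", fill = "Count") +
    theme_minimal()
}

#' Plot per-class one-vs-rest metrics
#'
#' @param object A `beetle_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beetle_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), -"class",
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value, fill = .data$class)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "Percent", fill = NULL,
         title = "Per-class one-vs-rest metrics") +
    theme_minimal()
}

#' Plot an LSTM training loss trace
#'
#' @param object An `lstm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lstm_fit <- function(object, ...) {
  ggplot(object$loss_trace, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "Epoch", y = "Mean cross-entropy",
         title = "LSTM training loss") +
    theme_minimal()
}

#' Plot entropy fusion weights
#'
#' @param object A `feature_bundle`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_bundle <- function(object, ...) {
  df <- tibble::tibble(backbone = names(object$weights),
                       weight = as.numeric(object$weights))
  ggplot(df, aes(x = .data$backbone, y = .data$weight)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Entropy weight", title = "Feature fusion weights") +
    theme_minimal()
}
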