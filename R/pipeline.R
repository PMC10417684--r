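#' Hyperparameter search space for the classifier
#'
#' The optimizer searches the unit cube; each coordinate decodes to one
#' hyperparameter by an affine (continuous), log-affine (log-continuous)
#' or rounded-affine (integer) map. The default space tunes the LSTM
#' training knobs that fully determine the classification-error fitness
#' at desk scale.
#'
#' @param space Optional tibble with columns `name`, `type`
#'   (`"continuous"`, `"integer"`, `"log"`), `lower`, `upper` to
#'   override the default.
#' @return A `hyperparam_space` tibble.
#' @export
hyperparam_space <- function(space = NULL) {
  if (is.null(space)) {
    space <- tibble::tribble(
      ~name,            ~type,      ~lower, ~upper,
      "learning_rate",  "log",       1e-4,   1e-1,
      "hidden_size",    "integer",   8,      128,
      "batch_size",     "integer",   4,      32,
      "chunk_count",    "integer",   1,      8,
      "epochs",         "integer",   20,     200
    )
  }
  space <- tibble::as_tibble(space)
  stopifnot(all(c("name", "type", "lower", "upper") %in% names(space)))
  if (any(!space$type %in% c("continuous", "integer", "log"))) {
    abort("`type` must be continuous, integer or log.")
  }
  if (any(space$lower > space$upper)) abort("`lower` must not exceed `upper`.")
  if (any(space$type == "log" & space$lower <= 0)) {
    abort("log-scale hyperparameters need positive bounds.")
  }
  structure(space, class = c("hyperparam_space", class(space)))
}

#' Decode a unit-cube position into a named hyperparameter set
#'
#' @param position Numeric vector in \[0, 1\]^D, one coordinate per row
#'   of `space`. Out-of-range coordinates are clipped with a warning.
#' @param space A [hyperparam_space()].
#' @return Named list of decoded values (integers for integer fields).
#' @examples
#' decode_position(rep(0.5, 5), hyperparam_space())
#' @export
decode_position <- function(position, space = hyperparam_space()) {
  if (length(position) != nrow(space)) {
    abort("`position` length must equal the number of hyperparameters.")
  }
  if (any(position < 0 | position > 1)) {
    warn("Position outside [0, 1]; clipping.")
    position <- clip(position, 0, 1)
  }
  vals <- lapply(seq_len(nrow(space)), function(j) {
    p <- position[j]
    lo <- space$lower[j]; hi <- space$upper[j]
    switch(space$type[j],
      continuous = lo + p * (hi - lo),
      log = 10^(log10(lo) + p * (log10(hi) - log10(lo))),
      integer = as.integer(clip(round_half_up(lo + p * (hi - lo), 0), lo, hi))
    )
  })
  setNames(vals, space$name)
}

#' Tune classifier hyperparameters with the dung beetle optimizer
#'
#' The optimizer searches the unit cube; each candidate decodes to a
#' hyperparameter set, an LSTM is trained on an inner-training portion
#' of the supplied (training) data and scored by its classification
#' error rate on the inner-validation portion — the fitness the swarm
#' minimizes. Candidates whose training diverges receive `+Inf`
#' fitness. The held-out test split must never be passed here.
#'
#' @param features Numeric matrix (training samples x fused dim).
#' @param labels Training labels.
#' @param space A [hyperparam_space()].
#' @param dbo A [dbo_config()]; desk-scale default population 6,
#'   5 iterations.
#' @param inner_fraction Fraction of `features` held out for fitness
#'   validation (stratified; default 0.2).
#' @param seed Integer seed.
#' @return A `tuning_result` list: `best_hyperparams`, `best_fitness`
#'   (inner-validation error, percent), `optimizer` (the `dbo_result`),
#'   `inner_split`.
#' @export
tune_hyperparams <- function(features, labels, space = hyperparam_space(),
                             dbo = dbo_config(population_size = 6L,
                                              max_iterations = 5L),
                             inner_fraction = 0.2, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) abort("`features`/`labels` mismatch.")
  inner <- stratified_split(labels, train_fraction = 1 - inner_fraction,
                            seed = derive_seed(seed, "inner_split"))
  Xtr <- features[inner$train, , drop = FALSE]
  ytr <- labels[inner$train]
  Xva <- features[inner$test, , drop = FALSE]
  yva <- labels[inner$test]
  class_names <- sort(unique(as.character(labels)))

  objective <- function(position) {
    hp <- decode_position(position, space)
    fit <- tryCatch(
      lstm_train(Xtr, ytr, hp, seed = derive_seed(seed, "candidate"),
                 class_names = class_names),
      error = function(e) NULL
    )
    if (is.null(fit)) return(Inf)
    classification_error_rate(yva, predict(fit, Xva))
  }

  dbo$seed <- derive_seed(seed, "dbo_tune")
  bounds <- dbo_bounds(rep(0, nrow(space)), rep(1, nrow(space)))
  res <- dbo_optimize(objective, bounds, dbo)
  structure(
    list(
      best_hyperparams = decode_position(res$best_position, space),
      best_fitness = res$best_fitness,
      optimizer = res,
      inner_split = inner
    ),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("Hyperparameter tuning result (inner-validation error",
      sprintf("%.2f%%)\n", x$best_fitness))
  for (nm in names(x$best_hyperparams)) {
    cat(sprintf("  %-14s %s\n", nm, format(x$best_hyperparams[[nm]])))
  }
  invisible(x)
}

#' End-to-end pipeline configuration
#'
#' @param data Either a tibble from [generate_lung_images()] /
#'   [read_image_dataset()], or a directory path of images, or `NULL`
#'   to generate the default synthetic fixture.
#' @param backbones List of [backbone_spec()]s. Default: three
#'   fixed-seed surrogate extractors standing in for the ResNet18,
#'   DenseNet201 and Inception-ResNet-v2 slots.
#' @param split_fraction Outer train fraction (0.8 or 0.7
#'   conventionally).
#' @param table_matching Use the fixed lungdb test counts (see
#'   [stratified_split()]).
#' @param dbo A [dbo_config()] for the tuner (desk-scale default 6 x 5).
#' @param space A [hyperparam_space()].
#' @param inner_fraction Inner validation fraction for the tuner.
#' @param synthetic Arguments forwarded to [generate_lung_images()]
#'   when `data` is `NULL` (list).
#' @param output_dir Optional directory for reports, traces and the
#'   resolved configuration.
#' @param seed Master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL,
                            backbones = default_backbones(),
                            split_fraction = 0.8,
                            table_matching = FALSE,
                            dbo = dbo_config(population_size = 6L,
                                             max_iterations = 5L),
                            space = hyperparam_space(),
                            inner_fraction = 0.2,
                            synthetic = list(),
                            output_dir = NULL,
                            seed = 1L) {
  structure(
    list(data = data, backbones = backbones, split_fraction = split_fraction,
         table_matching = isTRUE(table_matching), dbo = dbo, space = space,
         inner_fraction = inner_fraction, synthetic = synthetic,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Default backbone trio for desk-scale runs
#'
#' Three surrogate extractors with distinct fixed filter seeds, one per
#' backbone slot of the fusion stage.
#'
#' @param feature_dim Pooled width of each surrogate (default 32).
#' @param input_size Input side length (default 64).
#' @return List of three [backbone_spec()]s.
#' @export
default_backbones <- function(feature_dim = 32L, input_size = 64L) {
  slots <- c("resnet18_slot", "densenet201_slot", "inception_resnet_v2_slot")
  lapply(seq_along(slots), function(i) {
    backbone_spec("surrogate_tiny", input_size = input_size,
                  feature_dim = feature_dim, seed = 100L + i,
                  alias = slots[i])
  })
}

#' Run the full classification pipeline
#'
#' Extract per-backbone features, entropy-fuse them, stratify an outer
#' train/test split, tune the classifier's hyperparameters with the
#' dung beetle optimizer on the training split only, retrain on the
#' full training split with the tuned set, and evaluate on both splits.
#' The test indices are never visible to the tuner. Bit-reproducible
#' for a fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `reports` (train/test
#'   `beetle_evaluation`s), `fit` (`lstm_fit`), `tuning`
#'   (`tuning_result`), `bundle` (`feature_bundle`), `split`, `labels`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  dataset <- stage("data", {
    if (is.null(config$data)) {
      args <- utils::modifyList(
        list(seed = derive_seed(config$seed, "generate")), config$synthetic
      )
      do.call(generate_lung_images, args)
    } else if (is.character(config$data)) {
      read_image_dataset(config$data)
    } else {
      config$data
    }
  })
  labels <- dataset$label

  bundle <- stage("extract_fuse", {
    per_backbone <- lapply(config$backbones, function(spec) {
      extract_features(dataset$image, spec)
    })
    names(per_backbone) <- vapply(config$backbones, function(s) s$alias, "")
    feature_bundle(per_backbone)
  })

  split <- stage("split", stratified_split(
    labels, train_fraction = config$split_fraction,
    seed = derive_seed(config$seed, "outer_split"),
    table_matching = config$table_matching
  ))
  stopifnot(length(intersect(split$train, split$test)) == 0L)

  tuning <- stage("tune", tune_hyperparams(
    bundle$fused[split$train, , drop = FALSE], labels[split$train],
    space = config$space, dbo = config$dbo,
    inner_fraction = config$inner_fraction,
    seed = derive_seed(config$seed, "tune")
  ))

  fit <- stage("train", lstm_train(
    bundle$fused[split$train, , drop = FALSE], labels[split$train],
    tuning$best_hyperparams,
    seed = derive_seed(config$seed, "final_train"),
    class_names = sort(unique(as.character(labels)))
  ))

  reports <- stage("evaluate", {
    pred_train <- predict(fit, bundle$fused[split$train, , drop = FALSE])
    pred_test <- predict(fit, bundle$fused[split$test, , drop = FALSE])
    cls <- sort(unique(as.character(labels)))
    list(
      train = evaluate_predictions(labels[split$train], pred_train, cls),
      test = evaluate_predictions(labels[split$test], pred_test, cls)
    )
  })

  result <- structure(
    list(reports = reports, fit = fit, tuning = tuning, bundle = bundle,
         split = split, labels = labels, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) stage("write", write_pipeline_outputs(result))
  result
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frac <- result$config$split_fraction
  write_evaluation(result$reports$train, file.path(dir, "report_train"),
                   split = sprintf("train_%.2f", frac))
  write_evaluation(result$reports$test, file.path(dir, "report_test"),
                   split = sprintf("test_%.2f", 1 - frac))
  utils::write.table(result$tuning$optimizer$history,
                     file.path(dir, "fitness_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hp <- result$tuning$best_hyperparams
  cfg_lines <- c(
    sprintf("seed=%d", result$config$seed),
    sprintf("split_fraction=%g", frac),
    sprintf("table_matching=%s", result$config$table_matching),
    sprintf("inner_fraction=%g", result$config$inner_fraction),
    sprintf("dbo_population=%d", result$config$dbo$population_size),
    sprintf("dbo_iterations=%d", result$config$dbo$max_iterations),
    vapply(names(hp), function(nm) sprintf("tuned_%s=%s", nm, format(hp[[nm]])), "")
  )
  writeLines(cfg_lines, file.path(dir, "resolved_config.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Lung image classification pipeline result\n")
  cat(sprintf("  %d samples, %d fused feature dimensions, split %.0f:%.0f\n",
              length(x$labels), ncol(x$bundle$fused),
              100 * x$config$split_fraction, 100 * (1 - x$config$split_fraction)))
  cat(sprintf("  tuned inner-validation error: %.2f%%\n", x$tuning$best_fitness))
  cat(sprintf("  test error rate: %.2f%%  test macro accuracy: %.2f%%\n",
              x$reports$test$error_rate, x$reports$test$macro$accuracy))
  invisible(x)
}
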