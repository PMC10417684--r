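# Forward pass over a batch with caches, returning mean cross-entropy
# loss, probabilities and everything backprop needs.
lstm_forward_cached <- function(xs, Y, params) {
  n <- ncol(xs[[1L]])
  state <- list(h = matrix(0, params$hidden_size, n),
                c = matrix(0, params$hidden_size, n))
  caches <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    state <- lstm_step(xs[[t]], state, params, cache = TRUE)
    caches[[t]] <- state$cache
  }
  logits <- params$Why %*% state$h + params$bhy
  probs <- softmax(logits)                       # (K x n)
  loss <- -mean(log(pmax(colSums(probs * Y), 1e-300)))
  list(loss = loss, probs = probs, caches = caches, h_final = state$h)
}

# Backpropagation through time for the peephole LSTM. `Y` is a one-hot
# (K x n) matrix. Returns gradients of the mean cross-entropy loss with
# respect to every array in `params`.
#
# Derivatives are taken through the cached gate values:
#   sigma'(a) = v(1 - v) for v = sigma(a)
#   g'(a) = (4 - g^2)/4  for g = g(a)  (g = 4*sigma - 2)
#   h'(c) = (1 - h^2)/2  for the default scaled-sigmoid output squashing
#   h'(c) = -2/(1 + c)^2 for the literal rational form
lstm_gradients <- function(xs, Y, params) {
  fwd <- lstm_forward_cached(xs, Y, params)
  n <- ncol(Y)
  Tn <- length(xs)
  H <- params$hidden_size

  grads <- lapply(params[lstm_array_names()], function(a) {
    if (is.matrix(a)) matrix(0, nrow(a), ncol(a)) else numeric(length(a))
  })
  names(grads) <- lstm_array_names()

  dlogits <- (fwd$probs - Y) / n                 # (K x n)
  grads$Why <- dlogits %*% t(fwd$h_final)
  grads$bhy <- rowSums(dlogits)
  dh <- t(params$Why) %*% dlogits
  dc <- matrix(0, H, n)

  for (t in rev(seq_len(Tn))) {
    cc <- fwd$caches[[t]]
    c_t <- cc$f * cc$cprev + cc$i * cc$g
    dhc <- if (params$literal_h) -2 / (1 + c_t)^2 else (1 - cc$hc^2) / 2

    da_o <- (dh * cc$hc) * cc$o * (1 - cc$o)
    dc <- dc + dh * cc$o * dhc + da_o * params$wco
    da_g <- (dc * cc$i) * (4 - cc$g^2) / 4
    da_i <- (dc * cc$g) * cc$i * (1 - cc$i)
    da_f <- (dc * cc$cprev) * cc$f * (1 - cc$f)

    grads$Wxi <- grads$Wxi + da_i %*% t(cc$x)
    grads$Wxf <- grads$Wxf + da_f %*% t(cc$x)
    grads$Wxc <- grads$Wxc + da_g %*% t(cc$x)
    grads$Wxo <- grads$Wxo + da_o %*% t(cc$x)
    grads$Whi <- grads$Whi + da_i %*% t(cc$hprev)
    grads$Whf <- grads$Whf + da_f %*% t(cc$hprev)
    grads$Whc <- grads$Whc + da_g %*% t(cc$hprev)
    grads$Who <- grads$Who + da_o %*% t(cc$hprev)
    grads$wci <- grads$wci + rowSums(da_i * cc$cprev)
    grads$wcf <- grads$wcf + rowSums(da_f * cc$cprev)
    grads$wco <- grads$wco + rowSums(da_o * c_t)
    grads$bi <- grads$bi + rowSums(da_i)
    grads$bf <- grads$bf + rowSums(da_f)
    grads$bc <- grads$bc + rowSums(da_g)
    grads$bo <- grads$bo + rowSums(da_o)

    dh <- t(params$Whi) %*% da_i + t(params$Whf) %*% da_f +
      t(params$Whc) %*% da_g + t(params$Who) %*% da_o
    dc <- dc * cc$f + da_i * params$wci + da_f * params$wcf
  }
  list(loss = fwd$loss, grads = grads)
}

one_hot <- function(labels, class_names) {
  Y <- matrix(0, length(class_names), length(labels))
  Y[cbind(match(as.character(labels), class_names), seq_along(labels))] <- 1
  Y
}

#' Train the peephole LSTM classifier
#'
#' Minimizes softmax cross-entropy over the encoded sequences by plain
#' mini-batch gradient descent (no adaptive optimizer, so a tuned
#' learning rate is directly interpretable). Features are standardized
#' column-wise; the centering/scaling is stored in the fit and reapplied
#' at prediction time. Deterministic for a fixed seed.
#'
#' @param features Numeric matrix (n x feature_dim).
#' @param labels Vector of class labels, length n.
#' @param hyperparams Named list: `learning_rate`, `epochs`,
#'   `batch_size`, `hidden_size`, `chunk_count`.
#' @param seed Integer seed (weight init and batch shuffling).
#' @param class_names Optional class ordering; defaults to sorted unique
#'   labels.
#' @param literal_h Use the rational output squashing (default `FALSE`).
#' @return An `lstm_fit` list: `params`, `encoding`, `class_names`,
#'   `center`, `scale`, `loss_trace` (tibble epoch/loss),
#'   `hyperparams`.
#' @export
lstm_train <- function(features, labels, hyperparams, seed = 1L,
                       class_names = NULL, literal_h = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    abort("`features` rows and `labels` length must agree.")
  }
  hp <- hyperparams
  needed <- c("learning_rate", "epochs", "batch_size", "hidden_size", "chunk_count")
  missing <- setdiff(needed, names(hp))
  if (length(missing)) abort(paste0("Missing hyperparameters: ", paste(missing, collapse = ", ")))
  if (is.null(class_names)) class_names <- sort(unique(as.character(labels)))

  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  X <- sweep(sweep(features, 2, center), 2, scale, "/")

  encoding <- sequence_encoding(ncol(X), hp$chunk_count)
  params <- lstm_init(encoding$chunk_length, hp$hidden_size,
                      length(class_names), seed = seed, literal_h = literal_h)
  Yfull <- one_hot(labels, class_names)

  n <- nrow(X)
  rng <- rng_stream(derive_seed(seed, "lstm_batches"))
  epochs <- as.integer(hp$epochs)
  batch_size <- max(1L, min(as.integer(hp$batch_size), n))
  lr <- hp$learning_rate
  arrs <- lstm_array_names()
  loss_trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- rng$sample(n)
    ep_loss <- 0
    n_batches <- ceiling(n / batch_size)
    for (b in seq_len(n_batches)) {
      idx <- ord[(((b - 1L) * batch_size + 1L):min(b * batch_size, n))]
      xs <- encode_sequences(X[idx, , drop = FALSE], encoding)
      res <- lstm_gradients(xs, Yfull[, idx, drop = FALSE], params)
      if (!is.finite(res$loss)) {
        abort(sprintf("Training diverged at epoch %d (non-finite loss).", ep))
      }
      for (a in arrs) params[[a]] <- params[[a]] - lr * res$grads[[a]]
      ep_loss <- ep_loss + res$loss * length(idx)
    }
    loss_trace[ep] <- ep_loss / n
  }

  structure(
    list(
      params = params,
      encoding = encoding,
      class_names = class_names,
      center = center,
      scale = scale,
      loss_trace = tibble::tibble(epoch = seq_len(epochs), loss = loss_trace),
      hyperparams = hp
    ),
    class = "lstm_fit"
  )
}

#' Predict classes or probabilities from a fitted LSTM
#'
#' @param object An `lstm_fit` from [lstm_train()].
#' @param features Numeric matrix (n x feature_dim), same columns as at
#'   training time.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of predicted classes, or an (n x K)
#'   probability matrix.
#' @export
predict.lstm_fit <- function(object, features, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  features <- as.matrix(features)
  X <- sweep(sweep(features, 2, object$center), 2, object$scale, "/")
  probs <- lstm_forward(X, object$encoding, object$params)
  colnames(probs) <- object$class_names
  if (type == "prob") return(probs)
  object$class_names[max.col(probs, ties.method = "first")]
}

#' @export
print.lstm_fit <- function(x, ...) {
  cat("Peephole LSTM classifier\n")
  cat("  hidden cells:", x$params$hidden_size,
      " timesteps:", x$encoding$chunk_count,
      " classes:", paste(x$class_names, collapse = ", "), "\n")
  cat("  final training loss:", format(utils::tail(x$loss_trace$loss, 1)), "\n")
  invisible(x)
}
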