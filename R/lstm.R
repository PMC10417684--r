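#' Gate activations of the peephole LSTM
#'
#' `lstm_sigmoid()` is the standard logistic function 1/(1+exp(-x)).
#' `g_activation()` is the cell-input squashing 4/(1+exp(-x)) - 2, with
#' range (-2, 2). `h_activation()` is the cell-output squashing; its
#' default form is the scaled sigmoid 2/(1+exp(-x)) - 1 = tanh(x/2) with
#' range (-1, 1). A `literal = TRUE` flag switches `h_activation()` to
#' the rational form 2/(1+x) - 1, which is non-monotone and singular at
#' x = -1; it is kept only for fidelity experiments and is never the
#' default (see the methods vignette for the rationale).
#'
#' @param x Numeric vector or matrix.
#' @param literal Use the rational form of h (default `FALSE`).
#' @return Elementwise transformed values.
#' @name lstm-activations
NULL

#' @rdname lstm-activations
#' @export
lstm_sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname lstm-activations
#' @export
g_activation <- function(x) 4 / (1 + exp(-x)) - 2

#' @rdname lstm-activations
#' @export
h_activation <- function(x, literal = FALSE) {
  if (literal) 2 / (1 + x) - 1 else 2 / (1 + exp(-x)) - 1
}

#' Sequence encoding of a fused feature vector
#'
#' Fused feature vectors are not natively sequential; to exercise the
#' recurrence they are split into `chunk_count` timesteps of
#' `chunk_length` values each, zero-padded on the right so that
#' `chunk_count * chunk_length >= feature_dim`. The same encoding must be
#' used at training and prediction time.
#'
#' @param feature_dim Length of the fused feature vector.
#' @param chunk_count Number of timesteps (default 4).
#' @return List with `chunk_count`, `chunk_length`, `feature_dim`.
#' @export
sequence_encoding <- function(feature_dim, chunk_count = 4L) {
  chunk_count <- as.integer(chunk_count)
  if (chunk_count < 1L) abort("`chunk_count` must be a positive integer.")
  if (feature_dim < 1L) abort("`feature_dim` must be a positive integer.")
  list(
    chunk_count = chunk_count,
    chunk_length = as.integer(ceiling(feature_dim / chunk_count)),
    feature_dim = as.integer(feature_dim)
  )
}

# Split rows of `features` (n x feature_dim) into a list of chunk_count
# matrices of shape (chunk_length x n), zero-padded on the right.
encode_sequences <- function(features, encoding) {
  n <- nrow(features)
  total <- encoding$chunk_count * encoding$chunk_length
  padded <- matrix(0, nrow = n, ncol = total)
  padded[, seq_len(ncol(features))] <- features
  lapply(seq_len(encoding$chunk_count), function(t) {
    cols <- ((t - 1L) * encoding$chunk_length + 1L):(t * encoding$chunk_length)
    t(padded[, cols, drop = FALSE])
  })
}

#' Initialize peephole LSTM parameters
#'
#' Input, recurrent and peephole weights for the input, forget, cell and
#' output gates, biases, and a linear softmax head. Weights are drawn
#' uniform in (-r, r) with r = 1/sqrt(fan-in); peepholes and biases start
#' at zero.
#'
#' @param input_dim Timestep input length (chunk length).
#' @param hidden_size Number of memory cells.
#' @param n_classes Number of output classes.
#' @param seed Integer seed.
#' @param literal_h Use the rational output squashing (default `FALSE`).
#' @return An `lstm_params` list of named arrays plus shape metadata.
#' @export
lstm_init <- function(input_dim, hidden_size, n_classes, seed = 1L,
                      literal_h = FALSE) {
  rng <- rng_stream(derive_seed(seed, "lstm_init"))
  mat <- function(nr, nc, fan_in) {
    r <- 1 / sqrt(fan_in)
    matrix(rng$runif(nr * nc, -r, r), nrow = nr)
  }
  h <- as.integer(hidden_size)
  p <- list(
    Wxi = mat(h, input_dim, input_dim), Whi = mat(h, h, h),
    Wxf = mat(h, input_dim, input_dim), Whf = mat(h, h, h),
    Wxc = mat(h, input_dim, input_dim), Whc = mat(h, h, h),
    Wxo = mat(h, input_dim, input_dim), Who = mat(h, h, h),
    wci = numeric(h), wcf = numeric(h), wco = numeric(h),
    bi = numeric(h), bf = numeric(h), bc = numeric(h), bo = numeric(h),
    Why = mat(as.integer(n_classes), h, h), bhy = numeric(as.integer(n_classes))
  )
  structure(
    c(p, list(input_dim = as.integer(input_dim), hidden_size = h,
              n_classes = as.integer(n_classes), literal_h = isTRUE(literal_h),
              version = "1")),
    class = "lstm_params"
  )
}

# names of the numeric arrays inside lstm_params (order fixed for
# serialization and gradient checking)
lstm_array_names <- function() {
  c("Wxi", "Whi", "Wxf", "Whf", "Wxc", "Whc", "Wxo", "Who",
    "wci", "wcf", "wco", "bi", "bf", "bc", "bo", "Why", "bhy")
}

#' One peephole LSTM step
#'
#' Gate equations with peephole (diagonal) cell connections:
#' \deqn{i_t = \sigma(W_{xi} x_t + W_{hi} h_{t-1} + w_{ci} \circ c_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf} x_t + W_{hf} h_{t-1} + w_{cf} \circ c_{t-1} + b_f)}
#' \deqn{c_t = f_t \circ c_{t-1} + i_t \circ g(W_{xc} x_t + W_{hc} h_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + w_{co} \circ c_t + b_o)}
#' \deqn{h_t = o_t \circ h(c_t)}
#'
#' @param x_t Input matrix (input_dim x batch) or vector.
#' @param state List with `h` and `c`, each (hidden x batch).
#' @param params An `lstm_params`.
#' @return New state; with `cache = TRUE`, also the gate values needed
#'   for backpropagation.
#' @param cache Keep intermediate gate values (default `FALSE`).
#' @export
lstm_step <- function(x_t, state, params, cache = FALSE) {
  if (!is.matrix(x_t)) x_t <- matrix(x_t, ncol = 1)
  hprev <- state$h
  cprev <- state$c
  if (!is.matrix(hprev)) hprev <- matrix(hprev, ncol = ncol(x_t))
  if (!is.matrix(cprev)) cprev <- matrix(cprev, ncol = ncol(x_t))
  if (any(!is.finite(hprev)) || any(!is.finite(cprev))) {
    abort("Non-finite LSTM state: training has diverged.")
  }
  i_t <- lstm_sigmoid(params$Wxi %*% x_t + params$Whi %*% hprev +
                        params$wci * cprev + params$bi)
  f_t <- lstm_sigmoid(params$Wxf %*% x_t + params$Whf %*% hprev +
                        params$wcf * cprev + params$bf)
  g_t <- g_activation(params$Wxc %*% x_t + params$Whc %*% hprev + params$bc)
  c_t <- f_t * cprev + i_t * g_t
  o_t <- lstm_sigmoid(params$Wxo %*% x_t + params$Who %*% hprev +
                        params$wco * c_t + params$bo)
  hc <- h_activation(c_t, literal = params$literal_h)
  h_t <- o_t * hc
  out <- list(h = h_t, c = c_t)
  if (cache) {
    out$cache <- list(x = x_t, hprev = hprev, cprev = cprev,
                      i = i_t, f = f_t, g = g_t, o = o_t, hc = hc)
  }
  out
}

#' Class probabilities for fused feature vectors
#'
#' Splits each fused vector into timesteps per `encoding`, runs the
#' recurrence from a zero state, and applies the linear head plus
#' softmax to the final hidden state.
#'
#' @param features Numeric matrix (n x feature_dim) or single vector.
#' @param encoding A [sequence_encoding()].
#' @param params An `lstm_params`.
#' @return Matrix (n x n_classes) of probabilities; rows sum to 1.
#' @export
lstm_forward <- function(features, encoding, params) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  xs <- encode_sequences(features, encoding)
  n <- nrow(features)
  state <- list(h = matrix(0, params$hidden_size, n),
                c = matrix(0, params$hidden_size, n))
  for (t in seq_along(xs)) state <- lstm_step(xs[[t]], state, params)
  logits <- params$Why %*% state$h + params$bhy
  t(softmax(logits))
}

#' Serialize LSTM parameters
#'
#' Writes all named arrays plus shape metadata and a version field into
#' one RDS archive; [read_lstm()] restores them bit-exactly.
#'
#' @param params An `lstm_params`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lstm <- function(params, path) {
  saveRDS(unclass(params), path)
  invisible(path)
}

#' @rdname write_lstm
#' @export
read_lstm <- function(path) {
  structure(readRDS(path), class = "lstm_params")
}
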