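test_that("gate activations match their closed forms", {
  expect_equal(lstm_sigmoid(0), 0.5)
  expect_equal(lstm_sigmoid(2), 0.8807971, tolerance = 1e-6)
  expect_equal(g_activation(0), 0)
  expect_equal(g_activation(1), 4 / (1 + exp(-1)) - 2)
  expect_equal(g_activation(1), 0.9242343, tolerance = 1e-6)
  expect_equal(g_activation(50), 2, tolerance = 1e-6)
  expect_equal(g_activation(-50), -2, tolerance = 1e-6)
  expect_equal(h_activation(0), 0)
  expect_equal(h_activation(2), tanh(1))
  # algebraic identities on random inputs
  set.seed(3)
  x <- rnorm(50, sd = 3)
  expect_equal(lstm_sigmoid(x), 1 - lstm_sigmoid(-x))
  expect_equal(h_activation(x), g_activation(x) / 2)
  expect_equal(h_activation(x), tanh(x / 2))
  # the literal rational form is preserved behind its flag
  expect_equal(h_activation(1, literal = TRUE), 0)
  expect_equal(h_activation(3, literal = TRUE), -0.5)
})

test_that("the zero-parameter step sits at its fixed point exactly", {
  p <- lstm_init(3, 4, 2, seed = 1)
  for (a in beetlefuse:::lstm_array_names()) p[[a]][] <- 0
  st <- lstm_step(rnorm(3), list(h = rep(0, 4), c = rep(0, 4)), p, cache = TRUE)
  expect_equal(as.numeric(st$cache$i), rep(0.5, 4))
  expect_equal(as.numeric(st$cache$f), rep(0.5, 4))
  expect_equal(as.numeric(st$cache$o), rep(0.5, 4))
  expect_equal(as.numeric(st$c), rep(0, 4))
  expect_equal(as.numeric(st$h), rep(0, 4))
})

test_that("a hand-evaluated step with nonzero initial cell state checks out", {
  # all weights zero, c0 = 1: i = f = 0.5, c1 = 0.5, o = 0.5,
  # h1 = 0.5 * h(0.5)
  p <- lstm_init(2, 1, 2, seed = 1)
  for (a in beetlefuse:::lstm_array_names()) p[[a]][] <- 0
  st <- lstm_step(c(0.3, -0.7), list(h = 0, c = 1), p)
  expect_equal(as.numeric(st$c), 0.5)
  expect_equal(as.numeric(st$h), 0.5 * (2 / (1 + exp(-0.5)) - 1), tolerance = 1e-12)
  expect_equal(as.numeric(st$h), 0.5 * tanh(0.25))
  expect_equal(as.numeric(st$h), 0.1224593, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  input_dim <- 5; hidden <- 4; K <- 3; n <- 2; Tn <- 3
  params <- lstm_init(input_dim, hidden, K, seed = 9)
  # perturb every array (incl. peepholes/biases) so all paths carry signal
  for (a in beetlefuse:::lstm_array_names()) {
    params[[a]] <- params[[a]] + rnorm(length(params[[a]]), sd = 0.3)
  }
  xs <- lapply(seq_len(Tn), function(t) matrix(rnorm(input_dim * n), input_dim))
  Y <- beetlefuse:::one_hot(sample(c("a", "b", "c"), n, TRUE), c("a", "b", "c"))
  res <- beetlefuse:::lstm_gradients(xs, Y, params)
  lossfn <- function(p) beetlefuse:::lstm_forward_cached(xs, Y, p)$loss
  eps <- 1e-5
  worst <- 0
  for (a in beetlefuse:::lstm_array_names()) {
    for (j in seq_along(params[[a]])) {
      p1 <- params; p1[[a]][j] <- p1[[a]][j] + eps
      p2 <- params; p2[[a]][j] <- p2[[a]][j] - eps
      num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      worst <- max(worst, abs(num - res$grads[[a]][j]) /
                     max(1e-8, abs(num) + abs(res$grads[[a]][j])))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("forward produces proper probabilities and honors the encoding", {
  set.seed(8)
  enc <- sequence_encoding(10, 4)
  expect_equal(enc$chunk_length, 3L)      # zero-padded on the right
  p <- lstm_init(enc$chunk_length, 6, 3, seed = 2)
  X <- matrix(rnorm(50), nrow = 5)
  probs <- lstm_forward(X, enc, p)
  expect_equal(dim(probs), c(5L, 3L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-9)

  # chunk_count = 1 reduces to a single-step readout
  enc1 <- sequence_encoding(10, 1)
  p1 <- lstm_init(10, 6, 3, seed = 2)
  probs1 <- lstm_forward(X, enc1, p1)
  st <- lstm_step(t(X), list(h = matrix(0, 6, 5), c = matrix(0, 6, 5)), p1)
  manual <- t(beetlefuse:::softmax(p1$Why %*% st$h + p1$bhy))
  expect_equal(probs1, manual)

  # permuting the head rows permutes output probabilities identically
  perm <- c(3, 1, 2)
  pp <- p
  pp$Why <- p$Why[perm, ]
  pp$bhy <- p$bhy[perm]
  expect_equal(lstm_forward(X, enc, pp), probs[, perm])
})

test_that("the cell state stays bounded on long random sequences", {
  set.seed(5)
  p <- lstm_init(4, 6, 2, seed = 13)
  for (a in c("Wxi", "Whi", "Wxf", "Whf", "Wxc", "Whc", "Wxo", "Who")) {
    p[[a]][] <- rnorm(length(p[[a]]), sd = 1 / sqrt(ncol(p[[a]])))
  }
  st <- list(h = matrix(0, 6, 1), c = matrix(0, 6, 1))
  max_c <- 0
  for (t in 1:1000) {
    st <- lstm_step(rnorm(4), st, p)
    max_c <- max(max_c, abs(st$c))
  }
  expect_true(is.finite(max_c))
  # with forget gates strictly below 1 the cell is a leaky accumulator of
  # a (-2, 2)-bounded input, so it cannot blow up
  expect_lt(max_c, 100)
  expect_true(all(abs(st$h) <= 1))
})

test_that("training separates a linearly separable two-class problem", {
  fx <- two_class_features()
  # independent separability oracle: multinomial logistic fit
  oracle <- suppressWarnings(stats::glm(factor(fx$y) ~ fx$X, family = binomial()))
  expect_gte(mean((oracle$fitted.values > 0.5) ==
                    (factor(fx$y) == levels(factor(fx$y))[2])), 0.95)
  hp <- list(learning_rate = 0.05, epochs = 200, batch_size = 10,
             hidden_size = 8, chunk_count = 4)
  fit <- lstm_train(fx$X, fx$y, hp, seed = 1)
  acc <- mean(predict(fit, fx$X) == fx$y)
  expect_gte(acc, 0.95)
  # epoch-averaged loss decreases overall on this separable fixture
  expect_lt(tail(fit$loss_trace$loss, 1), fit$loss_trace$loss[1])
})

test_that("zero learning rate leaves parameters untouched; seeds reproduce", {
  fx <- two_class_features(n_per = 10, dim = 6)
  hp0 <- list(learning_rate = 0, epochs = 3, batch_size = 5,
              hidden_size = 4, chunk_count = 2)
  fit0 <- lstm_train(fx$X, fx$y, hp0, seed = 4)
  init <- lstm_init(fit0$encoding$chunk_length, 4, 2, seed = 4)
  for (a in beetlefuse:::lstm_array_names()) {
    expect_identical(fit0$params[[a]], init[[a]])
  }
  hp <- utils::modifyList(hp0, list(learning_rate = 0.02))
  f1 <- lstm_train(fx$X, fx$y, hp, seed = 4)
  f2 <- lstm_train(fx$X, fx$y, hp, seed = 4)
  expect_identical(tail(f1$loss_trace$loss, 1), tail(f2$loss_trace$loss, 1))
  expect_identical(f1$params, f2$params)
})

test_that("the padding convention is shared between training and prediction", {
  fx <- two_class_features(n_per = 8, dim = 10)   # 10 not divisible by 4
  hp <- list(learning_rate = 0.02, epochs = 5, batch_size = 4,
             hidden_size = 4, chunk_count = 4)
  fit <- lstm_train(fx$X, fx$y, hp, seed = 2)
  expect_equal(fit$encoding$chunk_length, 3L)
  expect_equal(fit$encoding$chunk_count, 4L)
  # prediction runs through the stored encoding without dimension errors
  expect_length(predict(fit, fx$X), nrow(fx$X))
  # padding is material: the same features under a different chunking
  # give different probabilities (so consistency matters)
  p_alt <- lstm_forward(
    sweep(sweep(fx$X, 2, fit$center), 2, fit$scale, "/")[1:2, ],
    sequence_encoding(10, 2),
    lstm_init(5, 4, 2, seed = 2)
  )
  p_fit <- predict(fit, fx$X[1:2, ], type = "prob")
  expect_false(isTRUE(all.equal(unname(p_alt), unname(p_fit))))
})

test_that("parameters serialize and load back bit-exactly", {
  p <- lstm_init(5, 7, 3, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  write_lstm(p, path)
  q <- read_lstm(path)
  expect_identical(unclass(q), unclass(p))
  expect_equal(q$version, "1")
})
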