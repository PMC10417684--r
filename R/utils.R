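#' @importFrom rlang abort warn .data
#' @importFrom stats runif rnorm setNames
NULL

# Clip a numeric vector (or matrix) elementwise into [lower, upper].
clip <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# Round half-up to `digits` decimals. Used only at display/report time;
# all internal arithmetic keeps full precision. base::round() rounds
# half-to-even, which does not match how the metric tables are printed.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

softmax <- function(x) {
  # column-wise if a matrix
  if (is.matrix(x)) {
    z <- exp(sweep(x, 2, apply(x, 2, max)))
    sweep(z, 2, colSums(z), "/")
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

# Independent, restorable RNG sub-streams. Each stream owns a saved
# .Random.seed; drawing from one leaves every other stream (and the
# caller's RNG state) untouched, so adding draws to one behavioural role
# of the optimizer never perturbs another role's sequence.
rng_stream <- function(seed) {
  state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, globalenv())
    out <- fn(...)
    state <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    sample = function(x, size = NULL, replace = FALSE) {
      # mirror base::sample's scalar convention: sample(n) permutes 1:n
      if (is.null(size)) {
        size <- if (length(x) == 1L && is.numeric(x) && x >= 1) x else length(x)
      }
      draw(base::sample, x, size, replace)
    }
  )
}

# Derive a child seed from a master seed and a label, staying within the
# 32-bit integer range. FNV-style mix keeps distinct labels apart.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Largest-remainder apportionment of `total` into parts proportional to
# `weights`; ties broken toward earlier entries. Deterministic.
apportion <- function(total, weights) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- raw - base
  short <- total - sum(base)
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
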