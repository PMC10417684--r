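# Shared fixtures, built once per test run.

# Deterministic stand-in for an rng stream: every uniform draw returns
# `u`, every normal draw returns `z`. Lets the stochastic position
# updates be checked against hand-evaluated expectations.
fixed_rng <- function(u = 0.5, z = 1) {
  list(
    runif = function(n, min = 0, max = 1) rep(u, n),
    rnorm = function(n, mean = 0, sd = 1) rep(z, n),
    sample = function(x, size = NULL, replace = FALSE) {
      if (length(x) == 1L) x <- seq_len(x)
      if (is.null(size)) size <- length(x)
      x[seq_len(size)]
    }
  )
}

# Small default-condition synthetic dataset, shared across test files.
lung_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_lung_images(seed = 101)
    cache
  }
})

# Surrogate features of the fixture under the default backbone trio.
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- lung_fixture()
      specs <- default_backbones()
      mats <- lapply(specs, function(s) extract_features(d$image, s))
      names(mats) <- vapply(specs, function(s) s$alias, "")
      cache <<- feature_bundle(mats)
    }
    cache
  }
})

# Well-separated two-class feature clouds for classifier tests.
two_class_features <- function(n_per = 25, dim = 12, gap = 3, seed = 7) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * dim), n_per) + gap,
    matrix(rnorm(n_per * dim), n_per)
  )
  list(X = X, y = rep(c("pos", "neg"), each = n_per))
}
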