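#' Configuration for the dung beetle optimizer
#'
#' The optimizer maintains four behavioural subpopulations: ball-rolling
#' beetles (with an obstacle-triggered dancing move), brood balls updated
#' inside a shrinking spawning region anchored at the global best,
#' foraging beetles inside a shrinking region anchored at the current
#' population best, and thieving beetles drawn toward the population best
#' with steps scaled by distance to both bests.
#'
#' @param population_size Number of beetles (default 30).
#' @param max_iterations Iteration budget Tmax.
#' @param k Flexure coefficient of the rolling update, in (0, 0.2]
#'   (default 0.1).
#' @param b_roll Light-intensity constant of the rolling update, in
#'   \[0, 1\] (default 0.3).
#' @param S Thief step constant (default 0.5).
#' @param role_counts Integer 4-vector (rollers, broods, foragers,
#'   thieves) summing to `population_size`. Default 6/6/7/11 at
#'   population 30, apportioned proportionally (largest remainder)
#'   otherwise.
#' @param obstacle_probability Probability that a roller meets an
#'   obstacle in a given iteration and dances instead of rolling
#'   (default 0.1).
#' @param seed Integer seed; every stochastic element of the run flows
#'   from it through per-role sub-streams.
#' @return A `dbo_config` list.
#' @export
dbo_config <- function(population_size = 30L,
                       max_iterations = 100L,
                       k = 0.1,
                       b_roll = 0.3,
                       S = 0.5,
                       role_counts = NULL,
                       obstacle_probability = 0.1,
                       seed = 1L) {
  population_size <- as.integer(population_size)
  max_iterations <- as.integer(max_iterations)
  if (population_size < 4L) abort("`population_size` must be at least 4 (one beetle per role).")
  if (max_iterations < 1L) abort("`max_iterations` must be a positive integer.")
  if (!(k > 0 && k <= 0.2)) abort("`k` must lie in (0, 0.2].")
  if (b_roll < 0 || b_roll > 1) abort("`b_roll` must lie in [0, 1].")
  if (obstacle_probability < 0 || obstacle_probability > 1) {
    abort("`obstacle_probability` must lie in [0, 1].")
  }
  if (is.null(role_counts)) {
    role_counts <- apportion(population_size, c(6, 6, 7, 11))
  }
  role_counts <- as.integer(role_counts)
  if (length(role_counts) != 4L || any(role_counts < 0L) ||
      sum(role_counts) != population_size) {
    abort("`role_counts` must be 4 non-negative integers summing to `population_size`.")
  }
  structure(
    list(
      population_size = population_size,
      max_iterations = max_iterations,
      k = k, b_roll = b_roll, S = S,
      role_counts = setNames(role_counts, c("roller", "brood", "forager", "thief")),
      obstacle_probability = obstacle_probability,
      seed = as.integer(seed)
    ),
    class = "dbo_config"
  )
}

#' Box bounds of a search problem
#'
#' @param lower,upper Numeric vectors of equal length D with
#'   `lower <= upper` elementwise.
#' @return A `dbo_bounds` list with elements `lower`, `upper`, `dim`.
#' @export
dbo_bounds <- function(lower, upper) {
  if (length(lower) != length(upper)) abort("`lower` and `upper` must have equal length.")
  if (any(lower > upper)) abort("`lower` must not exceed `upper` in any dimension.")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 dim = length(lower)),
            class = "dbo_bounds")
}

#' Obstacle-free rolling update
#'
#' A rolling beetle steers by light: its new position is
#' `x + alpha * k * x_prev + b_roll * |x - x_worst|`, where `alpha` is +1
#' (no deviation) or -1 (deviation from the original direction), `k` is
#' the flexure coefficient and the last term simulates the change in
#' light intensity relative to the worst beetle. The caller clips the
#' result to the global bounds.
#'
#' @param position,previous_position,worst Numeric vectors of length D.
#' @param alpha Either +1 or -1.
#' @param config A [dbo_config()].
#' @return Updated position (unclipped).
#' @export
roll_obstacle_free <- function(position, previous_position, worst, alpha, config) {
  if (length(position) != length(previous_position) ||
      length(position) != length(worst)) {
    abort("`position`, `previous_position` and `worst` must share one length.")
  }
  if (!alpha %in% c(-1, 1)) abort("`alpha` must be +1 or -1.")
  position + alpha * config$k * previous_position +
    config$b_roll * abs(position - worst)
}

#' Dancing update on meeting an obstacle
#'
#' A blocked beetle dances to reorient: `x + tan(theta) * |x - x_prev|`
#' with `theta` in \[0, pi\]. At theta = 0, pi/2 or pi the position is
#' returned unchanged (no reorientation happens there; this also guards
#' the tangent pole).
#'
#' @param position,previous_position Numeric vectors of length D.
#' @param theta Dance angle in \[0, pi\].
#' @return Updated position (unclipped).
#' @export
dance <- function(position, previous_position, theta) {
  if (length(position) != length(previous_position)) {
    abort("`position` and `previous_position` must share one length.")
  }
  if (theta < 0 || theta > pi) abort("`theta` must lie in [0, pi].")
  eps <- sqrt(.Machine$double.eps)
  if (min(abs(theta - c(0, pi / 2, pi))) < eps) return(position)
  position + tan(theta) * abs(position - previous_position)
}

#' Shrinking spawning/foraging bounds
#'
#' The spawning region (anchor = global best) and the foraging region
#' (anchor = current population best) contract toward their anchor as
#' iterations progress: with `R = 1 - t/Tmax`,
#' `lower* = max(anchor * (1 - R), lower)` and
#' `upper* = min(anchor * (1 + R), upper)` elementwise. For a negative
#' anchor the naive interval can invert (lower* > upper*); the two values
#' are then swapped and re-clipped to the global bounds so a valid
#' interval containing the shrunken neighbourhood survives.
#'
#' @param anchor Numeric vector of length D.
#' @param t Current iteration, `0 <= t <= Tmax`.
#' @param Tmax Iteration budget (> 0).
#' @param global_bounds A [dbo_bounds()].
#' @return List with `lower_star`, `upper_star`, `R`.
#' @export
shrinking_bounds <- function(anchor, t, Tmax, global_bounds) {
  if (Tmax <= 0) abort("`Tmax` must be positive.")
  if (t < 0 || t > Tmax) abort("`t` must lie in [0, Tmax].")
  R <- 1 - t / Tmax
  lo <- pmax(anchor * (1 - R), global_bounds$lower)
  hi <- pmin(anchor * (1 + R), global_bounds$upper)
  inverted <- lo > hi
  if (any(inverted)) {
    tmp <- lo[inverted]
    lo[inverted] <- hi[inverted]
    hi[inverted] <- tmp
    lo[inverted] <- clip(lo[inverted], global_bounds$lower[inverted], global_bounds$upper[inverted])
    hi[inverted] <- clip(hi[inverted], global_bounds$lower[inverted], global_bounds$upper[inverted])
  }
  list(lower_star = lo, upper_star = hi, R = R)
}

#' Brood-ball update inside the spawning region
#'
#' `B_new = gbest + b1 * (B - lower*) + b2 * (B - upper*)` with `b1`,
#' `b2` independent uniform \[0,1\] vectors; the result is clipped into
#' the spawning region, since brood balls must stay inside it.
#'
#' @param brood_position Current brood-ball position.
#' @param gbest Global best position.
#' @param sbounds Reconciled shrinking bounds from [shrinking_bounds()].
#' @param rng An RNG stream (list with `$runif`); draws two length-D
#'   uniform vectors.
#' @return Updated, clipped position.
#' @export
update_brood <- function(brood_position, gbest, sbounds, rng) {
  d <- length(brood_position)
  b1 <- rng$runif(d)
  b2 <- rng$runif(d)
  out <- gbest + b1 * (brood_position - sbounds$lower_star) +
    b2 * (brood_position - sbounds$upper_star)
  clip(out, sbounds$lower_star, sbounds$upper_star)
}

#' Foraging update inside the foraging region
#'
#' `x_new = x + C1 * (x - lower*) + C2 * (x - upper*)` where `C1` is one
#' standard-normal scalar and `C2` a uniform \[0,1\] vector. The result
#' is clipped to the global bounds.
#'
#' @param position Current position.
#' @param fbounds Reconciled shrinking bounds anchored at the population
#'   best.
#' @param rng RNG stream (uses `$rnorm` once and `$runif` once).
#' @param global_bounds A [dbo_bounds()].
#' @return Updated, clipped position.
#' @export
update_forager <- function(position, fbounds, rng, global_bounds) {
  d <- length(position)
  C1 <- rng$rnorm(1)
  C2 <- rng$runif(d)
  out <- position + C1 * (position - fbounds$lower_star) +
    C2 * (position - fbounds$upper_star)
  clip(out, global_bounds$lower, global_bounds$upper)
}

#' Thieving update
#'
#' A thief moves to the population best perturbed by its distance to both
#' bests: `x_new = lbest + S * g * (|x - gbest| + |x - lbest|)` with `g`
#' a standard-normal vector and `S` a constant. Clipped to the global
#' bounds.
#'
#' @param position Current position.
#' @param gbest Global best position.
#' @param lbest Current population best position.
#' @param config A [dbo_config()] (supplies `S`).
#' @param rng RNG stream (uses `$rnorm`).
#' @param global_bounds A [dbo_bounds()].
#' @return Updated, clipped position.
#' @export
update_thief <- function(position, gbest, lbest, config, rng, global_bounds) {
  d <- length(position)
  g <- rng$rnorm(d)
  out <- lbest + config$S * g * (abs(position - gbest) + abs(position - lbest))
  clip(out, global_bounds$lower, global_bounds$upper)
}

#' Run the dung beetle optimizer
#'
#' Minimizes `objective` over a box. Each iteration the four roles update
#' in place (unconditional replacement) with all positions clipped to the
#' bounds; the best-ever solution is tracked separately so the reported
#' trace is monotone non-increasing. Candidates whose objective returns a
#' non-finite value receive `+Inf` fitness.
#'
#' @param objective Function mapping a length-D numeric vector to a
#'   scalar to be minimized.
#' @param bounds A [dbo_bounds()].
#' @param config A [dbo_config()].
#' @return A `dbo_result` list: `best_position`, `best_fitness`,
#'   `history` (tibble: iteration, best_fitness, mean_fitness),
#'   `evaluations`, `config`, `bounds`.
#' @examples
#' res <- dbo_optimize(function(x) sum((x - 2)^2),
#'                     dbo_bounds(0, 4),
#'                     dbo_config(population_size = 12, max_iterations = 40, seed = 7))
#' res$best_position
#' @export
dbo_optimize <- function(objective, bounds, config = dbo_config()) {
  d <- bounds$dim
  n <- config$population_size
  Tmax <- config$max_iterations
  roles <- rep(c("roller", "brood", "forager", "thief"), times = config$role_counts)

  streams <- list(
    init = rng_stream(derive_seed(config$seed, "init")),
    roller = rng_stream(derive_seed(config$seed, "roller")),
    brood = rng_stream(derive_seed(config$seed, "brood")),
    forager = rng_stream(derive_seed(config$seed, "forager")),
    thief = rng_stream(derive_seed(config$seed, "thief"))
  )

  eval_fit <- function(x) {
    f <- objective(x)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) Inf else as.numeric(f)
  }

  pos <- matrix(streams$init$runif(n * d), nrow = n)
  pos <- sweep(sweep(pos, 2, bounds$upper - bounds$lower, "*"), 2, bounds$lower, "+")
  prev <- pos
  fit <- apply(pos, 1, eval_fit)
  evals <- n

  best_idx <- which.min(fit)
  gbest <- pos[best_idx, ]
  gbest_fit <- fit[best_idx]

  hist_best <- numeric(Tmax + 1L)
  hist_mean <- numeric(Tmax + 1L)
  hist_best[1L] <- gbest_fit
  hist_mean[1L] <- mean(fit[is.finite(fit)])

  for (t in seq_len(Tmax)) {
    lbest <- pos[which.min(fit), ]
    worst <- pos[which.max(fit), ]
    sb <- shrinking_bounds(gbest, t, Tmax, bounds)
    fb <- shrinking_bounds(lbest, t, Tmax, bounds)
    old <- pos

    for (i in seq_len(n)) {
      xi <- pos[i, ]
      new <- switch(roles[i],
        roller = {
          if (streams$roller$runif(1) < config$obstacle_probability) {
            theta <- streams$roller$runif(1, 0, pi)
            dance(xi, prev[i, ], theta)
          } else {
            alpha <- if (streams$roller$runif(1) < 0.5) 1 else -1
            roll_obstacle_free(xi, prev[i, ], worst, alpha, config)
          }
        },
        brood = update_brood(xi, gbest, sb, streams$brood),
        forager = update_forager(xi, fb, streams$forager, bounds),
        thief = update_thief(xi, gbest, lbest, config, streams$thief, bounds)
      )
      pos[i, ] <- clip(new, bounds$lower, bounds$upper)
    }
    prev <- old

    fit <- apply(pos, 1, eval_fit)
    evals <- evals + n
    it_best <- which.min(fit)
    if (fit[it_best] < gbest_fit) {
      gbest_fit <- fit[it_best]
      gbest <- pos[it_best, ]
    }
    hist_best[t + 1L] <- gbest_fit
    hist_mean[t + 1L] <- mean(fit[is.finite(fit)])
  }

  history <- tibble::tibble(
    iteration = 0:Tmax,
    best_fitness = hist_best,
    mean_fitness = hist_mean
  )

  structure(
    list(
      best_position = gbest,
      best_fitness = gbest_fit,
      history = history,
      evaluations = evals,
      config = config,
      bounds = bounds
    ),
    class = "dbo_result"
  )
}

#' @export
print.dbo_result <- function(x, ...) {
  cat("Dung beetle optimization result\n")
  cat("  dimensions:", x$bounds$dim,
      " population:", x$config$population_size,
      " iterations:", x$config$max_iterations, "\n")
  cat("  best fitness:", format(x$best_fitness), "\n")
  cat("  objective evaluations:", x$evaluations, "\n")
  invisible(x)
}

#' Random search baseline over a box
#'
#' Uniform sampling with the same evaluation budget as a DBO run; used as
#' the null baseline when benchmarking the optimizer.
#'
#' @inheritParams dbo_optimize
#' @param n_evaluations Total objective evaluations.
#' @param seed Integer seed.
#' @return List with `best_position`, `best_fitness`, `evaluations`.
#' @export
random_search <- function(objective, bounds, n_evaluations, seed = 1L) {
  rng <- rng_stream(derive_seed(seed, "random_search"))
  best_fit <- Inf
  best_pos <- NULL
  d <- bounds$dim
  for (i in seq_len(n_evaluations)) {
    x <- bounds$lower + rng$runif(d) * (bounds$upper - bounds$lower)
    f <- objective(x)
    if (is.finite(f) && f < best_fit) {
      best_fit <- f
      best_pos <- x
    }
  }
  list(best_position = best_pos, best_fitness = best_fit, evaluations = n_evaluations)
}
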