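test_that("obstacle-free rolling follows the flexure update", {
  cfg <- dbo_config(seed = 1)
  # all-zero fixed point
  expect_equal(roll_obstacle_free(0, 0, 0, 1, cfg), 0)
  # hand evaluations, both rolling directions
  expect_equal(roll_obstacle_free(1.0, 0.5, 3.0, 1, cfg), 1.65)
  expect_equal(roll_obstacle_free(1.0, 0.5, 3.0, -1, cfg), 1.55)
  expect_error(roll_obstacle_free(c(1, 2), 1, 1, 1, cfg), "length")
  expect_error(roll_obstacle_free(1, 1, 1, 0.5, cfg), "alpha")
})

test_that("dancing reorients by the tangent and freezes at 0, pi/2, pi", {
  x <- c(2.0, -1.0)
  for (theta in c(0, pi / 2, pi)) {
    expect_identical(dance(x, c(1.0, 0.0), theta), x)
  }
  expect_equal(dance(2.0, 1.0, pi / 4), 3.0)
  # zero displacement term
  expect_equal(dance(x, x, 1.2), x)
  expect_error(dance(1, 1, -0.1), "theta")
})

test_that("spawning/foraging bounds shrink linearly and stay valid", {
  gb <- dbo_bounds(c(0, -10), c(20, 10))
  # R = 0: interval collapses onto the (clipped) anchor
  sb <- shrinking_bounds(c(5, 5), t = 100, Tmax = 100, gb)
  expect_equal(sb$R, 0)
  expect_equal(sb$lower_star, c(5, 5))
  expect_equal(sb$upper_star, c(5, 5))
  # R = 1 hand evaluation: anchor 5, global [0, 20] -> [0, 10]
  sb <- shrinking_bounds(c(5, 5), t = 0, Tmax = 100, gb)
  expect_equal(sb$R, 1)
  expect_equal(sb$lower_star[1], 0)
  expect_equal(sb$upper_star[1], 10)
  # negative anchor inverts the naive interval; reconciliation restores order
  sb <- shrinking_bounds(c(-5, -5), t = 0, Tmax = 100,
                         dbo_bounds(c(-10, -10), c(10, 10)))
  expect_true(all(sb$lower_star <= sb$upper_star))
  expect_true(all(sb$lower_star >= -10 & sb$upper_star <= 10))
  # strict linearity of the schedule; intervals nested in global bounds
  Tmax <- 50
  Rs <- vapply(0:Tmax, function(t) shrinking_bounds(c(2, 2), t, Tmax, gb)$R, 0)
  expect_equal(Rs, 1 - (0:Tmax) / Tmax)
  for (t in c(0, 13, 50)) {
    sb <- shrinking_bounds(c(2, -3), t, Tmax, gb)
    expect_true(all(sb$lower_star >= gb$lower & sb$upper_star <= gb$upper))
  }
  expect_error(shrinking_bounds(1, 0, 0, gb), "Tmax")
})

test_that("brood, forager and thief updates match hand evaluations with fixed draws", {
  gb <- dbo_bounds(-100, 100)
  rng <- fixed_rng(u = 0.5, z = 1)
  # brood: gbest + 0.5*(B - L*) + 0.5*(B - U*) = 1 + 1 - 1 = 1
  sb <- list(lower_star = 0, upper_star = 4)
  expect_equal(update_brood(2, 1, sb, rng), 1)
  # degenerate region pins the brood to gbest
  sb0 <- list(lower_star = 1, upper_star = 1)
  expect_equal(update_brood(1, 1, sb0, rng), 1)
  # forager: x + C1*(x - L) + C2*(x - U) = 3 + 2 - 1 = 4
  fb <- list(lower_star = 1, upper_star = 5)
  expect_equal(update_forager(3, fb, rng, gb), 4)
  expect_equal(update_forager(3, list(lower_star = 3, upper_star = 3), rng, gb), 3)
  # thief: lbest + S*g*(|x-gbest| + |x-lbest|) = 3 + 0.5*(1+1) = 4
  cfg <- dbo_config(seed = 1)
  expect_equal(update_thief(2, 1, 3, cfg, rng, gb), 4)
  expect_equal(update_thief(3, 3, 3, cfg, rng, gb), 3)
})

test_that("brood positions always stay inside the spawning region", {
  set.seed(4)
  gb <- dbo_bounds(rep(-5, 3), rep(5, 3))
  for (rep_i in 1:25) {
    anchor <- runif(3, -5, 5)
    sb <- shrinking_bounds(anchor, sample(0:9, 1), 10, gb)
    rng <- rng_stream(rep_i)
    out <- update_brood(runif(3, -5, 5), anchor, sb, rng)
    expect_true(all(out >= sb$lower_star - 1e-12 & out <= sb$upper_star + 1e-12))
  }
})

test_that("the optimizer recovers a one-dimensional quadratic minimum", {
  res <- dbo_optimize(function(x) (x - 2)^2, dbo_bounds(0, 4),
                      dbo_config(population_size = 30, max_iterations = 100, seed = 3))
  expect_lt(abs(res$best_position - 2), 1e-2)
})

test_that("a constant objective yields a flat trace at that constant", {
  res <- dbo_optimize(function(x) 7.5, dbo_bounds(c(-1, -1), c(1, 1)),
                      dbo_config(population_size = 8, max_iterations = 10, seed = 2))
  expect_equal(res$best_fitness, 7.5)
  expect_true(all(res$history$best_fitness == 7.5))
})

test_that("best-so-far traces are monotone and positions honor the bounds", {
  gb <- dbo_bounds(c(-2, -3, -1), c(2, 1, 4))
  for (s in 1:5) {
    # a wiggly random objective; also records every position it is handed
    seen <- list()
    obj <- function(x) {
      seen[[length(seen) + 1L]] <<- x
      sum(sin(3 * x) * x^2) + sum(x)
    }
    res <- dbo_optimize(obj, gb, dbo_config(population_size = 10,
                                            max_iterations = 15, seed = s))
    expect_true(all(diff(res$history$best_fitness) <= 0))
    pos <- do.call(rbind, seen)
    expect_true(all(sweep(pos, 2, gb$lower, ">=") & sweep(pos, 2, gb$upper, "<=")))
    expect_equal(res$best_fitness, tail(res$history$best_fitness, 1))
    expect_equal(res$evaluations, 10 * 16)
  }
})

test_that("a fixed seed reproduces the optimization bit for bit", {
  obj <- function(x) sum(x^2) + sin(x[1])
  cfg <- dbo_config(population_size = 12, max_iterations = 20, seed = 99)
  b <- dbo_bounds(c(-3, -3), c(3, 3))
  r1 <- dbo_optimize(obj, b, cfg)
  r2 <- dbo_optimize(obj, b, cfg)
  expect_identical(r1, r2)
})

test_that("non-finite objective values become +Inf fitness, not failures", {
  obj <- function(x) if (x[1] > 0) NaN else sum(x^2)
  res <- dbo_optimize(obj, dbo_bounds(-1, 1),
                      dbo_config(population_size = 8, max_iterations = 10, seed = 5))
  expect_true(is.finite(res$best_fitness))
  expect_lte(res$best_fitness, 1)
})

test_that("more iterations never worsen the median on a separable convex objective", {
  sphere <- function(x) sum(x^2)
  b <- dbo_bounds(rep(-5, 3), rep(5, 3))
  best_at <- function(Tmax) {
    vapply(1:20, function(s) {
      dbo_optimize(sphere, b, dbo_config(population_size = 15,
                                         max_iterations = Tmax,
                                         seed = s))$best_fitness
    }, 0)
  }
  expect_lte(median(best_at(60)), median(best_at(30)))
})

test_that("configuration invariants are enforced", {
  expect_error(dbo_config(k = 0.3), "k")
  expect_error(dbo_config(k = 0), "k")
  expect_error(dbo_config(role_counts = c(1, 1, 1, 1), population_size = 30), "role_counts")
  expect_error(dbo_bounds(c(0, 1), c(1, 0)), "lower")
  # proportional role apportionment keeps the reference 6/6/7/11 split at 30
  expect_equal(unname(dbo_config(population_size = 30)$role_counts), c(6L, 6L, 7L, 11L))
  expect_equal(sum(dbo_config(population_size = 13)$role_counts), 13L)
})

test_that("the optimizer trace exports as a plain-text table", {
  res <- dbo_optimize(function(x) sum(x^2), dbo_bounds(-1, 1),
                      dbo_config(population_size = 6, max_iterations = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tidy(res), path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(path)
  expect_equal(names(back), c("iteration", "best_fitness", "mean_fitness"))
  expect_equal(back$best_fitness, res$history$best_fitness)
})
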