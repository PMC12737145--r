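# Particle swarm optimizer: initialization, convergence, trace
# invariants, and agreement with exhaustive search on small lattices.

test_that("swarm initialization respects bounds, rounding, determinism", {
  sp <- search_space(
    pso_dim("a", 1, 100, kind = "integer"),
    pso_dim("b", -2, 2),
    pso_dim("c", 0.01, 10, log = TRUE)
  )
  sw <- init_swarm(sp, n_particles = 10, seed = 2)
  expect_equal(dim(sw$position), c(10, 3))
  # decoded positions honor bounds and integer constraints
  seen <- list()
  obj <- function(p) {
    seen[[length(seen) + 1]] <<- p
    0
  }
  pso_optimize(obj, sp, n_particles = 10, n_iterations = 1, seed = 2)
  for (p in seen) {
    expect_true(p$a >= 1 && p$a <= 100 && p$a == round(p$a))
    expect_true(p$b >= -2 && p$b <= 2)
    expect_true(p$c >= 0.01 && p$c <= 10)
  }
  expect_identical(init_swarm(sp, 10, seed = 2), init_swarm(sp, 10, seed = 2))
  # degenerate-but-valid single integer point
  sp1 <- search_space(pso_dim("k", 1, 2, kind = "integer"))
  r <- pso_optimize(function(p) p$k, sp1, 5, 3, seed = 1)
  expect_equal(r$best_position$k, 1L)
})

test_that("sphere objective is minimized to 1e-2 on every seed", {
  sp <- search_space(pso_dim("x", -5, 5))
  for (s in 1:20) {
    r <- pso_optimize(function(p) p$x^2, sp, n_particles = 10,
                      n_iterations = 20, seed = s)
    expect_lte(r$best_score, 1e-2)
  }
})

test_that("a particle seeded at the optimum pins g_best from iteration 1", {
  sp <- search_space(pso_dim("x", -5, 5), pso_dim("y", -5, 5))
  r <- pso_optimize(function(p) (p$x - 1)^2 + (p$y + 2)^2, sp,
                    n_particles = 6, n_iterations = 10, seed = 3,
                    init_positions = list(list(x = 1, y = -2)))
  expect_equal(r$best_score, 0)
  expect_true(all(r$trace$g_best == 0))
})

test_that("trace invariants: g_best monotone and dominated by p_best", {
  sp <- search_space(pso_dim("x", -4, 4), pso_dim("y", -4, 4))
  rosenbrock <- function(p) (1 - p$x)^2 + 5 * (p$y - p$x^2)^2
  for (s in 1:5) {
    r <- pso_optimize(rosenbrock, sp, 8, 15, seed = s)
    expect_true(all(diff(r$trace$g_best) <= 0))
    expect_true(all(r$trace$g_best <= apply(r$trace$p_best, 1, min) + 1e-12))
    expect_equal(r$best_score, min(r$trace$g_best))
  }
})

test_that("six-point lattice is solved exactly within a 10x10 budget", {
  sp <- search_space(pso_dim("x", 0, 2, kind = "integer"),
                     pso_dim("y", 0, 1, kind = "integer"))
  f <- function(p) c(3.2, 1.7, 2.9, 0.4, 5.0, 2.2)[p$x + 1 + 3 * p$y]
  for (s in 1:10) {
    r <- pso_optimize(f, sp, n_particles = 10, n_iterations = 10, seed = s)
    expect_equal(r$best_score, 0.4)
  }
})

test_that("49-point lattice minimum is found in >= 90% of 50 seeds", {
  sp <- search_space(pso_dim("x", 0, 6, kind = "integer"),
                     pso_dim("y", 0, 6, kind = "integer"))
  f <- function(p) (p$x - 4)^2 / 4 + (p$y - 2)^2 / 4 +
    2 * sin(2 * p$x) * sin(2 * p$y)
  grid <- expand.grid(x = 0:6, y = 0:6)
  fmin <- min(apply(grid, 1, function(g) f(list(x = g[1], y = g[2]))))
  hits <- vapply(1:50, function(s) {
    r <- pso_optimize(f, sp, n_particles = 10, n_iterations = 10, seed = s)
    isTRUE(all.equal(r$best_score, fmin))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("non-finite objective values are treated as +Inf with a warning", {
  sp <- search_space(pso_dim("x", -1, 1))
  f <- function(p) if (p$x < 0) NaN else p$x^2
  w <- capture_warnings(r <- pso_optimize(f, sp, 8, 10, seed = 4))
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(r$best_score))
  expect_gte(r$best_position$x, 0)
})

test_that("space construction validates names, bounds, and kinds", {
  expect_error(pso_dim("x", 5, 5), "lower < upper")
  expect_error(pso_dim("n", 1.5, 7, kind = "integer"), "integer bounds")
  expect_error(pso_dim("r", -1, 1, log = TRUE), "positive")
  expect_error(search_space(pso_dim("x", 0, 1), pso_dim("x", 0, 2)),
               "unique")
})
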