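# Particle swarm optimization over mixed integer/continuous boxes,
# written from scratch. Velocity update:
#   v <- w*v + c1*r1*(p_best - x) + c2*r2*(g_best - x)
# with positions clamped to bounds, velocities clamped to a fraction of
# the dimension range, log-scale dimensions optimized in log10 space and
# integer dimensions rounded at evaluation/reporting time.

#' Define one search-space dimension
#'
#' @param name hyperparameter name (unique within a space).
#' @param lower,upper bounds, `lower < upper`; integer dimensions require
#'   integer bounds.
#' @param kind `"continuous"` or `"integer"`.
#' @param log if `TRUE`, the dimension is sampled and updated on a log10
#'   scale (bounds must be positive).
#' @return a `pso_dim` list.
#' @export
pso_dim <- function(name, lower, upper, kind = c("continuous", "integer"),
                    log = FALSE) {
  kind <- match.arg(kind)
  if (!is.character(name) || nchar(name) == 0) stop("dimension needs a name", call. = FALSE)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("dimension '", name, "': need finite lower < upper", call. = FALSE)
  }
  if (kind == "integer" && (lower %% 1 != 0 || upper %% 1 != 0)) {
    stop("dimension '", name, "': integer dimensions need integer bounds",
         call. = FALSE)
  }
  if (log && lower <= 0) {
    stop("dimension '", name, "': log-scale requires positive bounds",
         call. = FALSE)
  }
  structure(list(name = name, lower = lower, upper = upper, kind = kind,
                 log = log), class = "pso_dim")
}

#' Assemble a hyperparameter search space
#'
#' @param ... `pso_dim` objects.
#' @return a `search_space` object (ordered list of dimensions).
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 1 && is.list(dims[[1]]) && !inherits(dims[[1]], "pso_dim")) {
    dims <- dims[[1]]
  }
  if (length(dims) == 0) stop("search space must have at least one dimension", call. = FALSE)
  stopifnot(all(vapply(dims, inherits, logical(1), "pso_dim")))
  nms <- vapply(dims, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("dimension names must be unique", call. = FALSE)
  structure(dims, names = nms, class = "search_space")
}

# Bounds in the internal (possibly log10-transformed) coordinate system.
space_bounds <- function(space) {
  lo <- vapply(space, function(d) if (d$log) log10(d$lower) else d$lower, 0)
  hi <- vapply(space, function(d) if (d$log) log10(d$upper) else d$upper, 0)
  list(lower = lo, upper = hi)
}

# Map an internal-coordinate vector to a named list of natural-scale
# values, rounding integer dimensions.
decode_position <- function(x, space) {
  vals <- lapply(seq_along(space), function(j) {
    d <- space[[j]]
    v <- if (d$log) 10^x[j] else x[j]
    v <- min(max(v, d$lower), d$upper)
    if (d$kind == "integer") as.integer(round(v)) else v
  })
  names(vals) <- names(space)
  vals
}

# Internal coordinates for a named list of natural-scale values (used for
# warm-start positions), clamped into bounds.
encode_position <- function(values, space) {
  vapply(seq_along(space), function(j) {
    d <- space[[j]]
    v <- min(max(values[[d$name]], d$lower), d$upper)
    if (d$log) log10(v) else v
  }, 0)
}

#' Initialize a particle swarm
#'
#' Positions are uniform within bounds (log-uniform on log-scale
#' dimensions); velocities uniform in +/- half the dimension range.
#' Optional `init_positions` (a list of named value lists) warm-start the
#' first particles, e.g. at a model family's library defaults.
#'
#' @param space a [search_space()].
#' @param n_particles number of particles (>= 1).
#' @param seed integer seed.
#' @param init_positions optional list of named lists of natural-scale
#'   values used for the leading particles.
#' @return list with matrices `position` and `velocity`
#'   (particles x dimensions, internal coordinates).
#' @export
init_swarm <- function(space, n_particles, seed = 1, init_positions = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  b <- space_bounds(space)
  d <- length(space)
  with_seed(seed, {
    pos <- matrix(runif(n_particles * d), nrow = n_particles)
    pos <- sweep(sweep(pos, 2, b$upper - b$lower, "*"), 2, b$lower, "+")
    vel <- matrix(runif(n_particles * d, min = -0.5, max = 0.5), nrow = n_particles)
    vel <- sweep(vel, 2, b$upper - b$lower, "*")
    if (!is.null(init_positions)) {
      k <- min(length(init_positions), n_particles)
      for (i in seq_len(k)) pos[i, ] <- encode_position(init_positions[[i]], space)
    }
    colnames(pos) <- colnames(vel) <- names(space)
    list(position = pos, velocity = vel)
  })
}

#' Particle swarm optimization
#'
#' Minimizes `objective` over the search space. The objective receives a
#' named list of natural-scale values (integers rounded) and must return
#' a scalar score; non-finite scores are treated as `+Inf` with a
#' warning. The returned `best_score` is the minimum objective value
#' evaluated anywhere during the run, and the trace records every
#' particle's personal best (`p_best`) and the global best (`g_best`)
#' after initialization (iteration 0) and after each iteration.
#'
#' @param objective function(named list) -> scalar score to minimize.
#' @param space a [search_space()].
#' @param n_particles swarm size (default 10).
#' @param n_iterations number of velocity/position updates (default 20).
#' @param seed integer seed.
#' @param inertia,cognitive,social PSO coefficients (defaults 0.7, 1.5, 1.5).
#' @param velocity_clamp velocities are clamped to this fraction of each
#'   dimension's range (default 0.5).
#' @param init_positions optional warm-start positions, see [init_swarm()].
#' @param restart_worst if `TRUE` (default), after each iteration the
#'   particle with the worst current score is re-seeded uniformly in the
#'   bounds. This anti-stagnation step keeps small discrete spaces
#'   explored after the swarm contracts; personal and global bests are
#'   unaffected.
#' @return list with `best_position` (named list), `best_score`, and
#'   `trace` (class `pso_trace`: `p_best` matrix of (n_iterations + 1) rows
#'   x n_particles columns, `g_best` vector, `best_position`).
#' @export
pso_optimize <- function(objective, space, n_particles = 10,
                         n_iterations = 20, seed = 1, inertia = 0.7,
                         cognitive = 1.5, social = 1.5,
                         velocity_clamp = 0.5, init_positions = NULL,
                         restart_worst = TRUE) {
  stopifnot(inherits(space, "search_space"))
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  b <- space_bounds(space)
  rng <- b$upper - b$lower
  vmax <- velocity_clamp * rng

  eval_one <- function(x) {
    s <- objective(decode_position(x, space))
    if (!is.finite(s)) {
      warning("objective returned a non-finite value; treated as +Inf",
              call. = FALSE)
      s <- Inf
    }
    s
  }

  swarm <- init_swarm(space, n_particles, seed = seed,
                      init_positions = init_positions)
  pos <- swarm$position
  vel <- swarm$velocity
  scores <- apply(pos, 1, eval_one)

  p_best_pos <- pos
  p_best <- scores
  g_idx <- which.min(p_best)
  g_best_pos <- pos[g_idx, ]
  g_best <- p_best[g_idx]

  p_trace <- matrix(NA_real_, nrow = n_iterations + 1, ncol = n_particles)
  g_trace <- numeric(n_iterations + 1)
  p_trace[1, ] <- p_best
  g_trace[1] <- g_best

  with_seed(seed + 1L, {
    for (it in seq_len(n_iterations)) {
      r1 <- matrix(runif(n_particles * length(space)), nrow = n_particles)
      r2 <- matrix(runif(n_particles * length(space)), nrow = n_particles)
      vel <- inertia * vel +
        cognitive * r1 * (p_best_pos - pos) +
        social * r2 * sweep(-pos, 2, g_best_pos, "+")
      vel <- pmin(pmax(vel, matrix(-vmax, n_particles, length(space), byrow = TRUE)),
                  matrix(vmax, n_particles, length(space), byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(b$lower, n_particles, length(space), byrow = TRUE)),
                  matrix(b$upper, n_particles, length(space), byrow = TRUE))
      scores <- apply(pos, 1, eval_one)
      improved <- scores < p_best
      p_best[improved] <- scores[improved]
      p_best_pos[improved, ] <- pos[improved, , drop = FALSE]
      g_idx <- which.min(p_best)
      if (p_best[g_idx] < g_best) {
        g_best <- p_best[g_idx]
        g_best_pos <- p_best_pos[g_idx, ]
      }
      p_trace[it + 1, ] <- p_best
      g_trace[it + 1] <- g_best
      # anti-stagnation restart: re-seed the currently worst particle so
      # small discrete spaces keep being explored after the swarm
      # contracts (its personal best is retained, so g_best stays
      # monotone and the update rule is untouched for the rest)
      if (restart_worst && it < n_iterations) {
        worst <- which.max(scores)
        pos[worst, ] <- b$lower + runif(length(space)) * rng
        vel[worst, ] <- (runif(length(space)) - 0.5) * rng
      }
    }
  })

  best_position <- decode_position(g_best_pos, space)
  trace <- structure(list(p_best = p_trace, g_best = g_trace,
                          best_position = best_position),
                     class = "pso_trace")
  list(best_position = best_position, best_score = g_best, trace = trace)
}
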