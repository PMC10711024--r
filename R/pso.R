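#' Configuration for the standard particle swarm optimizer
#'
#' Defaults follow the hybrid ANN-PSO setup used for the extraction
#' study: 40 particles, acceleration constants \eqn{c_1 = c_2 = 0.5},
#' inertia weight varying linearly from 0.4 to 0.6 over the
#' generations, and a fixed budget of 2000 generations as the sole
#' stopping rule.
#'
#' @param bounds 2-row matrix (rows \code{low}, \code{high}) or list of
#'   length-2 vectors giving per-dimension search bounds.
#' @param swarm_size Number of particles (>= 2; default 40).
#' @param c1,c2 Cognitive and social acceleration constants
#'   (default 0.5 each).
#' @param inertia Length-2 vector: inertia weight at the first and last
#'   generation, interpolated linearly (default \code{c(0.4, 0.6)}).
#' @param max_generations Number of generations to run (default 2000).
#' @param seed Integer seed for initialization and the per-update
#'   uniform random draws.
#'
#' @return A list of class \code{"pso_config"}.
#' @export
pso_config <- function(bounds, swarm_size = 40L, c1 = 0.5, c2 = 0.5,
                       inertia = c(0.4, 0.6), max_generations = 2000L,
                       seed = 1L) {
  if (is.list(bounds)) bounds <- vapply(bounds, as.numeric, numeric(2))
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L) stop("'bounds' must have rows low, high")
  if (any(bounds[1, ] >= bounds[2, ]))
    stop("each dimension needs low < high bounds")
  if (swarm_size < 2L) stop("'swarm_size' must be >= 2")
  if (c1 < 0 || c2 < 0) stop("acceleration constants must be >= 0")
  if (max_generations < 1L) stop("'max_generations' must be >= 1")
  if (length(inertia) != 2L) stop("'inertia' must give start and end weights")
  structure(list(bounds = bounds, swarm_size = as.integer(swarm_size),
                 c1 = c1, c2 = c2, inertia = inertia,
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "pso_config")
}

eval_objective <- function(objective, X) {
  v <- tryCatch(objective(X), error = function(e) NULL)
  if (is.numeric(v) && length(v) == nrow(X)) return(as.numeric(v))
  apply(X, 1L, function(row) as.numeric(objective(row)))
}

check_finite_fitness <- function(fit, X) {
  bad <- which(!is.finite(fit))
  if (length(bad)) {
    stop(sprintf("objective returned a non-finite value at position (%s)",
                 paste(signif(X[bad[1L], ], 6), collapse = ", ")))
  }
  fit
}

#' Initialize a particle swarm
#'
#' Positions are uniform within bounds; velocities uniform in
#' \eqn{\pm 0.2} times the per-dimension range.
#'
#' @param objective Objective function (see \code{\link{pso_optimize}}).
#' @param config A \code{\link{pso_config}}.  The caller is responsible
#'   for seeding the RNG.
#' @return A list of class \code{"swarm_state"}.
#' @export
swarm_init <- function(objective, config) {
  d <- ncol(config$bounds)
  n <- config$swarm_size
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  rng <- hi - lo
  X <- sweep(sweep(matrix(stats::runif(n * d), n, d), 2, rng, `*`),
             2, lo, `+`)
  V <- sweep(matrix(stats::runif(n * d, -1, 1), n, d), 2, 0.2 * rng, `*`)
  fit <- check_finite_fitness(eval_objective(objective, X), X)
  g <- which.max(fit)
  structure(list(positions = X, velocities = V,
                 pbest_pos = X, pbest_fit = fit,
                 gbest_pos = X[g, ], gbest_fit = fit[g],
                 generation = 0L),
            class = "swarm_state")
}

#' Advance a particle swarm by one generation
#'
#' Velocity update
#' \eqn{v \leftarrow w v + c_1 r_1 (p - x) + c_2 r_2 (g - x)} with
#' independent uniform draws \eqn{r_1, r_2} per particle and per
#' dimension, followed by the position update \eqn{x \leftarrow x + v}.
#' Positions are clamped to the bounds, with the velocity zeroed on any
#' clamped dimension; personal and global bests are then refreshed
#' (maximization).
#'
#' @param state A \code{swarm_state}.
#' @param objective Objective function.
#' @param w Inertia weight for this generation.
#' @param config A \code{\link{pso_config}}.
#' @return The updated \code{swarm_state}.
#' @export
pso_step <- function(state, objective, w, config) {
  X <- state$positions; V <- state$velocities
  n <- nrow(X); d <- ncol(X)
  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  G <- matrix(state$gbest_pos, n, d, byrow = TRUE)
  V <- w * V + config$c1 * r1 * (state$pbest_pos - X) +
    config$c2 * r2 * (G - X)
  X <- X + V
  lo <- matrix(config$bounds[1, ], n, d, byrow = TRUE)
  hi <- matrix(config$bounds[2, ], n, d, byrow = TRUE)
  clamped <- X < lo | X > hi
  X <- pmin(pmax(X, lo), hi)
  V[clamped] <- 0
  fit <- check_finite_fitness(eval_objective(objective, X), X)
  improved <- fit > state$pbest_fit
  state$pbest_pos[improved, ] <- X[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fit[improved]
  g <- which.max(state$pbest_fit)
  state$positions <- X
  state$velocities <- V
  state$gbest_pos <- state$pbest_pos[g, ]
  state$gbest_fit <- state$pbest_fit[g]
  state$generation <- state$generation + 1L
  state
}

#' Maximize an objective with standard particle swarm optimization
#'
#' Runs exactly \code{config$max_generations} generations (the fixed
#' generation budget is the sole stopping rule) and returns the best
#' position found.  Maximization is the native sense; minimize by
#' negating the objective.
#'
#' @param objective Either a function mapping a length-\eqn{d} numeric
#'   vector to a scalar, or a vectorized function mapping an
#'   \eqn{n \times d} matrix to an \eqn{n}-vector (detected
#'   automatically; the vectorized form is much faster).
#' @param config A \code{\link{pso_config}} whose bounds define
#'   \eqn{d}.
#'
#' @return An object of class \code{"swarm_result"}: list with
#'   \code{best_position}, \code{best_fitness}, \code{history}
#'   (global-best fitness per generation), \code{evaluations},
#'   \code{config}.
#'
#' @examples
#' cfg <- pso_config(rbind(rep(-5, 3), rep(5, 3)),
#'                   max_generations = 100, seed = 1)
#' res <- pso_optimize(function(x) -sum(x^2), cfg)
#' res$best_position   # near the origin
#' @export
pso_optimize <- function(objective, config) {
  stopifnot(inherits(config, "pso_config"))
  set.seed(config$seed)
  state <- swarm_init(objective, config)
  gmax <- config$max_generations
  history <- numeric(gmax)
  w0 <- config$inertia[1]; w1 <- config$inertia[2]
  for (g in seq_len(gmax)) {
    w <- if (gmax > 1L) w0 + (w1 - w0) * (g - 1) / (gmax - 1) else w0
    state <- pso_step(state, objective, w, config)
    history[g] <- state$gbest_fit
  }
  structure(
    list(best_position = state$gbest_pos,
         best_fitness = state$gbest_fit,
         history = history,
         evaluations = config$swarm_size * (gmax + 1L),
         config = config),
    class = "swarm_result"
  )
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("PSO result after %d generations (%d evaluations)\n",
              length(x$history), x$evaluations))
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "),
      "\n  best fitness: ", signif(x$best_fitness, 8), "\n")
  invisible(x)
}
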