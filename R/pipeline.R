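#' Specify the multi-response fitness aggregation
#'
#' The hybrid optimization maximizes all five responses jointly through
#' a scalar fitness: a weighted sum of min-max-normalized predicted
#' responses,
#' \deqn{f(x) = \sum_r w_r \frac{\hat y_r(x) - \min_r}{\max_r - \min_r}.}
#' By default all responses carry equal weight 1 and the normalization
#' ranges are taken from the model (the surrogate's training response
#' ranges, or the surface values over the design region).
#'
#' @param weights Non-negative per-response weights, not all zero
#'   (default equal).
#' @param ranges Optional 2-row matrix (rows \code{min}, \code{max},
#'   one column per response) of normalization ranges; must be
#'   non-degenerate.
#' @param responses Response names (default
#'   \code{\link{response_names}()}).
#'
#' @return A list of class \code{"fitness_spec"}.
#' @export
fitness_spec <- function(weights = NULL, ranges = NULL,
                         responses = response_names()) {
  if (is.null(weights)) weights <- rep(1, length(responses))
  if (length(weights) != length(responses))
    stop("one weight per response required")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  if (!is.null(ranges)) {
    ranges <- as.matrix(ranges)
    if (nrow(ranges) != 2L || ncol(ranges) != length(responses))
      stop("'ranges' must be a 2 x n_responses matrix (min, max)")
    if (any(ranges[2, ] <= ranges[1, ]))
      stop("degenerate normalization range")
  }
  structure(list(weights = as.numeric(weights), ranges = ranges,
                 responses = responses),
            class = "fitness_spec")
}

# A prediction closure over natural-unit points: matrix n x 3 -> n x 5.
model_predictor <- function(model) {
  if (inherits(model, "trained_surrogate")) {
    list(
      predict = function(X) predict(model, X),
      responses = model$responses,
      factors = {
        f <- uae_factors()
        names(f) <- names(f)
        f
      },
      default_ranges = rbind(model$output_scaler$min,
                             model$output_scaler$max)
    )
  } else if (inherits(model, "uae_ground_truth") ||
             (is.list(model) &&
              all(vapply(model, inherits, logical(1), "quadratic_surface")))) {
    surfaces <- if (inherits(model, "uae_ground_truth")) model$surfaces
                else model
    factors <- surfaces[[1L]]$factors
    pred <- function(X) {
      coded <- code_point(factors, X)
      if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1L)
      out <- vapply(surfaces, evaluate_surface, numeric(nrow(coded)),
                    coded = coded)
      if (!is.matrix(out)) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, names(surfaces)))
      out
    }
    # surface values over the coded design points give the natural
    # normalization window for each response
    grid <- coded_matrix(make_bbd(factors, center_reps = 1L))
    vals <- vapply(surfaces, evaluate_surface, numeric(nrow(grid)),
                   coded = grid)
    list(predict = pred, responses = names(surfaces), factors = factors,
         default_ranges = rbind(apply(vals, 2, min), apply(vals, 2, max)))
  } else {
    stop("'model' must be a trained_surrogate or a list of quadratic_surface")
  }
}

#' Compose a scalar fitness over natural-unit factor settings
#'
#' @param model A \code{trained_surrogate}, a
#'   \code{\link{uae_ground_truth}} bundle, or a named list of five
#'   \code{\link{quadratic_surface}}s.
#' @param spec A \code{\link{fitness_spec}} (default: equal weights,
#'   model-derived normalization ranges).
#'
#' @return A function mapping a natural-unit point (length-3 vector) or
#'   matrix of points to the scalar fitness (vectorized over rows).
#' @export
make_fitness <- function(model, spec = NULL) {
  mp <- model_predictor(model)
  if (is.null(spec)) spec <- fitness_spec(responses = mp$responses)
  if (!identical(length(spec$weights), length(mp$responses)))
    stop("fitness spec and model disagree on the number of responses")
  ranges <- if (is.null(spec$ranges)) mp$default_ranges else spec$ranges
  if (any(ranges[2, ] <= ranges[1, ]))
    stop("degenerate normalization range")
  w <- spec$weights
  lo <- ranges[1, ]; span <- ranges[2, ] - ranges[1, ]
  function(x) {
    single <- is.null(dim(x))
    X <- if (single) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
    P <- mp$predict(X)
    val <- drop(sweep(sweep(P, 2, lo, `-`), 2, span, `/`) %*% w)
    if (single) unname(val) else unname(as.numeric(val))
  }
}

#' Optimize the extraction process with the hybrid surrogate-PSO scheme
#'
#' Composes the scalar fitness (\code{\link{make_fitness}}) over the
#' model's predictions and maximizes it with the particle swarm
#' optimizer over the natural-unit factor box (defaulting to the
#' declared factor ranges).
#'
#' @param model A \code{trained_surrogate}, \code{uae_ground_truth}, or
#'   list of \code{quadratic_surface}s.
#' @param spec A \code{\link{fitness_spec}} (default equal weights).
#' @param config A \code{\link{pso_config}}; its bounds default to the
#'   model's factor ranges when \code{config} is \code{NULL}.
#' @param seed Seed used when \code{config} is \code{NULL}.
#' @param generations,swarm_size Swarm settings used when \code{config}
#'   is \code{NULL} (defaults 2000 and 40).
#'
#' @return An object of class \code{"optimization_report"}: list with
#'   \code{optimum} (natural units), \code{predicted} (5 responses at
#'   the optimum), \code{fitness}, \code{experimental} and
#'   \code{percent_error} (filled by \code{\link{validate_report}}),
#'   \code{swarm} (the \code{swarm_result}), \code{fitness_spec},
#'   \code{config}.
#'
#' @examples
#' gt <- uae_ground_truth()
#' cfg <- pso_config(rbind(c(10, 30, 10), c(30, 40, 30)),
#'                   max_generations = 150, seed = 2)
#' rep <- optimize_process(gt, config = cfg)
#' rep$optimum
#' @export
optimize_process <- function(model, spec = NULL, config = NULL, seed = 1L,
                             generations = 2000L, swarm_size = 40L) {
  mp <- model_predictor(model)
  fit_fun <- make_fitness(model, spec)
  if (is.null(spec)) spec <- fitness_spec(responses = mp$responses)
  if (is.null(config)) {
    f <- mp$factors
    bounds <- rbind(vapply(f, `[[`, numeric(1), "low"),
                    vapply(f, `[[`, numeric(1), "high"))
    config <- pso_config(bounds, swarm_size = swarm_size,
                         max_generations = generations, seed = seed)
  }
  if (all(config$bounds[1, ] == config$bounds[2, ])) {
    # degenerate box: the single feasible point is the optimum
    x <- config$bounds[1, ]
    swarm <- NULL
    best <- x
    best_fit <- fit_fun(x)
  } else {
    swarm <- pso_optimize(fit_fun, config)
    best <- swarm$best_position
    best_fit <- swarm$best_fitness
  }
  predicted <- mp$predict(matrix(best, nrow = 1L))[1L, ]
  names(predicted) <- mp$responses
  factor_names <- vapply(mp$factors, `[[`, character(1), "name")
  structure(
    list(optimum = stats::setNames(best, factor_names),
         predicted = predicted, fitness = best_fit,
         experimental = NULL, percent_error = NULL,
         swarm = swarm, fitness_spec = spec, config = config),
    class = "optimization_report"
  )
}

#' Percent prediction error against an experimental value
#'
#' \eqn{100 |e - p| / |e|} with the experimental value \eqn{e} as the
#' denominator (the convention that reproduces the published
#' validation-error row), rounded to \code{digits} decimals for
#' reporting.
#'
#' @param experimental,predicted Numeric vectors (recycled); every
#'   experimental value must be non-zero.
#' @param digits Decimal places for reporting (default 2); use
#'   \code{NULL} for full precision.
#' @return Numeric vector of percent errors (>= 0).
#'
#' @examples
#' percent_error(39.32, 38.41)   # 2.31
#' @export
percent_error <- function(experimental, predicted, digits = 2) {
  if (any(experimental == 0))
    stop("percent error undefined for a zero experimental value")
  pe <- 100 * abs(experimental - predicted) / abs(experimental)
  if (is.null(digits)) pe else round(pe, digits)
}

#' Attach experimental validation to an optimization report
#'
#' @param report An \code{optimization_report}.
#' @param experimental Length-5 vector of measured responses at the
#'   reported optimum.
#' @return The report with \code{experimental} and \code{percent_error}
#'   (2-decimal) filled in.
#' @export
validate_report <- function(report, experimental) {
  stopifnot(inherits(report, "optimization_report"))
  if (length(experimental) != length(report$predicted))
    stop("experimental vector length must match the predicted responses")
  report$experimental <- stats::setNames(as.numeric(experimental),
                                         names(report$predicted))
  report$percent_error <- percent_error(report$experimental,
                                        report$predicted)
  report
}

#' @export
print.optimization_report <- function(x, ...) {
  cat("Hybrid surrogate-PSO optimization report\n")
  cat("Optimum (natural units, rounded):",
      paste(sprintf("%s = %g", names(x$optimum), round(x$optimum)),
            collapse = ", "), "\n")
  tab <- data.frame(Predicted = round(x$predicted, 2))
  if (!is.null(x$experimental)) {
    tab$Experimental <- round(x$experimental, 2)
    tab$`% Error` <- x$percent_error
  }
  print(t(tab))
  invisible(x)
}

#' Serialize an optimization report to JSON
#'
#' Full-precision optimum and predictions, plus the swarm configuration
#' and seed for provenance, are written; the human-readable rounding in
#' \code{print} is not applied.
#'
#' @param report An \code{optimization_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "optimization_report"))
  obj <- list(
    optimum = as.list(report$optimum),
    predicted = as.list(report$predicted),
    fitness = report$fitness,
    experimental = if (is.null(report$experimental)) NULL
                   else as.list(report$experimental),
    percent_error = if (is.null(report$percent_error)) NULL
                    else as.list(report$percent_error),
    config = list(
      swarm_size = report$config$swarm_size,
      c1 = report$config$c1, c2 = report$config$c2,
      inertia = report$config$inertia,
      max_generations = report$config$max_generations,
      seed = report$config$seed,
      bounds_low = report$config$bounds[1, ],
      bounds_high = report$config$bounds[2, ],
      boundary_handling = "clamp with velocity zeroing",
      initialization = "uniform positions; velocities +/-0.2 range"),
    weights = report$fitness_spec$weights
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
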