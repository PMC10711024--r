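#' Define a process factor
#'
#' A factor specification holds the natural-unit range of one process
#' variable together with the affine coding that maps it onto the
#' \eqn{[-1, +1]} interval used by the Box-Behnken design and the coded
#' quadratic response surfaces.
#'
#' @param name Factor name (e.g. \code{"time"}).
#' @param low,high Natural-unit range endpoints; \code{low < high}.  The
#'   design center is \code{(low + high)/2} and the coded half-range is
#'   \code{(high - low)/2}.
#' @param units Free-text unit label (e.g. \code{"min"}).
#'
#' @return An object of class \code{"factor_spec"}: a list with elements
#'   \code{name}, \code{low}, \code{high}, \code{units}, \code{center},
#'   \code{half_range}.
#'
#' @examples
#' factor_spec("time", 10, 30, "min")
#' @export
factor_spec <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(low) || !is.finite(high))
    stop("factor bounds must be finite")
  if (low >= high)
    stop("'low' must be strictly less than 'high'")
  structure(
    list(name = name, low = low, high = high, units = units,
         center = (low + high) / 2, half_range = (high - low) / 2),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s: %g to %g %s (center %g, half-range %g)\n",
              x$name, x$low, x$high, x$units, x$center, x$half_range))
  invisible(x)
}

#' The ultrasound-assisted extraction process factors
#'
#' The three factors governing ultrasound-assisted extraction of
#' phytochemicals from green coconut shell: sonication time (10-30 min),
#' bath temperature (30-40 degrees C), and solid-solvent ratio, encoded
#' by the denominator X of the 1:X g/ml ratio (10-30).
#'
#' @return A list of three \code{\link{factor_spec}} objects named
#'   \code{time}, \code{temperature}, \code{ratio}.
#'
#' @examples
#' uae_factors()
#' @export
uae_factors <- function() {
  list(
    time        = factor_spec("time", 10, 30, "min"),
    temperature = factor_spec("temperature", 30, 40, "degC"),
    ratio       = factor_spec("ratio", 10, 30, "g/ml denominator")
  )
}

check_factors <- function(factors) {
  if (length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("'factors' must be a list of exactly 3 factor_spec objects")
  factors
}

#' Convert natural factor settings to coded units
#'
#' Applies the affine coding \code{coded = (natural - center)/half_range}
#' per factor, so the design range maps onto \eqn{[-1, +1]}.
#' \code{decode_point} is the exact inverse.
#'
#' @param factors A list of 3 \code{\link{factor_spec}} objects.
#' @param x A numeric vector of length 3, or a matrix/data frame with 3
#'   columns (one row per point), in natural units for \code{code_point}
#'   and coded units for \code{decode_point}.
#'
#' @return Numeric vector or matrix of the same shape as \code{x}.
#'   \code{code_point} warns (but proceeds) when a value lies outside the
#'   declared factor range.
#'
#' @examples
#' f <- uae_factors()
#' code_point(f, c(20, 35, 20))      # design center -> (0, 0, 0)
#' decode_point(f, c(-1, 0, 1))      # -> c(10, 35, 30)
#' @export
code_point <- function(factors, x) {
  check_factors(factors)
  x <- as_point_matrix(x)
  if (!all(is.finite(x))) stop("non-finite factor values")
  ctr <- vapply(factors, `[[`, numeric(1), "center")
  hr  <- vapply(factors, `[[`, numeric(1), "half_range")
  lo  <- vapply(factors, `[[`, numeric(1), "low")
  hi  <- vapply(factors, `[[`, numeric(1), "high")
  out_of_range <- sweep(x, 2, lo, `<`) | sweep(x, 2, hi, `>`)
  if (any(out_of_range))
    warning("natural values outside the declared factor range")
  coded <- sweep(sweep(x, 2, ctr, `-`), 2, hr, `/`)
  drop_point(coded)
}

#' @rdname code_point
#' @export
decode_point <- function(factors, x) {
  check_factors(factors)
  x <- as_point_matrix(x)
  if (!all(is.finite(x))) stop("non-finite factor values")
  ctr <- vapply(factors, `[[`, numeric(1), "center")
  hr  <- vapply(factors, `[[`, numeric(1), "half_range")
  drop_point(sweep(sweep(x, 2, hr, `*`), 2, ctr, `+`))
}

as_point_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a factor point must have 3 coordinates")
    x <- matrix(as.numeric(x), nrow = 1L, dimnames = list(NULL, names(x)))
    attr(x, "was_vector") <- TRUE
    return(x)
  }
  if (ncol(x) != 3L) stop("factor points must have 3 columns")
  storage.mode(x) <- "double"
  x
}

drop_point <- function(x) {
  if (isTRUE(attr(x, "was_vector"))) return(drop(x[1L, , drop = TRUE]))
  attr(x, "was_vector") <- NULL
  x
}

#' Generate a three-factor Box-Behnken design
#'
#' Builds the standard 3-factor Box-Behnken design: 12 edge-midpoint
#' runs (all four \eqn{\pm 1} combinations over each of the three factor
#' pairs, with the third factor held at its center) plus
#' \code{center_reps} replicates of the all-center run.  With the default
#' 6 center replicates the design has 18 runs, leaving 8 residual
#' degrees of freedom for a 10-coefficient quadratic model.
#'
#' @param factors A list of 3 \code{\link{factor_spec}} objects
#'   (default \code{\link{uae_factors}()}).
#' @param center_reps Number of center-point replicates (>= 1; default 6).
#' @param shuffle_seed If non-\code{NULL}, the run order is permuted with
#'   this seed; by default runs are in deterministic standard order
#'   (edge runs in factor-pair order, centers last).
#'
#' @return A \code{data.frame} of class \code{"bbd_design"} with columns
#'   \code{run_id}, the three natural-unit factor columns (named after
#'   the factors), and coded columns \code{coded_A}, \code{coded_B},
#'   \code{coded_C}.  The factor list is attached as attribute
#'   \code{"factors"}.
#'
#' @examples
#' d <- make_bbd(center_reps = 6)
#' nrow(d)            # 18
#' colSums(d[, c("coded_A", "coded_B", "coded_C")])  # balance
#' @export
make_bbd <- function(factors = uae_factors(), center_reps = 6L,
                     shuffle_seed = NULL) {
  check_factors(factors)
  if (!is.numeric(center_reps) || center_reps < 1 ||
      center_reps != round(center_reps))
    stop("'center_reps' must be a positive whole number")
  pm <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  edge <- do.call(rbind, lapply(pairs, function(p) {
    m <- matrix(0, nrow = 4L, ncol = 3L)
    m[, p[1L]] <- pm$a
    m[, p[2L]] <- pm$b
    m
  }))
  coded <- rbind(edge, matrix(0, nrow = center_reps, ncol = 3L))
  if (!is.null(shuffle_seed)) {
    ord <- local({
      set.seed(shuffle_seed)
      sample.int(nrow(coded))
    })
    coded <- coded[ord, , drop = FALSE]
  }
  natural <- decode_point(factors, coded)
  d <- data.frame(run_id = seq_len(nrow(coded)))
  for (j in 1:3) d[[factors[[j]]$name]] <- natural[, j]
  d$coded_A <- coded[, 1L]
  d$coded_B <- coded[, 2L]
  d$coded_C <- coded[, 3L]
  structure(d, factors = factors, class = c("bbd_design", "data.frame"))
}

#' Extract the coded design matrix from a design table
#'
#' @param design A \code{bbd_design} (or any data frame with columns
#'   \code{coded_A}, \code{coded_B}, \code{coded_C}).
#' @return A numeric matrix with columns \code{A}, \code{B}, \code{C}.
#' @export
coded_matrix <- function(design) {
  need <- c("coded_A", "coded_B", "coded_C")
  if (!all(need %in% names(design)))
    stop("design lacks coded columns coded_A, coded_B, coded_C")
  m <- as.matrix(design[, need])
  colnames(m) <- c("A", "B", "C")
  m
}

#' Read and write design tables as CSV
#'
#' The on-disk layout is a plain CSV with columns \code{run_id}, the
#' natural factor columns, \code{coded_A}, \code{coded_B},
#' \code{coded_C}, then any response columns (conventionally
#' \code{yield_pct}, \code{phenols_gae}, \code{flavonoids_qe},
#' \code{tannins_tae}, \code{antioxidant_pct}).
#'
#' @param design A \code{bbd_design} data frame.
#' @param path File path.
#' @param factors Factor specifications to re-attach on read
#'   (default \code{\link{uae_factors}()}).
#' @return \code{read_design} returns a \code{bbd_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, factors = uae_factors()) {
  d <- utils::read.csv(path)
  structure(d, factors = check_factors(factors),
            class = c("bbd_design", "data.frame"))
}

#' Names of the five extraction responses
#'
#' Column-name convention for the five measured responses: extraction
#' yield (%), total phenolics (mg GAE/g), total flavonoids (mg QE/g),
#' total tannins (mg TAE/g), and DPPH antioxidant activity (%).
#'
#' @return Character vector of length 5.
#' @export
response_names <- function() {
  c("yield_pct", "phenols_gae", "flavonoids_qe", "tannins_tae",
    "antioxidant_pct")
}
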