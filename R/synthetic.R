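#' Published coded response surfaces and residual noise levels
#'
#' The five coded-factor quadratic surfaces reported for
#' ultrasound-assisted extraction from green coconut shell, one per
#' response (extraction yield %, total phenolics GAE/g, total
#' flavonoids QE/g, total tannins TAE/g, DPPH antioxidant activity %),
#' together with the residual standard deviation reported for each
#' fitted model.  These serve as the ground truth for the synthetic
#' Box-Behnken data generator, standing in for the unpublished raw
#' 18-run table.
#'
#' @return A list of class \code{"uae_ground_truth"} with elements
#'   \code{surfaces} (named list of five
#'   \code{\link{quadratic_surface}}s) and \code{noise_sd} (named
#'   numeric vector of per-response residual SDs).
#'
#' @examples
#' gt <- uae_ground_truth()
#' evaluate_surface(gt$surfaces$yield_pct, c(0, 0, 0))
#' @export
uae_ground_truth <- function() {
  f <- uae_factors()
  coefs <- list(
    #                 int       A        B        C       AB      AC      BC       A2        B2        C2
    yield_pct = c(26.4683, -3.22,    -0.3175, 2.9475, 1.855,  0.04,   3.995,  -0.504167, -1.41917, 3.65083),
    phenols_gae = c(18.0467, -4.01575, -1.08575, 2.3025, 5.399, -0.5325, 6.7475, 0.786167, -3.94883, 7.70967),
    flavonoids_qe = c(13.0433, -3.9825, -1.0775, 2.365, 5.39, -0.53, 6.825, 0.770833, -3.94917, 7.77083),
    tannins_tae = c(122.83, -8.27, -1.47, 3.0325, 17.175, -1.945, 14.075, -6.84, -20.915, 12.86),
    antioxidant_pct = c(56.4683, -3.245, -0.2625, 2.9425, 1.805, 0.04, 4.005, -0.449167, -1.52417, 3.59583)
  )
  surfaces <- lapply(names(coefs), function(nm)
    quadratic_surface(coefs[[nm]], nm, f))
  names(surfaces) <- names(coefs)
  noise_sd <- c(yield_pct = 0.33, phenols_gae = 0.54, flavonoids_qe = 0.55,
                tannins_tae = 1.21, antioxidant_pct = 0.31)
  structure(list(surfaces = surfaces, noise_sd = noise_sd),
            class = "uae_ground_truth")
}

#' Simulate a Box-Behnken extraction experiment
#'
#' Generates an 18-run (by default) three-factor Box-Behnken design and
#' fills in the five response columns by evaluating the ground-truth
#' quadratic surfaces at each coded run and adding independent Gaussian
#' noise with per-response standard deviation
#' \code{noise_scale * ground_truth$noise_sd}.  With
#' \code{noise_scale = 0} the responses are exact surface values and a
#' quadratic refit recovers the ground-truth coefficients to machine
#' precision.
#'
#' @param ground_truth A \code{\link{uae_ground_truth}} bundle (or a
#'   compatible list of surfaces + noise SDs).
#' @param center_reps Center replicates for the design (default 6).
#' @param noise_scale Non-negative multiplier on the per-response noise
#'   SDs (default 1).
#' @param seed Integer seed; the dataset is reproducible from
#'   (\code{seed}, \code{noise_scale}, \code{center_reps}).
#'
#' @return A \code{bbd_design} data frame with the five response columns
#'   appended, plus attribute \code{"generation"} recording seed, noise
#'   scale and noise SDs.
#'
#' @examples
#' d <- simulate_bbd_experiment(seed = 1)
#' head(d)
#' @export
simulate_bbd_experiment <- function(ground_truth = uae_ground_truth(),
                                    center_reps = 6L, noise_scale = 1,
                                    seed = NULL) {
  if (!is.numeric(noise_scale) || noise_scale < 0)
    stop("'noise_scale' must be non-negative")
  factors <- ground_truth$surfaces[[1L]]$factors
  design <- make_bbd(factors, center_reps = center_reps)
  coded <- coded_matrix(design)
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(ground_truth$surfaces)) {
    mu <- evaluate_surface(ground_truth$surfaces[[nm]], coded)
    sd_nm <- noise_scale * ground_truth$noise_sd[[nm]]
    design[[nm]] <- mu + if (sd_nm > 0)
      stats::rnorm(nrow(design), 0, sd_nm) else 0
  }
  attr(design, "generation") <- list(seed = seed,
                                     noise_scale = noise_scale,
                                     noise_sd = ground_truth$noise_sd,
                                     center_reps = center_reps)
  design
}

#' Bundled constants from the source study
#'
#' All printed constants needed to exercise the pipeline without the
#' (unpublished) raw data:
#' \describe{
#'   \item{\code{factors}}{the three process factor specifications
#'     (time 10-30 min, temperature 30-40 degC, solid-solvent ratio
#'     denominator 10-30).}
#'   \item{\code{ground_truth}}{the five coded quadratic surfaces and
#'     residual SDs (see \code{\link{uae_ground_truth}}).}
#'   \item{\code{ann}}{the published weight/bias values of the best
#'     3-4-5 network as an \code{\link{ann_parameters}} object
#'     (hidden-major \code{W_ih}, output-major \code{W_ho}).}
#'   \item{\code{validation}}{predicted and experimental response vectors at
#'     the reported optimum (time 15 min, 33 degC, ratio 24), with the
#'     published percent-error row.}
#' }
#'
#' @return A named list with the elements described above.
#'
#' @examples
#' fx <- uae_fixtures()
#' fx$validation$predicted
#' @export
uae_fixtures <- function() {
  W_ih <- matrix(c(
    -7.2336, -1.0604,  4.7262,
     0.43575, 2.5957, -2.4158,
    20.2502, -9.4265, -2.8229,
    -3.3886, -4.7606,  4.7377
  ), nrow = 4L, byrow = TRUE)
  T_h <- c(4.4098, -0.85681, 12.2379, 0.92758)
  W_ho <- matrix(c(
    2.4338, -19.482,  -2.9182, -21.2476,
    6.1667, -42.6406, -5.3154, -48.1334,
    6.1947, -42.9296, -5.3605, -48.4433,
    9.3231, -51.6052, -5.0571, -60.2125,
    2.5763, -20.0191, -2.9495, -21.9176
  ), nrow = 5L, byrow = TRUE)
  T_o <- c(2.2397, 4.4757, 4.5168, 4.3392, 2.2433)
  list(
    factors = uae_factors(),
    ground_truth = uae_ground_truth(),
    ann = ann_parameters(W_ih, T_h, W_ho, T_o),
    validation = list(
      optimum = c(time = 15, temperature = 33, ratio = 24),
      predicted = stats::setNames(
        c(38.41, 40.99, 36.13, 176.73, 68.39), response_names()),
      experimental = stats::setNames(
        c(39.32, 41.12, 37.00, 177.32, 69.55), response_names()),
      percent_error = stats::setNames(
        c(2.31, 0.32, 2.35, 0.33, 1.67), response_names())
    )
  )
}
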