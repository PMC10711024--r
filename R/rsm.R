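surface_terms <- c("intercept", "A", "B", "C", "AB", "AC", "BC",
                   "A2", "B2", "C2")

#' Construct a coded second-order response surface
#'
#' A quadratic surface in the three coded factors A (time),
#' B (temperature), C (solid-solvent ratio):
#' \deqn{y = b_0 + b_A A + b_B B + b_C C + b_{AB} AB + b_{AC} AC +
#'       b_{BC} BC + b_{A^2} A^2 + b_{B^2} B^2 + b_{C^2} C^2.}
#'
#' @param coefficients Named numeric vector of the 10 coefficients, in
#'   the order \code{intercept, A, B, C, AB, AC, BC, A2, B2, C2}
#'   (names optional but checked when present).
#' @param response_name Name of the response this surface predicts.
#' @param factors Factor specifications giving the coding
#'   (default \code{\link{uae_factors}()}).
#'
#' @return An object of class \code{"quadratic_surface"}.
#' @export
quadratic_surface <- function(coefficients, response_name = "response",
                              factors = uae_factors()) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 10L)
    stop("a quadratic surface has exactly 10 coefficients")
  if (!all(is.finite(coefficients)))
    stop("surface coefficients must be finite")
  names(coefficients) <- surface_terms
  structure(
    list(response_name = response_name, coefficients = coefficients,
         factors = check_factors(factors)),
    class = "quadratic_surface"
  )
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cat(sprintf("Coded quadratic surface for '%s':\n", x$response_name))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Evaluate a quadratic surface at coded points
#'
#' @param surface A \code{\link{quadratic_surface}}.
#' @param coded A coded point (length-3 vector) or a matrix/data frame of
#'   coded points (3 columns A, B, C).
#'
#' @return Predicted response value(s), one per point.
#'
#' @examples
#' s <- uae_ground_truth()$surfaces$yield_pct
#' evaluate_surface(s, c(0, 0, 0))  # the surface intercept
#' @export
evaluate_surface <- function(surface, coded) {
  stopifnot(inherits(surface, "quadratic_surface"))
  x <- as_point_matrix(coded)
  if (!all(is.finite(x))) stop("non-finite coded values")
  attr(x, "was_vector") <- NULL
  unname(drop(quadratic_basis(x) %*% surface$coefficients))
}

# 10-column model matrix [1, A, B, C, AB, AC, BC, A^2, B^2, C^2]
quadratic_basis <- function(coded) {
  A <- coded[, 1L]; B <- coded[, 2L]; C <- coded[, 3L]
  cbind(intercept = 1, A = A, B = B, C = C,
        AB = A * B, AC = A * C, BC = B * C,
        A2 = A^2, B2 = B^2, C2 = C^2)
}

surface_model_frame <- function(design, response_name) {
  if (!response_name %in% names(design))
    stop(sprintf("design has no response column '%s'", response_name))
  y <- design[[response_name]]
  if (!all(is.finite(y)))
    stop(sprintf("response '%s' contains non-finite values", response_name))
  m <- coded_matrix(design)
  data.frame(y = y, A = m[, 1L], B = m[, 2L], C = m[, 3L])
}

#' Fit a coded second-order response surface by least squares
#'
#' Ordinary least squares on the 10-term coded basis
#' \code{[1, A, B, C, AB, AC, BC, A^2, B^2, C^2]}.  On a Box-Behnken
#' design with replicated centers the basis is well conditioned and the
#' fit is an exact interpolation of noiseless quadratic data.
#'
#' @param design A \code{\link{make_bbd}} design table carrying the
#'   response column.
#' @param response_name Name of the response column to fit.
#'
#' @return A \code{\link{quadratic_surface}} whose attribute
#'   \code{"fit"} holds the underlying \code{\link[stats]{lm}} object.
#' @export
fit_quadratic <- function(design, response_name) {
  df <- surface_model_frame(design, response_name)
  if (nrow(df) < 10L)
    stop("need at least 10 runs to fit a 10-coefficient quadratic")
  fit <- stats::lm(
    y ~ A + B + C + I(A * B) + I(A * C) + I(B * C) +
      I(A^2) + I(B^2) + I(C^2),
    data = df)
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("rank-deficient design: cannot fit quadratic")
  factors <- attr(design, "factors")
  if (is.null(factors)) factors <- uae_factors()
  surf <- quadratic_surface(unname(beta), response_name, factors)
  attr(surf, "fit") <- fit
  surf
}

#' Sequential ANOVA and fit statistics for a response-surface model
#'
#' Partitions the total sum of squares of a fitted quadratic into nine
#' single-degree-of-freedom term contributions (sequential sums of
#' squares in the order A, B, C, AB, AC, BC, A^2, B^2, C^2), a
#' lack-of-fit component, and pure error estimated from replicated
#' design points (the center replicates, in a standard 12+k
#' Box-Behnken design).  Also reports the residual SD, response mean,
#' coefficient of variation, R-squared, adjusted R-squared, and the
#' PRESS-based predicted R-squared
#' \eqn{1 - \mathrm{PRESS}/SS_\mathrm{total}}.
#'
#' @param design Design table with the response column.
#' @param response_name Response column name.
#'
#' @return An object of class \code{"rsm_anova"}: a list with elements
#'   \code{response_name}, \code{terms} (data frame of per-term df, SS,
#'   MS, F, p), \code{model} (df, SS, MS, F, p), \code{residual},
#'   \code{lack_of_fit} (NULL when the design has no replicated points),
#'   \code{pure_error}, \code{sd}, \code{mean}, \code{cv_percent},
#'   \code{r_squared}, \code{adj_r_squared}, \code{pred_r_squared},
#'   \code{press}.
#' @export
rsm_anova <- function(design, response_name) {
  df <- surface_model_frame(design, response_name)
  fit <- stats::lm(
    y ~ A + B + C + I(A * B) + I(A * C) + I(B * C) +
      I(A^2) + I(B^2) + I(C^2),
    data = df)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design")
  seq_tab <- stats::anova(fit)
  term_rows <- seq_len(nrow(seq_tab) - 1L)
  terms <- data.frame(
    term = surface_terms[-1L],
    df = seq_tab$Df[term_rows],
    sum_sq = seq_tab$`Sum Sq`[term_rows],
    row.names = NULL
  )
  n <- nrow(df)
  df_res <- n - 10L
  ss_res <- sum(stats::resid(fit)^2)
  ms_res <- ss_res / df_res
  terms$mean_sq <- terms$sum_sq / terms$df
  terms$f_value <- terms$mean_sq / ms_res
  terms$p_value <- stats::pf(terms$f_value, terms$df, df_res,
                             lower.tail = FALSE)
  ss_model <- sum(terms$sum_sq)
  ss_tot <- ss_model + ss_res
  model <- list(df = 9L, sum_sq = ss_model, mean_sq = ss_model / 9,
                f_value = (ss_model / 9) / ms_res,
                p_value = stats::pf((ss_model / 9) / ms_res, 9, df_res,
                                    lower.tail = FALSE))

  # pure error from replicated design points (center runs in a BBD)
  key <- interaction(df$A, df$B, df$C, drop = TRUE)
  reps <- split(df$y, key)
  reps <- reps[lengths(reps) > 1L]
  if (length(reps) > 0L) {
    ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1)))
    df_pe <- sum(lengths(reps) - 1L)
    df_lof <- df_res - df_pe
    ss_lof <- ss_res - ss_pe
    pure_error <- list(df = df_pe, sum_sq = ss_pe, mean_sq = ss_pe / df_pe)
    lack_of_fit <- if (df_lof > 0L && df_pe > 0L) {
      f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
      list(df = df_lof, sum_sq = ss_lof, mean_sq = ss_lof / df_lof,
           f_value = f_lof,
           p_value = stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE))
    } else NULL
  } else {
    pure_error <- NULL
    lack_of_fit <- NULL
  }

  press <- sum((stats::resid(fit) / (1 - stats::lm.influence(fit)$hat))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (ss_res / df_res) / (ss_tot / (n - 1L))
  structure(
    list(response_name = response_name,
         terms = terms, model = model,
         residual = list(df = df_res, sum_sq = ss_res, mean_sq = ms_res),
         lack_of_fit = lack_of_fit, pure_error = pure_error,
         sd = sqrt(ms_res), mean = mean(df$y),
         cv_percent = 100 * sqrt(ms_res) / mean(df$y),
         r_squared = r2, adj_r_squared = adj_r2,
         pred_r_squared = 1 - press / ss_tot, press = press,
         n_runs = n),
    class = "rsm_anova"
  )
}

#' @export
print.rsm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Sequential ANOVA for quadratic model of '%s' (%d runs)\n",
              x$response_name, x$n_runs))
  tab <- x$terms
  tab$sum_sq <- signif(tab$sum_sq, digits)
  tab$mean_sq <- signif(tab$mean_sq, digits)
  tab$f_value <- signif(tab$f_value, digits)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Model: df %d, F = %s\n", x$model$df,
              signif(x$model$f_value, digits)))
  if (!is.null(x$lack_of_fit))
    cat(sprintf("Lack of fit: df %d, F = %s;  pure error: df %d, MS = %s\n",
                x$lack_of_fit$df, signif(x$lack_of_fit$f_value, digits),
                x$pure_error$df, signif(x$pure_error$mean_sq, digits)))
  cat(sprintf(
    "SD %s, mean %s, CV%% %s, R2 %s, adj R2 %s, pred R2 %s\n",
    signif(x$sd, digits), signif(x$mean, digits),
    signif(x$cv_percent, digits), signif(x$r_squared, digits),
    signif(x$adj_r_squared, digits), signif(x$pred_r_squared, digits)))
  invisible(x)
}

#' Serialize surfaces and ANOVA reports to JSON
#'
#' @param x A \code{quadratic_surface} or \code{rsm_anova}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_surface <- function(x, path) {
  stopifnot(inherits(x, "quadratic_surface"))
  obj <- list(
    response_name = x$response_name,
    coefficients = as.list(x$coefficients),
    factors = lapply(x$factors, function(f)
      list(name = f$name, low = f$low, high = f$high, units = f$units))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  factors <- lapply(obj$factors, function(f)
    factor_spec(f$name, f$low, f$high, f$units))
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  quadratic_surface(unlist(obj$coefficients), obj$response_name, factors)
}

#' @rdname write_surface
#' @export
write_anova <- function(x, path) {
  stopifnot(inherits(x, "rsm_anova"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
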