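#' Hyperbolic-tangent sigmoid transfer function
#'
#' The \code{tansig} transfer function
#' \eqn{2/(1 + e^{-2x}) - 1}, algebraically identical to
#' \eqn{\tanh(x)}: strictly increasing, odd, with range \eqn{(-1, 1)}.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' tansig(0)          # 0
#' tansig(c(-2, 2))   # odd symmetry
#' @export
tansig <- function(x) 2 / (1 + exp(-2 * x)) - 1

#' Construct feed-forward network parameters
#'
#' Parameter container for a single-hidden-layer feed-forward network
#' with \code{tansig} hidden units and a linear output layer.  The
#' convention is hidden-major for \code{W_ih} (one row per hidden
#' neuron, one column per input) and output-major for \code{W_ho} (one
#' row per output neuron, one column per hidden neuron).
#'
#' @param W_ih Hidden-by-input weight matrix.
#' @param T_h Hidden bias vector (length = rows of \code{W_ih}).
#' @param W_ho Output-by-hidden weight matrix.
#' @param T_o Output bias vector (length = rows of \code{W_ho}).
#'
#' @return An object of class \code{"ann_parameters"}.
#' @export
ann_parameters <- function(W_ih, T_h, W_ho, T_o) {
  W_ih <- as.matrix(W_ih); W_ho <- as.matrix(W_ho)
  T_h <- as.numeric(T_h); T_o <- as.numeric(T_o)
  if (length(T_h) != nrow(W_ih))
    stop("hidden bias length must equal the number of hidden neurons")
  if (ncol(W_ho) != nrow(W_ih))
    stop("W_ho columns must equal the number of hidden neurons")
  if (length(T_o) != nrow(W_ho))
    stop("output bias length must equal the number of output neurons")
  if (!all(is.finite(W_ih), is.finite(T_h), is.finite(W_ho),
           is.finite(T_o)))
    stop("network parameters must be finite")
  structure(list(W_ih = W_ih, T_h = T_h, W_ho = W_ho, T_o = T_o),
            class = "ann_parameters")
}

#' @export
print.ann_parameters <- function(x, ...) {
  cat(sprintf("Feed-forward network parameters: %d-%d-%d (tansig hidden, linear output)\n",
              ncol(x$W_ih), nrow(x$W_ih), nrow(x$W_ho)))
  invisible(x)
}

#' Forward pass through a feed-forward network
#'
#' Computes, for each input row \eqn{x}: the hidden pre-activation
#' \eqn{W_{ih} x + T_h}, the \code{\link{tansig}} hidden activation,
#' and the linear output \eqn{W_{ho} h + T_o}.
#'
#' @param params An \code{\link{ann_parameters}} object.
#' @param x Input vector (length = input count) or matrix with one row
#'   per point, in the network's (scaled) input units.
#'
#' @return Output vector (single point) or matrix with one row per
#'   point.
#' @export
ann_forward <- function(params, x) {
  stopifnot(inherits(params, "ann_parameters"))
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(X) != ncol(params$W_ih))
    stop("input width does not match the network's input layer")
  H <- tansig(X %*% t(params$W_ih) +
                matrix(params$T_h, nrow(X), length(params$T_h), byrow = TRUE))
  O <- H %*% t(params$W_ho) +
    matrix(params$T_o, nrow(X), length(params$T_o), byrow = TRUE)
  if (single) drop(O) else O
}

#' Min-max scaler onto [-1, 1]
#'
#' @param min,max Per-variable range endpoints (named vectors); each
#'   \code{max} must exceed its \code{min}.
#' @return An object of class \code{"minmax_scaler"} with methods via
#'   \code{scale_to} / \code{scale_from}.
#' @export
minmax_scaler <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  if (length(min) != length(max)) stop("min/max length mismatch")
  if (any(!is.finite(min)) || any(!is.finite(max)) || any(max <= min))
    stop("degenerate scaler: need finite max > min per variable")
  structure(list(min = min, max = max), class = "minmax_scaler")
}

#' @rdname minmax_scaler
#' @param scaler A \code{minmax_scaler}.
#' @param x Vector or matrix in natural (\code{scale_to}) or scaled
#'   (\code{scale_from}) units.
#' @export
scale_to <- function(scaler, x) {
  if (is.null(dim(x)))
    2 * (x - scaler$min) / (scaler$max - scaler$min) - 1
  else
    sweep(sweep(x, 2, scaler$min, `-`), 2,
          (scaler$max - scaler$min) / 2, `/`) - 1
}

#' @rdname minmax_scaler
#' @export
scale_from <- function(scaler, x) {
  if (is.null(dim(x)))
    (x + 1) / 2 * (scaler$max - scaler$min) + scaler$min
  else
    sweep(sweep(x + 1, 2, (scaler$max - scaler$min) / 2, `*`),
          2, scaler$min, `+`)
}

#' Training configuration for the network surrogate
#'
#' @param iterations Maximum training epochs per run (default 2000).
#'   Both optimizers accept an epoch only when it does not increase the
#'   training MSE, so the budget is an upper bound; the
#'   Levenberg-Marquardt trainer stops early once no damping level
#'   yields further improvement.
#' @param runs Training restarts per architecture in
#'   \code{\link{select_architecture}} (default 10).
#' @param optimizer \code{"lm"} (damped Gauss-Newton /
#'   Levenberg-Marquardt on the full batch; default) or \code{"gd"}
#'   (plain full-batch gradient descent with backtracking from the
#'   drawn learning rate).
#' @param lr_range Range the per-run learning rate is drawn from
#'   (default \code{c(0.5, 1)}); used as the initial step size by the
#'   \code{"gd"} optimizer and recorded either way.
#' @param split Training/testing/validation fractions, summing to 1
#'   (default \code{c(0.70, 0.15, 0.15)}).
#' @param seed Integer seed controlling the data split, weight
#'   initialization and learning-rate draw.
#'
#' @return A list of class \code{"train_config"}.
#' @export
train_config <- function(iterations = 2000L, runs = 10L,
                         optimizer = c("lm", "gd"),
                         lr_range = c(0.5, 1), split = c(0.70, 0.15, 0.15),
                         seed = 1L) {
  if (iterations < 0) stop("'iterations' must be >= 0")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (length(lr_range) != 2L || lr_range[1] > lr_range[2])
    stop("invalid learning-rate range")
  structure(list(iterations = as.integer(iterations),
                 runs = as.integer(runs),
                 optimizer = match.arg(optimizer), lr_range = lr_range,
                 split = split, seed = as.integer(seed)),
            class = "train_config")
}

split_indices <- function(n, split) {
  idx <- sample.int(n)
  n_test <- round(split[2] * n)
  n_val <- round(split[3] * n)
  n_train <- n - n_test - n_val   # remainder to training
  list(train = sort(idx[seq_len(n_train)]),
       test = sort(idx[n_train + seq_len(n_test)]),
       validation = sort(idx[n_train + n_test + seq_len(n_val)]))
}

init_params <- function(n_in, n_hidden, n_out) {
  ann_parameters(
    W_ih = matrix(stats::runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
    T_h = stats::runif(n_hidden, -0.5, 0.5),
    W_ho = matrix(stats::runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden),
    T_o = stats::runif(n_out, -0.5, 0.5))
}

ann_loss_grad <- function(params, X, Y) {
  n <- nrow(X)
  Hpre <- X %*% t(params$W_ih) +
    matrix(params$T_h, n, length(params$T_h), byrow = TRUE)
  H <- tansig(Hpre)
  O <- H %*% t(params$W_ho) +
    matrix(params$T_o, n, length(params$T_o), byrow = TRUE)
  R <- O - Y
  loss <- mean(R^2)
  E <- 2 * R / length(R)
  dH <- (E %*% params$W_ho) * (1 - H^2)
  list(loss = loss,
       gW_ho = t(E) %*% H, gT_o = colSums(E),
       gW_ih = t(dH) %*% X, gT_h = colSums(dH))
}

apply_step <- function(params, g, step) {
  ann_parameters(params$W_ih - step * g$gW_ih,
                 params$T_h - step * g$gT_h,
                 params$W_ho - step * g$gW_ho,
                 params$T_o - step * g$gT_o)
}

ann_mse <- function(params, X, Y) mean((ann_forward(params, X) - Y)^2)

flatten_params <- function(p) c(p$W_ih, p$T_h, p$W_ho, p$T_o)

unflatten_params <- function(v, n_in, n_hidden, n_out) {
  i <- 0L
  W_ih <- matrix(v[i + seq_len(n_hidden * n_in)], n_hidden, n_in)
  i <- i + n_hidden * n_in
  T_h <- v[i + seq_len(n_hidden)]; i <- i + n_hidden
  W_ho <- matrix(v[i + seq_len(n_out * n_hidden)], n_out, n_hidden)
  i <- i + n_out * n_hidden
  ann_parameters(W_ih, T_h, W_ho, v[i + seq_len(n_out)])
}

# residual vector (column-major over outputs) and its Jacobian in the
# flattened parameter order used by flatten_params
ann_resid_jac <- function(params, X, Y) {
  n <- nrow(X); h <- nrow(params$W_ih)
  n_in <- ncol(X); n_out <- nrow(params$W_ho)
  H <- tansig(X %*% t(params$W_ih) +
                matrix(params$T_h, n, h, byrow = TRUE))
  D <- 1 - H^2
  R <- H %*% t(params$W_ho) +
    matrix(params$T_o, n, n_out, byrow = TRUE) - Y
  J <- matrix(0, n * n_out, h * n_in + h + n_out * h + n_out)
  for (o in seq_len(n_out)) {
    rows <- (o - 1L) * n + seq_len(n)
    for (hh in seq_len(h)) {
      base <- params$W_ho[o, hh] * D[, hh]
      for (j in seq_len(n_in))
        J[rows, (j - 1L) * h + hh] <- base * X[, j]
      J[rows, h * n_in + hh] <- base
      J[rows, h * n_in + h + (hh - 1L) * n_out + o] <- H[, hh]
    }
    J[rows, h * n_in + h + n_out * h + o] <- 1
  }
  list(r = as.numeric(R), J = J)
}

# Damped Gauss-Newton (Levenberg-Marquardt) on the batch MSE; epochs
# are accepted only when the loss decreases, so accepted-epoch loss is
# monotone.  Stops early once no damping level improves the loss.
train_lm_loop <- function(params, X, Y, iterations,
                          lambda0 = 1e-3, nu = 10) {
  n_in <- ncol(X); h <- nrow(params$W_ih); n_out <- nrow(params$W_ho)
  v <- flatten_params(params)
  lambda <- lambda0
  loss <- ann_mse(params, X, Y)
  if (!is.finite(loss)) stop("training diverged: non-finite loss")
  for (it in seq_len(iterations)) {
    rj <- ann_resid_jac(unflatten_params(v, n_in, h, n_out), X, Y)
    A <- crossprod(rj$J)
    g <- crossprod(rj$J, rj$r)
    accepted <- FALSE
    repeat {
      delta <- tryCatch(
        solve(A + lambda * diag(diag(A) + 1e-12), g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        v2 <- v - as.numeric(delta)
        l2 <- ann_mse(unflatten_params(v2, n_in, h, n_out), X, Y)
        if (is.finite(l2) && l2 < loss) {
          improvement <- loss - l2
          v <- v2; loss <- l2
          lambda <- max(lambda / nu, 1e-12)
          accepted <- improvement > 1e-6 * max(loss, 1e-12)
          break
        }
      }
      lambda <- lambda * nu
      if (lambda > 1e10) break
    }
    if (!accepted) break  # converged: no meaningful decrease available
  }
  list(params = unflatten_params(v, n_in, h, n_out), loss = loss)
}

train_gd_loop <- function(params, X, Y, iterations, lr) {
  loss <- ann_mse(params, X, Y)
  if (!is.finite(loss)) stop("training diverged: non-finite loss")
  for (it in seq_len(iterations)) {
    g <- ann_loss_grad(params, X, Y)
    step <- lr
    repeat {
      cand <- apply_step(params, g, step)
      cand_loss <- ann_mse(cand, X, Y)
      if (is.finite(cand_loss) && cand_loss <= g$loss) {
        params <- cand; loss <- cand_loss
        break
      }
      step <- step / 2
      if (step < 1e-14) { loss <- g$loss; break }  # stuck: keep current
    }
    if (!is.finite(loss)) stop("training diverged: non-finite loss")
  }
  list(params = params, loss = loss)
}

split_metrics <- function(params, Xs, Ys, splits) {
  out <- lapply(splits, function(idx) {
    if (length(idx) == 0L) return(list(mse = NA_real_, r2 = NA_real_))
    P <- ann_forward(params, Xs[idx, , drop = FALSE])
    Yk <- Ys[idx, , drop = FALSE]
    sse <- sum((P - Yk)^2)
    sst <- sum(sweep(Yk, 2, colMeans(Yk), `-`)^2)
    list(mse = sse / length(Yk),
         r2 = if (sst > 0) 1 - sse / sst else NA_real_)
  })
  names(out) <- names(splits)
  out
}

#' Train a feed-forward network surrogate of the extraction process
#'
#' Min-max scales the three factors (over their declared design ranges)
#' and the five responses (over their observed data ranges) onto
#' \eqn{[-1, 1]}, splits the runs into training/testing/validation
#' sets by a seeded permutation, and fits a
#' 3-\code{hidden}-5 network by full-batch back-propagation on the mean
#' squared error.  The default optimizer is damped Gauss-Newton
#' (Levenberg-Marquardt) with an analytic Jacobian; plain gradient
#' descent (\code{optimizer = "gd"}) backtracks each epoch from the
#' per-run learning rate drawn uniformly from \code{config$lr_range}.
#' Either way an epoch is accepted only when the training MSE does not
#' increase, so accepted epochs are monotone non-increasing in loss.
#' A non-finite loss aborts with an error.
#'
#' @param design A design table carrying the five response columns
#'   (see \code{\link{simulate_bbd_experiment}}).
#' @param hidden Number of hidden neurons.
#' @param config A \code{\link{train_config}}.
#' @param responses Response column names (default
#'   \code{\link{response_names}()}).
#'
#' @return An object of class \code{"trained_surrogate"}: a list with
#'   \code{params} (\code{\link{ann_parameters}}), \code{input_scaler},
#'   \code{output_scaler}, \code{architecture} (e.g. \code{"3-4-5"}),
#'   \code{metrics} (per-split MSE and R-squared), \code{splits},
#'   \code{learning_rate}, \code{config}.
#'
#' @examples
#' d <- simulate_bbd_experiment(seed = 3, noise_scale = 0)
#' s <- ann_train(d, hidden = 4, train_config(iterations = 200, seed = 7))
#' s$metrics$train$mse
#' @export
ann_train <- function(design, hidden, config = train_config(),
                      responses = response_names()) {
  if (nrow(design) < 10L) stop("need at least 10 runs to train")
  if (!all(responses %in% names(design)))
    stop("design lacks response columns: ",
         paste(setdiff(responses, names(design)), collapse = ", "))
  factors <- attr(design, "factors")
  if (is.null(factors)) factors <- uae_factors()
  Xnat <- as.matrix(design[, vapply(factors, `[[`, character(1), "name")])
  Ynat <- as.matrix(design[, responses])
  if (!all(is.finite(Ynat))) stop("non-finite response values")

  in_scaler <- minmax_scaler(vapply(factors, `[[`, numeric(1), "low"),
                             vapply(factors, `[[`, numeric(1), "high"))
  y_min <- apply(Ynat, 2, min); y_max <- apply(Ynat, 2, max)
  if (any(y_max <= y_min))
    stop("degenerate scaler: a response column is constant")
  out_scaler <- minmax_scaler(y_min, y_max)
  Xs <- scale_to(in_scaler, Xnat)
  Ys <- scale_to(out_scaler, Ynat)

  set.seed(config$seed)
  splits <- split_indices(nrow(Xs), config$split)
  params <- init_params(ncol(Xs), hidden, ncol(Ys))
  lr <- stats::runif(1, config$lr_range[1], config$lr_range[2])

  Xtr <- Xs[splits$train, , drop = FALSE]
  Ytr <- Ys[splits$train, , drop = FALSE]
  optimizer <- if (is.null(config$optimizer)) "lm" else config$optimizer
  fit <- if (optimizer == "lm")
    train_lm_loop(params, Xtr, Ytr, config$iterations)
  else
    train_gd_loop(params, Xtr, Ytr, config$iterations, lr)
  params <- fit$params

  structure(
    list(params = params, input_scaler = in_scaler,
         output_scaler = out_scaler, responses = responses,
         architecture = sprintf("%d-%d-%d", ncol(Xs), hidden, ncol(Ys)),
         hidden = hidden,
         metrics = split_metrics(params, Xs, Ys, splits),
         splits = splits, learning_rate = lr, optimizer = optimizer,
         config = config),
    class = "trained_surrogate"
  )
}

#' @export
print.trained_surrogate <- function(x, ...) {
  cat(sprintf("Trained network surrogate %s (lr %.3f)\n",
              x$architecture, x$learning_rate))
  for (nm in names(x$metrics))
    cat(sprintf("  %-10s MSE %.3g  R2 %.4f\n", nm,
                x$metrics[[nm]]$mse, x$metrics[[nm]]$r2))
  invisible(x)
}

#' Predict responses from a trained surrogate
#'
#' @param object A \code{trained_surrogate}.
#' @param newdata Natural-unit factor settings: length-3 vector or
#'   matrix/data frame with 3 columns (time, temperature, ratio).
#' @param ... Unused.
#' @return Natural-unit predicted responses (vector or matrix, columns
#'   named after the responses).
#' @export
predict.trained_surrogate <- function(object, newdata, ...) {
  single <- is.null(dim(newdata))
  X <- if (single) matrix(as.numeric(newdata), nrow = 1L)
       else as.matrix(newdata)
  out <- scale_from(object$output_scaler,
                    ann_forward(object$params, scale_to(object$input_scaler, X)))
  colnames(out) <- object$responses
  if (single) drop(out) else out
}

#' Search hidden-layer sizes for the best surrogate
#'
#' Trains \code{config$runs} restarts for each candidate hidden-layer
#' size and returns the surrogate with the highest validation
#' R-squared; ties are broken by lower validation MSE, then by fewer
#' hidden neurons.  Restart seeds are derived deterministically from
#' \code{config$seed}.
#'
#' @param design Design table with responses.
#' @param hidden_range Integer vector of hidden sizes to try.
#' @param config A \code{\link{train_config}}.
#' @param responses Response column names.
#'
#' @return The winning \code{trained_surrogate}, with attributes
#'   \code{"n_candidates"} (number of networks trained) and
#'   \code{"search"} (per-candidate summary data frame).
#' @export
select_architecture <- function(design, hidden_range = 2:8,
                                config = train_config(),
                                responses = response_names()) {
  hidden_range <- as.integer(hidden_range)
  if (length(hidden_range) == 0L) stop("empty hidden-size search range")
  best <- NULL
  rows <- list()
  k <- 0L
  for (h in hidden_range) {
    for (r in seq_len(config$runs)) {
      k <- k + 1L
      cfg_r <- config
      cfg_r$seed <- (config$seed * 1000L + h * 100L + r) %% .Machine$integer.max
      fit <- tryCatch(ann_train(design, h, cfg_r, responses),
                      error = function(e)
                        stop(sprintf("training failed for %d hidden units, run %d: %s",
                                     h, r, conditionMessage(e)), call. = FALSE))
      rows[[k]] <- data.frame(hidden = h, run = r,
                              val_r2 = fit$metrics$validation$r2,
                              val_mse = fit$metrics$validation$mse)
      if (is.null(best) || better_candidate(fit, best)) best <- fit
    }
  }
  attr(best, "n_candidates") <- k
  attr(best, "search") <- do.call(rbind, rows)
  best
}

better_candidate <- function(a, b) {
  ra <- a$metrics$validation$r2; rb <- b$metrics$validation$r2
  ma <- a$metrics$validation$mse; mb <- b$metrics$validation$mse
  if (is.na(ra)) return(FALSE)
  if (is.na(rb)) return(TRUE)
  if (ra != rb) return(ra > rb)
  if (ma != mb) return(ma < mb)
  a$hidden < b$hidden
}

#' Save and load network parameters as JSON
#'
#' The file stores \code{W_ih}, \code{T_h}, \code{W_ho}, \code{T_o} as
#' row-major lists (hidden-major for \code{W_ih}, output-major for
#' \code{W_ho}), plus optional scalers and an architecture string when
#' a full \code{trained_surrogate} is saved.
#'
#' @param params An \code{\link{ann_parameters}} or
#'   \code{trained_surrogate}.
#' @param path File path.
#' @return \code{save_ann} returns \code{path} invisibly;
#'   \code{load_ann} returns an \code{ann_parameters} (or a
#'   \code{trained_surrogate} when scalers are present in the file).
#' @export
save_ann <- function(params, path) {
  if (inherits(params, "trained_surrogate")) {
    obj <- list(
      architecture = params$architecture,
      W_ih = unname(params$params$W_ih),   # jsonlite writes rows as lists
      T_h = params$params$T_h,
      W_ho = unname(params$params$W_ho),
      T_o = params$params$T_o,
      scalers = list(
        input = list(min = params$input_scaler$min,
                     max = params$input_scaler$max),
        output = list(min = params$output_scaler$min,
                      max = params$output_scaler$max)),
      responses = params$responses)
  } else {
    stopifnot(inherits(params, "ann_parameters"))
    obj <- list(
      architecture = sprintf("%d-%d-%d", ncol(params$W_ih),
                             nrow(params$W_ih), nrow(params$W_ho)),
      W_ih = unname(params$W_ih),
      T_h = params$T_h,
      W_ho = unname(params$W_ho),
      T_o = params$T_o)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ann
#' @export
load_ann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, unlist))
  }
  params <- ann_parameters(to_mat(obj$W_ih), unlist(obj$T_h),
                           to_mat(obj$W_ho), unlist(obj$T_o))
  if (is.null(obj$scalers)) return(params)
  structure(
    list(params = params,
         input_scaler = minmax_scaler(obj$scalers$input$min,
                                      obj$scalers$input$max),
         output_scaler = minmax_scaler(obj$scalers$output$min,
                                       obj$scalers$output$max),
         responses = obj$responses,
         architecture = obj$architecture,
         hidden = nrow(params$W_ih),
         metrics = NULL, splits = NULL, learning_rate = NA_real_,
         config = NULL),
    class = "trained_surrogate")
}
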