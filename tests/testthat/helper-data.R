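# Shared fixtures built in code.

# Dense noiseless dataset sampled from the bundled ground-truth
# surfaces at random coded points; used for surrogate capacity checks
# where the 18-run design would confound capacity with data scarcity.
dense_surface_data <- function(n = 120, seed = 99) {
  gt <- uae_ground_truth()
  f <- uae_factors()
  set.seed(seed)
  coded <- matrix(stats::runif(n * 3, -1, 1), ncol = 3)
  nat <- decode_point(f, coded)
  d <- data.frame(run_id = seq_len(n), time = nat[, 1],
                  temperature = nat[, 2], ratio = nat[, 3],
                  coded_A = coded[, 1], coded_B = coded[, 2],
                  coded_C = coded[, 3])
  for (nm in names(gt$surfaces))
    d[[nm]] <- evaluate_surface(gt$surfaces[[nm]], coded)
  attr(d, "factors") <- f
  d
}

# Brute-force forward pass written as explicit scalar loops,
# independent of the package's matrix implementation.
forward_oracle <- function(params, x) {
  h <- nrow(params$W_ih)
  n_out <- nrow(params$W_ho)
  hl <- numeric(h)
  for (m in seq_len(h)) {
    s <- 0
    for (i in seq_along(x)) s <- s + x[i] * params$W_ih[m, i]
    hl[m] <- 2 / (1 + exp(-2 * (s + params$T_h[m]))) - 1
  }
  out <- numeric(n_out)
  for (o in seq_len(n_out)) {
    s <- 0
    for (m in seq_len(h)) s <- s + params$W_ho[o, m] * hl[m]
    out[o] <- s + params$T_o[o]
  }
  out
}

# Dense-grid maximum of a quadratic surface over the coded cube.
grid_max_surface <- function(surface, n_grid = 101) {
  g <- seq(-1, 1, length.out = n_grid)
  grid <- as.matrix(expand.grid(A = g, B = g, C = g))
  max(evaluate_surface(surface, grid))
}
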