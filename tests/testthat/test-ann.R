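test_that("tansig is the odd sigmoid identical to tanh", {
  expect_equal(tansig(0), 0)
  x <- seq(-6, 6, by = 0.37)
  expect_equal(tansig(x), -tansig(-x))
  expect_lt(max(abs(tansig(x) - tanh(x))), 1e-12)
  expect_true(all(tansig(c(-50, 50)) == c(-1, 1)))  # saturation, no overflow
  expect_true(all(diff(tansig(x)) > 0))
})

test_that("forward pass reduces to the bias for zero weights", {
  p <- ann_parameters(matrix(0, 4, 3), rep(0, 4), matrix(0, 5, 4),
                      c(1, 2, 3, 4, 5))
  expect_equal(ann_forward(p, c(0.3, -0.8, 0.1)), c(1, 2, 3, 4, 5))
  # hand-built 2-2-1 net, unit weights, zero biases, zero input
  p2 <- ann_parameters(matrix(1, 2, 2), c(0, 0), matrix(1, 1, 2), 0)
  expect_equal(ann_forward(p2, c(0, 0)), 0)
})

test_that("forward pass with the published 3-4-5 weights matches a scalar-loop oracle", {
  params <- uae_fixtures()$ann
  set.seed(31)
  for (i in 1:100) {
    x <- runif(3, -1, 1)
    expect_lt(max(abs(ann_forward(params, x) - forward_oracle(params, x))),
              1e-10)
  }
  # matrix form agrees with vector form
  X <- matrix(runif(30, -1, 1), ncol = 3)
  expect_equal(ann_forward(params, X),
               t(apply(X, 1, function(x) ann_forward(params, x))))
})

test_that("forward outputs respond continuously with a weight-norm gradient bound", {
  params <- uae_fixtures()$ann
  L <- norm(params$W_ho, "2") * norm(params$W_ih, "2")  # |tansig'| <= 1
  set.seed(8)
  for (i in 1:20) {
    x <- runif(3, -1, 1); dx <- runif(3, -0.05, 0.05)
    dy <- ann_forward(params, x + dx) - ann_forward(params, x)
    expect_lte(sqrt(sum(dy^2)), L * sqrt(sum(dx^2)) + 1e-9)
  }
})

test_that("min-max scaling round-trips and rejects degenerate ranges", {
  sc <- minmax_scaler(c(10, 30, 10), c(30, 40, 30))
  x <- cbind(runif(20, 10, 30), runif(20, 30, 40), runif(20, 10, 30))
  expect_lt(max(abs(scale_from(sc, scale_to(sc, x)) - x)), 1e-12)
  expect_equal(scale_to(sc, c(10, 30, 10)), c(-1, -1, -1))
  expect_equal(scale_to(sc, c(30, 40, 30)), c(1, 1, 1))
  expect_error(minmax_scaler(c(1, 2), c(3, 2)), "degenerate")
})

test_that("network parameter shapes are validated", {
  expect_error(ann_parameters(matrix(0, 4, 3), rep(0, 3), matrix(0, 5, 4),
                              rep(0, 5)), "hidden bias")
  expect_error(ann_parameters(matrix(0, 4, 3), rep(0, 4), matrix(0, 5, 3),
                              rep(0, 5)), "W_ho columns")
  expect_error(ann_parameters(matrix(NA_real_, 4, 3), rep(0, 4),
                              matrix(0, 5, 4), rep(0, 5)), "finite")
  p <- uae_fixtures()$ann
  expect_error(ann_forward(p, c(1, 2)), "input width")
})

test_that("a zero-iteration budget returns the seeded initial network", {
  d <- simulate_bbd_experiment(seed = 2)
  s <- ann_train(d, hidden = 4, train_config(iterations = 0, seed = 9))
  expect_s3_class(s$params, "ann_parameters")
  expect_true(is.finite(s$metrics$train$mse))
  expect_equal(s$architecture, "3-4-5")
})

test_that("training is bitwise-reproducible from its seed", {
  d <- simulate_bbd_experiment(seed = 2)
  s1 <- ann_train(d, hidden = 3, train_config(iterations = 100, seed = 5))
  s2 <- ann_train(d, hidden = 3, train_config(iterations = 100, seed = 5))
  expect_identical(s1$params, s2$params)
  expect_identical(s1$metrics, s2$metrics)
  s3 <- ann_train(d, hidden = 3, train_config(iterations = 100, seed = 6))
  expect_false(identical(s1$params, s3$params))
})

test_that("the surrogate has capacity for the smooth quadratic target", {
  # amply sampled noiseless surfaces: a 4-hidden-unit network should
  # generalize almost perfectly
  d <- dense_surface_data(n = 120, seed = 99)
  s <- ann_train(d, hidden = 4, train_config(iterations = 2000, seed = 2))
  expect_gt(s$metrics$validation$r2, 0.95)
  expect_gt(s$metrics$test$r2, 0.95)
})

test_that("training recovers a teacher network of the same architecture", {
  set.seed(77)
  teacher <- ann_parameters(
    matrix(runif(12, -1, 1), 4, 3), runif(4, -0.5, 0.5),
    matrix(runif(20, -1, 1), 5, 4), runif(5, -0.5, 0.5))
  f <- uae_factors()
  coded <- matrix(runif(200 * 3, -1, 1), ncol = 3)
  nat <- decode_point(f, coded)
  Y <- ann_forward(teacher, coded)
  d <- data.frame(run_id = 1:200, time = nat[, 1], temperature = nat[, 2],
                  ratio = nat[, 3], coded_A = coded[, 1],
                  coded_B = coded[, 2], coded_C = coded[, 3])
  for (j in seq_along(response_names())) d[[response_names()[j]]] <- Y[, j]
  attr(d, "factors") <- f
  s <- ann_train(d, hidden = 4, train_config(iterations = 2000, seed = 4))
  held <- c(s$splits$test, s$splits$validation)
  pred <- predict(s, as.matrix(d[held, c("time", "temperature", "ratio")]))
  mse <- mean((pred - Y[held, ])^2)
  expect_lt(mse, 1e-3 * mean(apply(Y, 2, var)))
})

test_that("architecture search counts candidates and selects reproducibly", {
  d <- simulate_bbd_experiment(seed = 11)
  cfg <- train_config(iterations = 50, runs = 10, seed = 3)
  s <- select_architecture(d, hidden_range = 4, cfg)
  expect_equal(attr(s, "n_candidates"), 10L)   # 10 runs x range of 1
  expect_equal(s$architecture, "3-4-5")
  cfg2 <- train_config(iterations = 50, runs = 2, seed = 3)
  s2 <- select_architecture(d, hidden_range = 2:4, cfg2)
  expect_equal(attr(s2, "n_candidates"), 6L)
  expect_true(s2$hidden %in% 2:4)
  expect_match(s2$architecture, sprintf("^3-%d-5$", s2$hidden))
  # the winner has the best validation R2 among the logged candidates
  search <- attr(s2, "search")
  expect_equal(s2$metrics$validation$r2, max(search$val_r2))
  s3 <- select_architecture(d, hidden_range = 2:4, cfg2)
  expect_identical(s3$params, s2$params)
})

test_that("network parameters and surrogates round-trip through JSON", {
  params <- uae_fixtures()$ann
  path <- tempfile(fileext = ".json")
  save_ann(params, path)
  p2 <- load_ann(path)
  expect_equal(p2$W_ih, params$W_ih)
  expect_equal(p2$W_ho, params$W_ho)
  expect_equal(p2$T_h, params$T_h)
  expect_equal(p2$T_o, params$T_o)
  d <- simulate_bbd_experiment(seed = 2)
  s <- ann_train(d, hidden = 3, train_config(iterations = 50, seed = 5))
  save_ann(s, path)
  s2 <- load_ann(path)
  expect_s3_class(s2, "trained_surrogate")
  x <- c(17, 36, 22)
  expect_equal(predict(s2, x), predict(s, x), tolerance = 1e-12)
  unlink(path)
})

test_that("training rejects degenerate inputs", {
  d <- simulate_bbd_experiment(seed = 2)
  d$yield_pct <- 5  # constant response column
  expect_error(ann_train(d, hidden = 3, train_config(seed = 1)),
               "degenerate scaler")
  d2 <- simulate_bbd_experiment(seed = 2)[1:8, ]
  expect_error(ann_train(d2, hidden = 3, train_config(seed = 1)),
               "at least 10")
})
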