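test_that("noiseless quadratic data is interpolated exactly", {
  gt <- uae_ground_truth()
  d <- simulate_bbd_experiment(noise_scale = 0, seed = 1)
  for (nm in response_names()) {
    surf <- fit_quadratic(d, nm)
    expect_lt(max(abs(surf$coefficients - gt$surfaces[[nm]]$coefficients)),
              1e-8)
  }
})

test_that("a constant response yields a pure-intercept surface", {
  d <- make_bbd()
  d$flat <- rep(7.5, nrow(d))
  surf <- fit_quadratic(d, "flat")
  expect_equal(unname(surf$coefficients[1]), 7.5)
  expect_lt(max(abs(surf$coefficients[-1])), 1e-10)
})

test_that("surface evaluation matches independent hand arithmetic", {
  gt <- uae_ground_truth()
  y <- gt$surfaces$yield_pct
  expect_equal(evaluate_surface(y, c(0, 0, 0)), 26.4683)
  # term-by-term evaluation at the coded optimum settings
  expect_equal(evaluate_surface(y, c(-0.5, -0.4, 0.4)), 29.33912,
               tolerance = 1e-3)
  expect_equal(evaluate_surface(gt$surfaces$tannins_tae, c(0, 0, 0)),
               122.83)
  # vectorized evaluation agrees with row-wise evaluation
  pts <- matrix(runif(30, -1, 1), ncol = 3)
  expect_equal(evaluate_surface(y, pts),
               apply(pts, 1, function(p) evaluate_surface(y, p)))
})

test_that("noisy refits stay within the least-squares sampling distribution", {
  gt <- uae_ground_truth()
  d <- simulate_bbd_experiment(seed = 42)   # tannins SD 1.21
  surf <- fit_quadratic(d, "tannins_tae")
  se <- sqrt(diag(vcov(attr(surf, "fit"))))
  z <- (surf$coefficients - gt$surfaces$tannins_tae$coefficients) / se
  expect_lt(max(abs(z)), 3)
})

test_that("fit-evaluate is a projection (refitting predictions is idempotent)", {
  d <- simulate_bbd_experiment(seed = 8)
  surf <- fit_quadratic(d, "phenols_gae")
  d$refit <- evaluate_surface(surf, coded_matrix(d))
  surf2 <- fit_quadratic(d, "refit")
  expect_lt(max(abs(surf2$coefficients - surf$coefficients)), 1e-10)
})

test_that("fitted coefficients are invariant to run order", {
  d <- simulate_bbd_experiment(seed = 9)
  surf <- fit_quadratic(d, "yield_pct")
  set.seed(1)
  d2 <- d[sample.int(nrow(d)), ]
  surf2 <- fit_quadratic(d2, "yield_pct")
  expect_equal(surf2$coefficients, surf$coefficients, tolerance = 1e-10)
})

test_that("ANOVA partitions degrees of freedom as in a 12+6 BBD", {
  d <- simulate_bbd_experiment(seed = 5)
  a <- rsm_anova(d, "yield_pct")
  expect_equal(a$model$df, 9L)
  expect_equal(a$residual$df, 8L)
  expect_equal(a$pure_error$df, 5L)       # 6 center replicates
  expect_equal(a$lack_of_fit$df, 3L)
  expect_equal(a$lack_of_fit$df + a$pure_error$df, a$residual$df)
  expect_equal(nrow(a$terms), 9L)
  expect_true(all(a$terms$df == 1L))
  # SS identity
  expect_equal(a$model$sum_sq + a$residual$sum_sq,
               sum((d$yield_pct - mean(d$yield_pct))^2))
  # pure error equals center-replicate scatter, computed directly
  centers <- d$yield_pct[rowSums(coded_matrix(d) == 0) == 3L]
  expect_equal(a$pure_error$sum_sq, sum((centers - mean(centers))^2))
})

test_that("sequential term SS match closed-form values on the orthogonal columns", {
  # on the 12+6 BBD, linear and interaction columns are mutually
  # orthogonal and orthogonal to the quadratic block, so their
  # sequential SS equal (column sum of squares) x coefficient^2
  d <- simulate_bbd_experiment(seed = 13)
  a <- rsm_anova(d, "antioxidant_pct")
  surf <- fit_quadratic(d, "antioxidant_pct")
  b <- surf$coefficients
  expected <- c(A = 8 * b[["A"]]^2, B = 8 * b[["B"]]^2, C = 8 * b[["C"]]^2,
                AB = 4 * b[["AB"]]^2, AC = 4 * b[["AC"]]^2,
                BC = 4 * b[["BC"]]^2)
  got <- setNames(a$terms$sum_sq[1:6], a$terms$term[1:6])
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("ANOVA summary statistics obey their defining inequalities", {
  d <- simulate_bbd_experiment(seed = 77)
  for (nm in c("yield_pct", "tannins_tae")) {
    a <- rsm_anova(d, nm)
    expect_gte(a$r_squared, 0); expect_lte(a$r_squared, 1)
    expect_lte(a$pred_r_squared, a$adj_r_squared)
    expect_lte(a$adj_r_squared, a$r_squared)
    expect_equal(a$cv_percent, 100 * a$sd / a$mean)
    expect_gte(a$press, a$residual$sum_sq)  # PRESS >= SSE
  }
  # noiseless: perfect fit
  d0 <- simulate_bbd_experiment(seed = 1, noise_scale = 0)
  a0 <- suppressWarnings(rsm_anova(d0, "yield_pct"))  # perfect-fit F warning
  expect_equal(a0$r_squared, 1, tolerance = 1e-10)
  expect_lt(a0$sd, 1e-6)
})

test_that("lack of fit is reported absent without replicated runs", {
  d <- simulate_bbd_experiment(center_reps = 1, seed = 3)
  a <- rsm_anova(d, "yield_pct")
  expect_null(a$lack_of_fit)
  expect_null(a$pure_error)
  expect_equal(a$residual$df, 3L)   # 13 runs - 10 coefficients
})

test_that("refits of low-noise data reproduce the published sign structure", {
  # negative time and temperature main effects, positive ratio effect
  d <- simulate_bbd_experiment(seed = 6, noise_scale = 0.25)
  for (nm in response_names()) {
    b <- fit_quadratic(d, nm)$coefficients
    expect_lt(b[["A"]], 0)
    expect_lt(b[["B"]], 0)
    expect_gt(b[["C"]], 0)
  }
})

test_that("surfaces round-trip through JSON", {
  d <- simulate_bbd_experiment(seed = 30)
  surf <- fit_quadratic(d, "flavonoids_qe")
  path <- tempfile(fileext = ".json")
  write_surface(surf, path)
  surf2 <- read_surface(path)
  expect_equal(surf2$coefficients, surf$coefficients, tolerance = 1e-12)
  expect_equal(surf2$response_name, surf$response_name)
  a <- rsm_anova(d, "flavonoids_qe")
  path2 <- tempfile(fileext = ".json")
  write_anova(a, path2)
  parsed <- jsonlite::read_json(path2, simplifyVector = TRUE)
  expect_equal(parsed$r_squared, a$r_squared, tolerance = 1e-12)
  unlink(c(path, path2))
})

test_that("fitting fails cleanly on bad input", {
  d <- make_bbd()
  expect_error(fit_quadratic(d, "yield_pct"), "no response column")
  d$yield_pct <- c(NA, rnorm(17))
  expect_error(fit_quadratic(d, "yield_pct"), "non-finite")
  # rank deficiency: all runs at the same point
  dc <- d[rep(13, 12), ]
  dc$yield_pct <- rnorm(12)
  expect_error(fit_quadratic(dc, "yield_pct"), "rank-deficient")
})
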