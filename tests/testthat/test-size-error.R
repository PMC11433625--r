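test_that("detection-limit filter keeps the boundary", {
  expect_equal(filter_detectable(c(80, 150, 400)), c(150, 400))
  expect_equal(filter_detectable(numeric()), numeric())
  expect_equal(filter_detectable(100), 100)
})

test_that("OLS calibration matches the closed-form normal equations", {
  # perfect identity data
  d <- data.frame(expected = c(100, 300, 500, 800),
                  measured = c(100, 300, 500, 800))
  m <- fit_lm(d)
  expect_equal(m$beta0, 0, tolerance = 1e-10)
  expect_equal(m$beta1, 1, tolerance = 1e-10)
  expect_equal(m$sigma, 0, tolerance = 1e-8)

  set.seed(50)
  d2 <- data.frame(expected = runif(80, 100, 900))
  d2$measured <- 3 + 0.95 * d2$expected + rnorm(80, sd = 5)
  m2 <- fit_lm(d2)
  x <- d2$expected; y <- d2$measured
  b1 <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(m2$beta1, b1, tolerance = 1e-10)
  expect_equal(m2$beta0, b0, tolerance = 1e-10)
  expect_equal(m2$delta, 0)
  expect_equal(m2$phi, 0)

  expect_error(fit_lm(data.frame(expected = c(1, 1, 1),
                                 measured = c(1, 2, 3))), "distinct")
})

test_that("OLS estimates are unbiased within Monte-Carlo error", {
  set.seed(51)
  hits <- 0L
  for (r in 1:20) {
    x <- runif(200, 100, 900)
    y <- 3 + 0.95 * x + rnorm(200, sd = 4)
    m <- fit_lm(data.frame(expected = x, measured = y))
    se1 <- 4 / sqrt(sum((x - mean(x))^2))
    if (abs(m$beta1 - 0.95) < 3 * se1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("varpow reduces to the OLS fit when delta = phi = 0", {
  d <- synth_calibration(noise_spec(sigma = 3, delta = 0, phi = 0),
                         n_lanes = 50, fragments_per_lane = 10, seed = 52)
  mv <- fit_varpow(d)
  ml <- fit_lm(d)
  expect_lt(abs(mv$beta1 - ml$beta1), 0.01)
  expect_lt(abs(mv$delta), 0.15)
  expect_lt(abs(mv$phi), 0.15)
})

test_that("varpow log-likelihood dominates the nested OLS fit and matches an independent evaluation", {
  for (seed in c(53, 54, 55)) {
    d <- synth_calibration(noise_spec(), n_lanes = 20,
                           fragments_per_lane = 8, seed = seed)
    mv <- fit_varpow(d)
    ml <- fit_lm(d)
    expect_gte(mv$loglik, ml$loglik)
    # independent block-diagonal Gaussian likelihood at the fitted params
    expect_equal(calibration_loglik(mv, d), mv$loglik, tolerance = 1e-6)
    expect_equal(calibration_loglik(ml, d), ml$loglik, tolerance = 1e-6)
  }
})

test_that("permissive ranges invert the prediction band", {
  id <- structure(list(kind = "lm", beta0 = 0, beta1 = 1, sigma = 0,
                       delta = 0, phi = 0, level = 0.95,
                       min_detectable = 100, loglik = NA_real_, n = 0L,
                       converged = TRUE), class = "calibration_model")
  expect_equal(unname(permissive_range(id, 432)), c(432, 432))

  m <- structure(list(kind = "varpow", beta0 = 2, beta1 = 0.97, sigma = 1.5,
                      delta = 0.6, phi = 0.4, level = 0.95,
                      min_detectable = 100, loglik = NA_real_, n = 0L,
                      converged = TRUE), class = "calibration_model")
  r1 <- permissive_range(m, 200)
  r2 <- permissive_range(m, 600)
  expect_true(r1[1] < 200 / 0.97 && r1[2] > (200 - 2) / 0.97)
  # interval width grows with measured size (power variance)
  expect_gt(diff(r2), diff(r1))
  # band inversion: at the endpoints the measurement sits on the band edge
  z <- qnorm(0.975)
  g <- function(x) 2 + 0.97 * x
  expect_equal(g(r1[[1]]) + z * 1.5 * g(r1[[1]])^0.6, 200, tolerance = 1e-5)
  expect_equal(g(r1[[2]]) - z * 1.5 * g(r1[[2]])^0.6, 200, tolerance = 1e-5)

  bad <- m; bad$beta1 <- -1
  expect_error(permissive_range(bad, 300), "slope")
})

test_that("scale equivariance holds for delta = 0", {
  m <- structure(list(kind = "lm", beta0 = 5, beta1 = 0.95, sigma = 4,
                      delta = 0, phi = 0, level = 0.95, min_detectable = 0,
                      loglik = NA_real_, n = 0L, converged = TRUE),
                 class = "calibration_model")
  r <- permissive_range(m, 400)
  mc <- m; mc$beta0 <- m$beta0 * 10; mc$sigma <- m$sigma * 10
  rc <- permissive_range(mc, 4000)
  expect_equal(unname(rc), unname(10 * r), tolerance = 1e-6)
})

test_that("coverage of the permissive range is close to nominal", {
  set.seed(56)
  m <- structure(list(kind = "varpow", beta0 = 2, beta1 = 0.97, sigma = 1.5,
                      delta = 0.6, phi = 0, level = 0.95,
                      min_detectable = 100, loglik = NA_real_, n = 0L,
                      converged = TRUE), class = "calibration_model")
  n <- 2000
  x <- runif(n, 120, 900)
  mu <- m$beta0 + m$beta1 * x
  meas <- mu + m$sigma * mu^m$delta * rnorm(n)
  rng <- permissive_range(m, meas)
  covered <- x >= rng[, 1] & x <= rng[, 2]
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})
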