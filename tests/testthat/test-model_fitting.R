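yF_grid15 <- exp(seq(log(2), log(200), length.out = 15))

# local helper mirroring the package's ascending polynomial convention
polyval_at <- function(coefs, x) coefs[1] + coefs[2] * x + coefs[3] * x^2

test_that("saturation fit recovers noiseless and noisy parameters", {
  truth <- c(N_max = 100, a_sat = 0.01)
  N <- truth["N_max"] * (1 - exp(-truth["a_sat"] * yF_grid15))
  fit <- fit_saturation(yF_grid15, N)
  expect_equal(fit$parameters[["N_max"]], 100, tolerance = 1e-3)
  expect_equal(fit$parameters[["a_sat"]], 0.01, tolerance = 1e-3)

  set.seed(21)
  N_noisy <- N * rlnorm(15, sdlog = 0.05)
  fit2 <- fit_saturation(yF_grid15, N_noisy)
  expect_equal(fit2$parameters[["N_max"]], 100, tolerance = 0.1)
  expect_equal(fit2$parameters[["a_sat"]], 0.01, tolerance = 0.1)
  expect_lt(fit2$r_squared, 1)
  expect_error(fit_saturation(c(1, 2), c(1, 2)), "3 distinct")
})

test_that("linear and linear-quadratic fits are exact on exact data", {
  expect_equal(fit_linear(yF_grid15, 0.5 * yF_grid15)$parameters[["k_direct"]],
               0.5, tolerance = 1e-12)
  lq <- fit_linear_quadratic(yF_grid15, 0.1 * yF_grid15 + 0.002 * yF_grid15^2)
  expect_equal(lq$parameters[["c1"]], 0.1, tolerance = 1e-10)
  expect_equal(lq$parameters[["c2"]], 0.002, tolerance = 1e-10)
  expect_false(attr(lq$parameters, "constrained"))
  # concave data activates the c2 >= 0 constraint
  lq2 <- fit_linear_quadratic(yF_grid15, 2 * sqrt(yF_grid15))
  expect_true(attr(lq2$parameters, "constrained"))
  expect_equal(lq2$parameters[["c2"]], 0)
})

test_that("gamma MLE recovers the generating parameters within 2% at n = 1e5", {
  set.seed(100)
  x <- rgamma(1e5, shape = 4, rate = 0.8)
  fit <- fit_gamma(x, method = "mle")
  expect_equal(fit$parameters[["a"]], 4, tolerance = 0.02)
  expect_equal(fit$parameters[["b"]], 0.8, tolerance = 0.02)
  # the two fitting routes agree within joint uncertainty at large n
  hfit <- fit_gamma(x, method = "histogram-ls")
  se <- sqrt(diag(fit$covariance))
  expect_lt(abs(hfit$parameters[["a"]] - fit$parameters[["a"]]), 6 * se["a"])
  expect_lt(abs(hfit$parameters[["b"]] - fit$parameters[["b"]]), 6 * se["b"])
  expect_gt(hfit$r_squared, 0.999)
  expect_error(fit_gamma(rep(3, 50)), "degenerate")
  expect_error(fit_gamma(rgamma(10, 4, 1) + 2), "at least 30")
})

test_that("quadratic trends of (a, b) are recovered from exact and noisy points", {
  truth <- default_truth_params()$gamma
  pq <- data.frame(yF = yF_grid15,
                   a = polyval_at(truth$poly_a, yF_grid15),
                   b = polyval_at(truth$poly_b, yF_grid15))
  g <- fit_gamma_trend(pq)
  expect_equal(g$poly_a, truth$poly_a, tolerance = 1e-8)
  expect_equal(g$poly_b, truth$poly_b, tolerance = 1e-8)
  expect_gt(attr(g, "fits")$a$r_squared, 1 - 1e-10)

  # 5% multiplicative noise: typical recovery within 10% sup-norm over the
  # range (a statistical claim, so assessed as the median over a block of
  # replicate noise draws)
  grid <- seq(2, 200, length.out = 200)
  sup_err <- sapply(1:10, function(s) {
    set.seed(s)
    pq_noisy <- transform(pq, a = a * rlnorm(15, sdlog = 0.05),
                          b = b * rlnorm(15, sdlog = 0.05))
    g2 <- fit_gamma_trend(pq_noisy, weights = "relative")
    c(max(abs(polyval_at(g2$poly_a, grid) - polyval_at(truth$poly_a, grid)) /
            polyval_at(truth$poly_a, grid)),
      max(abs(polyval_at(g2$poly_b, grid) - polyval_at(truth$poly_b, grid)) /
            polyval_at(truth$poly_b, grid)))
  })
  expect_lt(median(sup_err[1, ]), 0.1)
  expect_lt(median(sup_err[2, ]), 0.1)

  # constant parameters give (numerically) zero curvature
  gc <- fit_gamma_trend(data.frame(yF = yF_grid15, a = 3, b = 0.8))
  expect_equal(gc$poly_a[2:3], c(0, 0), tolerance = 1e-10)
  expect_error(fit_gamma_trend(data.frame(yF = c(1, 2), a = 1:2, b = 1:2)),
               "3 distinct")
})

test_that("R^2 is invariant under data reordering", {
  set.seed(5)
  N <- 100 * (1 - exp(-0.02 * yF_grid15)) * rlnorm(15, sdlog = 0.03)
  perm <- sample(15)
  f1 <- fit_saturation(yF_grid15, N)
  f2 <- fit_saturation(yF_grid15[perm], N[perm])
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
})


test_that("full calibration on noiseless fixtures reproduces the truth", {
  truth <- mgm_ground_truth(seed = 10)
  fitted <- calibrate_mgm(make_quality_yields(truth))
  t <- truth$mgm
  expect_equal(fitted$sb$k_direct, t$sb$k_direct, tolerance = 1e-6)
  expect_equal(fitted$sb$N_max, t$sb$N_max, tolerance = 1e-6)
  expect_equal(fitted$bd$a_sat, t$bd$a_sat, tolerance = 1e-6)
  expect_equal(fitted$ds_dsb$c1, t$ds_dsb$c1, tolerance = 1e-6)
  expect_equal(fitted$gamma$poly_a, t$gamma$poly_a, tolerance = 1e-6)
})
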