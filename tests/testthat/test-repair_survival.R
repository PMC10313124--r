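test_that("sigmoid lethality hits its anchors and limits", {
  for (d in c(0.5, 1, 5)) for (C05 in c(3, 5, 10)) {
    expect_equal(p_lethal(C05, repair_model_params(d, C05)), 0.5)
  }
  rp <- repair_model_params(d = 1, C0_5 = 5)
  expect_equal(p_lethal(7, rp), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_true(all(diff(p_lethal(seq(0, 20, 0.5), rp)) > 0))
  # steep repair: sub-threshold damage is never lethal
  expect_lt(p_lethal(4, repair_model_params(d = 50, C0_5 = 5)), 1e-9)
  expect_error(repair_model_params(-1, 5), "> 0")
})

test_that("Poisson site survival matches a Monte Carlo oracle", {
  # mu = 2 sites, mean lethality 0.5 -> S = exp(-1)
  expect_equal(poisson_survival(2, 0.5), exp(-1), tolerance = 1e-12)
  set.seed(14)
  n <- 1e6
  lethal <- rbinom(n, rpois(n, 2), 0.5)
  mc <- mean(lethal == 0)
  expect_lt(abs(mc - exp(-1)), 4 * sqrt(exp(-1) * (1 - exp(-1)) / n))
  expect_equal(poisson_survival(c(1, 2), 0), c(1, 1))
})

test_that("closed-form survival is sane in structure", {
  truth <- default_truth_params()
  rp <- repair_model_params(d = 1, C0_5 = 6)
  beam <- beam_spectrum(115.3)
  doses <- seq(0, 6, by = 0.5)
  curve <- survival_closed_form(doses, beam, truth, repair = rp)
  expect_equal(curve$survival[1], 1)
  expect_true(all(diff(curve$survival) < 0))
  expect_true(all(curve$survival > 0 & curve$survival <= 1))
  # single-quality exponent is linear in dose -> pure alpha, beta ~ 0
  lnS <- -log(curve$survival[-1])
  expect_equal(max(abs(lnS / doses[-1] - lnS[1] / doses[2])), 0,
               tolerance = 1e-9)
  expect_equal(attr(curve, "beta"), 0, tolerance = 1e-10)
})

test_that("raising the complexity shape lowers survival", {
  rp <- repair_model_params(d = 1, C0_5 = 6)
  base <- default_truth_params()$gamma
  shifted <- gamma_complexity_params(poly_a = base$poly_a + c(1, 0, 0),
                                     poly_b = base$poly_b)
  expect_gt(mean_lethality(50, shifted, rp), mean_lethality(50, base, rp))
})

test_that("Monte Carlo and closed-form survival agree within binomial error", {
  truth <- default_truth_params()
  rp <- repair_model_params(d = 1, C0_5 = 6)
  beam <- beam_spectrum(yF = c(10.95, 115.3), weights = c(0.3, 0.7))
  doses <- c(0.5, 1, 2, 4)
  n_reps <- 4000
  cf <- survival_closed_form(doses, beam, truth, repair = rp)
  mc <- survival_mc(doses, beam, truth, repair = rp, n_reps = n_reps,
                    seed = 2024)
  se <- sqrt(cf$survival * (1 - cf$survival) / n_reps)
  expect_true(all(abs(mc$survival - cf$survival) <= 4 * se + 1e-12))
})

test_that("discretization of the complexity law is consistent across paths", {
  # continuous-law closed form must match continuous-mode quadrature
  g <- default_truth_params()$gamma
  rp <- repair_model_params(d = 1.2, C0_5 = 5)
  el_disc <- mean_lethality(50, g, rp, discretize = TRUE)
  el_cont <- mean_lethality(50, g, rp, discretize = FALSE)
  expect_gt(el_disc, 0); expect_lt(el_disc, 1)
  # the discretized expectation equals a direct large-sample average
  set.seed(6)
  cx <- sample_complexities(2e5, 50, g)
  expect_equal(mean(p_lethal(cx, rp)), el_disc, tolerance = 0.01)
  expect_false(isTRUE(all.equal(el_disc, el_cont, tolerance = 1e-6)))
})

test_that("LQ fitting recovers exact, exponential and noisy curves", {
  doses <- seq(0.5, 6, by = 0.5)
  S <- exp(-(0.2 * doses + 0.05 * doses^2))
  fit <- fit_lq(doses, S)
  expect_equal(fit$parameters[["alpha"]], 0.2, tolerance = 1e-10)
  expect_equal(fit$parameters[["beta"]], 0.05, tolerance = 1e-10)

  fit_exp <- fit_lq(doses, exp(-0.3 * doses))
  expect_equal(fit_exp$parameters[["beta"]], 0, tolerance = 1e-10)

  set.seed(44)
  S_noisy <- exp(-(0.2 * doses + 0.05 * doses^2) * rlnorm(12, sdlog = 0.02))
  fit_n <- fit_lq(doses, S_noisy)
  expect_equal(fit_n$parameters[["alpha"]], 0.2, tolerance = 0.1)
  expect_equal(fit_n$parameters[["beta"]], 0.05, tolerance = 0.1)
  expect_error(fit_lq(c(1, 2), c(0.9, 0.8)), "3 distinct")
  expect_error(fit_lq(doses, rep(1.2, 12)), "in \\(0, 1\\]")
})

test_that("RBE ratios behave as dose ratios and alpha ratios", {
  truth <- default_truth_params()
  rp <- repair_model_params(d = 1, C0_5 = 6)
  doses <- seq(0, 8, by = 0.5)
  low <- survival_closed_form(doses, beam_spectrum(2), truth, repair = rp)
  high <- survival_closed_form(doses, beam_spectrum(115.3), truth, repair = rp)
  # self-comparison is 1 at every level
  for (L in c(0.9, 0.5, 0.1))
    expect_equal(rbe(low, low, L)$rbe, 1, tolerance = 1e-12)
  # the high-LET radiation needs less dose than the low-LET reference
  r <- rbe(low, high, 0.1)
  expect_gt(r$rbe, 1)
  expect_equal(r$dose_reference_Gy / r$dose_test_Gy, r$rbe)
  # hand-built curves with known 10%-survival doses of 6 and 3 Gy
  a_ref <- -log(0.1) / 6; a_test <- -log(0.1) / 3
  curve_ref <- structure(data.frame(dose_Gy = doses, survival = exp(-a_ref * doses)),
                         class = c("survival_curve", "data.frame"),
                         alpha = a_ref, beta = 0)
  curve_test <- structure(data.frame(dose_Gy = doses, survival = exp(-a_test * doses)),
                          class = c("survival_curve", "data.frame"),
                          alpha = a_test, beta = 0)
  expect_equal(rbe(curve_ref, curve_test, 0.1)$rbe, 2, tolerance = 1e-12)
  expect_equal(rbe_alpha_ratio(0.2, 0.4)$rbe, 2)
})
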