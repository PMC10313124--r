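#' Sigmoid repair-model parameters
#'
#' An illustrative repair model: the probability that a damage site becomes
#' irreparable (lethal) is a logistic function of its complexity. `d`
#' controls repair efficiency (steepness, per complexity unit) and `C0_5`
#' is the complexity at which lethality is exactly 50%.
#'
#' @param d Steepness, > 0.
#' @param C0_5 Half-effect complexity, > 0.
#' @return An object of class `repair_model_params`.
#' @export
repair_model_params <- function(d, C0_5) {
  if (d <= 0 || C0_5 <= 0) stop("d and C0_5 must be > 0", call. = FALSE)
  structure(list(d = d, C0_5 = C0_5), class = "repair_model_params")
}

#' Per-site lethality probability
#'
#' `p(C) = 1 / (1 + exp(-d * (C - C0.5)))`, strictly increasing in `C` and
#' equal to 0.5 exactly at `C = C0.5`.
#'
#' @param C Complexity, >= 0 (vectorized).
#' @param params A [repair_model_params()].
#' @return Lethality probabilities in (0, 1).
#' @examples
#' p_lethal(5, repair_model_params(d = 1, C0_5 = 5))  # 0.5
#' @export
p_lethal <- function(C, params) {
  stopifnot(inherits(params, "repair_model_params"))
  if (any(C < 0)) stop("complexity must be >= 0", call. = FALSE)
  1 / (1 + exp(-params$d * (C - params$C0_5)))
}

# Probability mass of the discretized complexity law (round to nearest
# integer, clamp at 2) on k = 2..kmax; matches sample_complexities().
discretized_complexity_pmf <- function(yF, gamma, tail_prob = 1e-12) {
  p <- gamma_params_at(yF, gamma)
  kmax <- max(3, ceiling(qgamma(1 - tail_prob, shape = p$a, rate = p$b)) + 1)
  k <- 2:kmax
  upper <- pgamma(k + 0.5, shape = p$a, rate = p$b)
  lower <- c(0, upper[-length(upper)])  # everything below 2.5 maps to C = 2
  mass <- upper - lower
  mass[length(mass)] <- mass[length(mass)] + (1 - upper[length(upper)])
  list(k = k, mass = mass)
}

#' Mean lethality of a site at a given radiation quality
#'
#' Expectation of [p_lethal()] under the complexity law at `yF`: a sum over
#' the discretized law (default, matching the generator) or Gauss quadrature
#' of the continuous Gamma density.
#'
#' @param yF Lineal energy, keV/um (scalar).
#' @param gamma A [gamma_complexity_params()].
#' @param repair A [repair_model_params()].
#' @param discretize Use the discretized complexity law (default `TRUE`).
#' @return Scalar in (0, 1).
#' @export
mean_lethality <- function(yF, gamma, repair, discretize = TRUE) {
  if (discretize) {
    pmf <- discretized_complexity_pmf(yF, gamma)
    sum(pmf$mass * p_lethal(pmf$k, repair))
  } else {
    p <- gamma_params_at(yF, gamma)
    f <- function(C) dgamma(C, shape = p$a, rate = p$b) * p_lethal(C, repair)
    q <- integrate(f, 0, Inf, rel.tol = 1e-10)
    if (q$message != "OK") stop("quadrature failed: ", q$message, call. = FALSE)
    q$value
  }
}

#' Survival probability under Poisson site statistics
#'
#' If the number of damage sites is Poisson with mean `mu` and sites become
#' lethal independently with mean probability `p_mean`, the cell survives
#' with probability `exp(-mu * p_mean)` (the expectation of the product of
#' per-site survivals). Building block of the closed-form survival curve.
#'
#' @param mu Expected number of sites, >= 0.
#' @param p_mean Mean per-site lethality in `[0, 1]`.
#' @return Survival probability.
#' @export
poisson_survival <- function(mu, p_mean) {
  stopifnot(all(mu >= 0), all(p_mean >= 0), all(p_mean <= 1))
  exp(-mu * p_mean)
}

# Per-component Poisson intensities at 1 Gy: expected tracks per Gy and
# expected DSB-containing sites per track.
component_intensities <- function(beam, params, nucleus) {
  lambda_T <- vapply(seq_len(nrow(beam)), function(ci)
    beam$weight[ci] / yF_to_zF(beam$yF[ci], nucleus), numeric(1))
  lambda_s <- suppressWarnings(
    n_ds_with_dsb(beam$yF, params$ds_dsb$c1, params$ds_dsb$c2))
  data.frame(yF = beam$yF, tracks_per_Gy = lambda_T, sites_per_track = lambda_s)
}

#' Closed-form survival curve
#'
#' Analytic counterpart of [survival_mc()] under the generator's
#' statistics: track counts are Poisson, site counts per track are Poisson,
#' and complexities are iid, so the survival probability is the compound
#' Poisson generating function evaluated at the mean per-site survival,
#' \deqn{S(D) = \exp\!\big(-\sum_c \lambda_{T,c}(D)\,
#'   (1 - e^{-\lambda_{s,c}\,\bar p_c})\big),}
#' summed over spectral components. For small per-track site yields this
#' reduces to `exp(-mu(D) * p_mean)` with `mu(D)` the expected total site
#' count ([poisson_survival()]).
#'
#' @param doses Dose grid, Gy, >= 0.
#' @param beam A [beam_spectrum()].
#' @param params An [mgm_parameters()].
#' @param nucleus A [nucleus_geometry()].
#' @param repair A [repair_model_params()].
#' @param discretize Use the discretized complexity law (default `TRUE`,
#'   matching the generator).
#' @return A data frame of class `survival_curve` with columns `dose_Gy`
#'   and `survival`, and attributes `alpha`, `beta` (LQ fit over the grid)
#'   and `method = "closed_form"`.
#' @export
survival_closed_form <- function(doses, beam, params,
                                 nucleus = nucleus_geometry(), repair,
                                 discretize = TRUE) {
  stopifnot(all(doses >= 0))
  intens <- component_intensities(beam, params, nucleus)
  p_bar <- vapply(intens$yF, mean_lethality, numeric(1),
                  gamma = params$gamma, repair = repair,
                  discretize = discretize)
  per_track_kill <- 1 - exp(-intens$sites_per_track * p_bar)
  surv <- vapply(doses, function(D)
    exp(-sum(intens$tracks_per_Gy * D * per_track_kill)), numeric(1))
  as_survival_curve(doses, surv, method = "closed_form")
}

#' Monte Carlo survival curve
#'
#' For each dose, `n_reps` independent damage realizations are drawn with
#' the generator's statistics (Poisson tracks, Poisson sites per track,
#' Gamma complexities); each site becomes lethal with probability
#' [p_lethal()] of its complexity, and the survival fraction is the
#' proportion of realizations with no lethal site.
#'
#' @inheritParams survival_closed_form
#' @param n_reps Realizations per dose, >= 1.
#' @param seed Optional integer seed (fixing it makes the curve
#'   reproducible).
#' @return A `survival_curve` data frame (attributes `alpha`, `beta`,
#'   `method = "mc"`, `n_reps`).
#' @export
survival_mc <- function(doses, beam, params, nucleus = nucleus_geometry(),
                        repair, n_reps = 1e4, seed = NULL,
                        discretize = TRUE) {
  stopifnot(all(doses >= 0), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  intens <- component_intensities(beam, params, nucleus)
  gp <- gamma_params_at(intens$yF, params$gamma)

  surv <- vapply(doses, function(D) {
    if (D == 0) return(1)
    lethal_any <- rep(FALSE, n_reps)
    for (ci in seq_len(nrow(intens))) {
      n_tracks <- rpois(n_reps, intens$tracks_per_Gy[ci] * D)
      # sum of per-track Poisson site counts is Poisson in the track total
      n_sites <- rpois(n_reps, n_tracks * intens$sites_per_track[ci])
      total <- sum(n_sites)
      if (total == 0) next
      cx <- rgamma(total, shape = gp$a[ci], rate = gp$b[ci])
      if (discretize) cx <- pmax(2, round(cx))
      lethal <- runif(total) < p_lethal(cx, repair)
      rep_id <- rep.int(seq_len(n_reps), n_sites)
      hit <- unique(rep_id[lethal])
      lethal_any[hit] <- TRUE
    }
    mean(!lethal_any)
  }, numeric(1))
  as_survival_curve(doses, surv, method = "mc", n_reps = n_reps)
}

as_survival_curve <- function(doses, survival, method, n_reps = NULL) {
  out <- data.frame(dose_Gy = doses, survival = survival)
  class(out) <- c("survival_curve", "data.frame")
  attr(out, "method") <- method
  if (!is.null(n_reps)) attr(out, "n_reps") <- n_reps
  usable <- doses > 0 & survival > 0 & survival <= 1
  if (sum(usable) >= 3) {
    lq <- fit_lq(doses[usable], survival[usable])
    attr(out, "alpha") <- lq$parameters[["alpha"]]
    attr(out, "beta") <- lq$parameters[["beta"]]
  }
  out
}

#' Fit the linear-quadratic survival model
#'
#' Least squares of `-ln S = alpha*D + beta*D^2` through the origin, with
#' both coefficients constrained non-negative (a negative unconstrained
#' estimate is set to zero and the other coefficient refitted).
#'
#' @param doses Dose grid, Gy, > 0, >= 3 distinct values.
#' @param survival Survival fractions in (0, 1].
#' @return An `mgm_fit` with parameters `alpha` (1/Gy) and `beta` (1/Gy^2).
#' @export
fit_lq <- function(doses, survival) {
  if (length(unique(doses)) < 3L)
    stop("need at least 3 distinct dose points", call. = FALSE)
  if (any(survival <= 0 | survival > 1))
    stop("survival must be in (0, 1]", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  y <- -log(survival)
  df <- data.frame(D = doses, y = y)
  fit <- lm(y ~ 0 + D + I(D^2), data = df)
  est <- unname(coef(fit))
  constrained <- FALSE
  if (est[2] < 0) {
    fit <- lm(y ~ 0 + D, data = df); est <- c(unname(coef(fit)), 0)
    constrained <- TRUE
  } else if (est[1] < 0) {
    fit <- lm(y ~ 0 + I(D^2), data = df); est <- c(0, unname(coef(fit)))
    constrained <- TRUE
  }
  params <- c(alpha = max(0, est[1]), beta = max(0, est[2]))
  attr(params, "constrained") <- constrained
  mgm_fit(
    parameters = params,
    covariance = if (constrained) NULL else suppressWarnings(vcov(fit)),
    r_squared = r_squared_of(y, params[1] * doses + params[2] * doses^2),
    residuals = y - (params[1] * doses + params[2] * doses^2),
    method = "linear-quadratic least squares on -ln S"
  )
}

# Dose achieving a survival level under the LQ model: the quadratic formula
# in its rationalized form, which stays stable as beta -> 0.
lq_dose <- function(alpha, beta, survival_level) {
  stopifnot(survival_level > 0, survival_level < 1)
  e <- -log(survival_level)
  if (alpha <= 0 && beta <= 0)
    stop("alpha and beta are both zero; level unreachable", call. = FALSE)
  2 * e / (alpha + sqrt(alpha^2 + 4 * max(beta, 0) * e))
}

#' Relative biological effectiveness at a survival level
#'
#' `rbe()` is the ratio of reference to test dose producing the same
#' survival, with doses solved analytically from each curve's fitted LQ
#' parameters. `rbe_alpha_ratio()` is the low-dose limit computed as the
#' ratio of the fitted alpha parameters (labelled `"RBE min"` after the
#' naming used with this model; for high-LET radiation this limit is
#' conventionally the maximum of RBE vs dose).
#'
#' @param reference,test `survival_curve` objects carrying fitted `alpha`
#'   and `beta` attributes (see [survival_closed_form()]).
#' @param survival_level Survival fraction at which doses are compared
#'   (e.g. 0.9, 0.5, 0.1).
#' @return A list of class `rbe_result` with elements `survival_level`,
#'   `rbe`, `dose_reference_Gy`, `dose_test_Gy`.
#' @export
rbe <- function(reference, test, survival_level) {
  get_lq <- function(curve, what) {
    a <- attr(curve, "alpha"); b <- attr(curve, "beta")
    if (is.null(a) || is.null(b))
      stop(what, " curve carries no LQ fit (too few usable points)",
           call. = FALSE)
    c(a, b)
  }
  lr <- get_lq(reference, "reference"); lt <- get_lq(test, "test")
  d_ref <- lq_dose(lr[1], lr[2], survival_level)
  d_test <- lq_dose(lt[1], lt[2], survival_level)
  structure(
    list(survival_level = survival_level, rbe = d_ref / d_test,
         dose_reference_Gy = d_ref, dose_test_Gy = d_test),
    class = "rbe_result"
  )
}

#' @rdname rbe
#' @param alpha_reference,alpha_test Fitted LQ alpha parameters, 1/Gy.
#' @export
rbe_alpha_ratio <- function(alpha_reference, alpha_test) {
  if (alpha_reference <= 0) stop("reference alpha must be > 0", call. = FALSE)
  structure(
    list(survival_level = "alpha_ratio (RBE min label)",
         rbe = alpha_test / alpha_reference,
         dose_reference_Gy = NA_real_, dose_test_Gy = NA_real_),
    class = "rbe_result"
  )
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("RBE = %.4g at level %s\n", x$rbe,
              format(x$survival_level)))
  invisible(x)
}
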