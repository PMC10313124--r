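#' Fit results
#'
#' Lightweight container returned by all calibration routines.
#'
#' @param parameters Named numeric vector of fitted parameters.
#' @param covariance Parameter covariance matrix (may be `NULL` when not
#'   available, e.g. for constrained fits).
#' @param r_squared Coefficient of determination, `1 - SS_res/SS_tot`,
#'   computed on the fitted scale.
#' @param residuals Residual vector on the fitted scale.
#' @param method Free-text description of the fitting method.
#' @return An object of class `mgm_fit`.
#' @keywords internal
mgm_fit <- function(parameters, covariance, r_squared, residuals, method) {
  structure(
    list(parameters = parameters, covariance = covariance,
         r_squared = r_squared, residuals = residuals, method = method),
    class = "mgm_fit"
  )
}

#' @export
print.mgm_fit <- function(x, ...) {
  cat("MGM fit (", x$method, ")\n", sep = "")
  print(signif(x$parameters, 6))
  cat(sprintf("R^2 = %.6f\n", x$r_squared))
  invisible(x)
}

r_squared_of <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

#' Fit the indirect-damage saturation law
#'
#' Nonlinear least squares for `N(yF) = N_max * (1 - exp(-a_sat * yF))`
#' (via `minpack.lm::nlsLM`), starting at `N_max = 1.2 * max(N)` and
#' `a_sat = 1 / median(yF)`.
#'
#' @param yF Lineal energies, keV/um, at least 3 distinct values.
#' @param N Observed indirect yields per track.
#' @param weights Optional least-squares weights (e.g. inverse bootstrap
#'   variances, or inverse squared values for multiplicative noise);
#'   unweighted by default.
#' @return An `mgm_fit` with parameters `N_max` and `a_sat`.
#' @export
fit_saturation <- function(yF, N, weights = NULL) {
  if (length(unique(yF)) < 3L)
    stop("need at least 3 distinct yF values", call. = FALSE)
  if (length(yF) != length(N)) stop("length mismatch", call. = FALSE)
  start <- list(N_max = 1.2 * max(N), a_sat = 1 / median(yF))
  dat <- data.frame(yF = yF, N = N, w = weights %||% rep(1, length(yF)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      N ~ N_max * (1 - exp(-a_sat * yF)),
      data = dat, weights = dat$w,
      start = start, lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12)
    ),
    error = function(e) stop(
      sprintf("saturation fit failed to converge (start N_max = %.4g, a_sat = %.4g): %s",
              start$N_max, start$a_sat, conditionMessage(e)), call. = FALSE)
  )
  est <- coef(fit)
  mgm_fit(
    parameters = c(N_max = unname(est["N_max"]), a_sat = unname(est["a_sat"])),
    covariance = tryCatch(vcov(fit), error = function(e) NULL),
    r_squared = r_squared_of(N, stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    method = "nonlinear least squares (Levenberg-Marquardt)"
  )
}

#' Fit the linear direct-damage law
#'
#' Least squares through the origin for `N = k_direct * yF`.
#'
#' @param yF Lineal energies, keV/um, >= 2 points.
#' @param N Observed direct yields per track.
#' @inheritParams fit_saturation
#' @return An `mgm_fit` with parameter `k_direct`.
#' @export
fit_linear <- function(yF, N, weights = NULL) {
  if (length(yF) < 2L) stop("need at least 2 points", call. = FALSE)
  dat <- data.frame(yF = yF, N = N, w = weights %||% rep(1, length(yF)))
  fit <- lm(N ~ 0 + yF, data = dat, weights = w)
  mgm_fit(
    parameters = c(k_direct = unname(coef(fit))),
    covariance = suppressWarnings(vcov(fit)),
    r_squared = r_squared_of(N, stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    method = "linear least squares through origin"
  )
}

#' Fit the linear-quadratic DSB-site law
#'
#' Least squares through the origin for `N = c1*yF + c2*yF^2` with the
#' quadratic coefficient constrained non-negative: if the unconstrained
#' estimate of `c2` is negative, the fit is repeated with `c2 = 0` and the
#' active constraint is reported in the `constrained` attribute of the
#' parameters.
#'
#' @param yF Lineal energies, keV/um, >= 3 points.
#' @param N Observed DSB-containing-site yields per track.
#' @inheritParams fit_saturation
#' @return An `mgm_fit` with parameters `c1` and `c2`.
#' @export
fit_linear_quadratic <- function(yF, N, weights = NULL) {
  if (length(unique(yF)) < 3L)
    stop("need at least 3 distinct yF values", call. = FALSE)
  df <- data.frame(yF = yF, N = N, w = weights %||% rep(1, length(yF)))
  fit <- lm(N ~ 0 + yF + I(yF^2), data = df, weights = w)
  est <- unname(coef(fit))
  constrained <- FALSE
  if (est[2] < 0) {
    constrained <- TRUE
    fit <- lm(N ~ 0 + yF, data = df, weights = w)
    est <- c(unname(coef(fit)), 0)
  }
  params <- c(c1 = est[1], c2 = est[2])
  attr(params, "constrained") <- constrained
  mgm_fit(
    parameters = params,
    covariance = if (constrained) NULL else suppressWarnings(vcov(fit)),
    r_squared = r_squared_of(N, stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    method = "linear-quadratic least squares through origin"
  )
}

gamma_moment_start <- function(x) {
  m <- mean(x); v <- var(x)
  if (v <= 0) stop("degenerate (all-equal) complexity sample", call. = FALSE)
  c(a = m^2 / v, b = m / v)
}

# Histogram of arbitrary positive draws on unit-width bins centered on
# integers; used by the histogram least-squares Gamma fit.
unit_binned_histogram <- function(x) {
  breaks <- seq(floor(min(x)) - 0.5, ceiling(max(x)) + 0.5, by = 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, mass = h$counts / length(x))
}

#' Fit a Gamma law to complexity scores
#'
#' Two routes to the Gamma parameters of a complexity sample:
#' `"mle"` (default) is continuous-Gamma maximum likelihood on the raw
#' scores, solving the profile score equation
#' `log(a) - digamma(a) = log(mean(x)) - mean(log(x))` by root finding,
#' with `b = a / mean(x)`; `"histogram-ls"` is least squares of the Gamma
#' density against the unit-bin normalized histogram, the method matching
#' figure-style fits of binned complexity data. In both modes `r_squared`
#' is reported against the unit-bin histogram so fit qualities are
#' comparable.
#'
#' @param complexities Numeric scores, >= 30 values, all >= 2.
#' @param method `"mle"` or `"histogram-ls"`.
#' @return An `mgm_fit` with parameters `a` (shape) and `b` (rate).
#' @export
fit_gamma <- function(complexities, method = c("mle", "histogram-ls")) {
  method <- match.arg(method)
  x <- complexities
  if (length(x) < 30L) stop("need at least 30 complexity scores", call. = FALSE)
  if (any(x <= 0)) stop("scores must be positive", call. = FALSE)
  start <- gamma_moment_start(x)
  hist_df <- unit_binned_histogram(x)

  if (method == "mle") {
    s <- log(mean(x)) - mean(log(x))
    g <- function(a) log(a) - digamma(a) - s
    a_hat <- uniroot(g, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    b_hat <- a_hat / mean(x)
    n <- length(x)
    # observed Fisher information of the Gamma log-likelihood
    info <- n * matrix(c(trigamma(a_hat), -1 / b_hat,
                         -1 / b_hat, a_hat / b_hat^2), 2, 2)
    covariance <- solve(info)
    dimnames(covariance) <- list(c("a", "b"), c("a", "b"))
    method_label <- "Gamma maximum likelihood"
  } else {
    obj <- function(p) sum((dgamma(hist_df$mid, shape = p[1], rate = p[2]) -
                              hist_df$mass)^2)
    opt <- optim(start, obj, method = "L-BFGS-B",
                 lower = c(1e-6, 1e-6),
                 control = list(maxit = 10000, factr = 1e4))
    a_hat <- opt$par[1]; b_hat <- opt$par[2]
    covariance <- NULL
    method_label <- "Gamma histogram least squares"
  }
  fitted_mass <- dgamma(hist_df$mid, shape = a_hat, rate = b_hat)
  mgm_fit(
    parameters = c(a = unname(a_hat), b = unname(b_hat)),
    covariance = covariance,
    r_squared = r_squared_of(hist_df$mass, fitted_mass),
    residuals = hist_df$mass - fitted_mass,
    method = method_label
  )
}

#' Fit the quadratic yF-trends of the Gamma parameters
#'
#' Two independent quadratic least-squares fits of the per-quality Gamma
#' shape and rate against lineal energy (or log10 of it). Positivity of
#' both trends is verified on the validity range; violations are reported
#' as a warning by the [gamma_complexity_params()] constructor.
#'
#' @param per_quality Data frame with columns `yF`, `a`, `b`: one fitted
#'   Gamma parameter pair per radiation quality; >= 3 distinct `yF`.
#' @param abscissa `"yF"` (default) or `"log10yF"`.
#' @param valid_range_keV_um Validity range recorded in the result.
#' @param weights Optional least-squares weights: a numeric vector applied
#'   to both fits, or `"relative"` for inverse squared-value weights per
#'   curve; unweighted by default.
#' @return A [gamma_complexity_params()] object; the two `mgm_fit`s are
#'   attached as attribute `fits`.
#' @export
fit_gamma_trend <- function(per_quality, abscissa = c("yF", "log10yF"),
                            valid_range_keV_um = c(2, 200), weights = NULL) {
  abscissa <- match.arg(abscissa)
  stopifnot(all(c("yF", "a", "b") %in% names(per_quality)))
  if (length(unique(per_quality$yF)) < 3L)
    stop("need at least 3 distinct yF values", call. = FALSE)
  x <- if (abscissa == "log10yF") log10(per_quality$yF) else per_quality$yF
  quad <- function(y) {
    w <- if (identical(weights, "relative")) 1 / y^2 else
      weights %||% rep(1, length(x))
    dat <- data.frame(x = x, y = y, w = w)
    fit <- lm(y ~ x + I(x^2), data = dat, weights = w)
    mgm_fit(
      parameters = setNames(unname(coef(fit)), c("p0", "p1", "p2")),
      covariance = suppressWarnings(vcov(fit)),
      r_squared = r_squared_of(y, stats::fitted(fit)),
      residuals = as.numeric(stats::residuals(fit)),
      method = "quadratic least squares"
    )
  }
  fit_a <- quad(per_quality$a)
  fit_b <- quad(per_quality$b)
  out <- gamma_complexity_params(
    poly_a = fit_a$parameters, poly_b = fit_b$parameters,
    abscissa = abscissa, valid_range_keV_um = valid_range_keV_um
  )
  attr(out, "fits") <- list(a = fit_a, b = fit_b)
  out
}

#' Calibrate all MGM functions from per-quality yields
#'
#' Runs the full calibration: linear fits for direct SB/BD yields,
#' saturation fits for indirect SB/BD yields, the linear-quadratic fit for
#' DSB-containing sites, and the quadratic Gamma-parameter trends. The
#' input is one row per radiation quality (the per-track mean yields at
#' each yF), as produced by [make_quality_yields()] or assembled from
#' [summarize_tracks()] / [fit_gamma()] output.
#'
#' Weighting: `"none"` (ordinary least squares, the default) or
#' `"relative"` (inverse squared-value weights, the inverse-variance choice
#' when measurement errors scale with the measured yield, as they do for
#' bootstrapped yields with roughly constant relative uncertainty).
#'
#' @param quality_yields Data frame with columns `yF`, `sb_direct`,
#'   `sb_indirect`, `bd_direct`, `bd_indirect`, `ds_dsb`, `gamma_a`,
#'   `gamma_b`.
#' @param abscissa Abscissa mode for the Gamma trends.
#' @param weighting `"none"` or `"relative"` (see Details).
#' @param provenance Metadata list stored in the result.
#' @return An [mgm_parameters()] object; individual `mgm_fit`s are attached
#'   as attribute `fits`.
#' @export
calibrate_mgm <- function(quality_yields, abscissa = c("yF", "log10yF"),
                          weighting = c("none", "relative"),
                          provenance = list()) {
  abscissa <- match.arg(abscissa)
  weighting <- match.arg(weighting)
  req <- c("yF", "sb_direct", "sb_indirect", "bd_direct", "bd_indirect",
           "ds_dsb", "gamma_a", "gamma_b")
  missing_cols <- setdiff(req, names(quality_yields))
  if (length(missing_cols))
    stop("quality_yields is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  q <- quality_yields
  w_of <- function(v) if (weighting == "relative") 1 / v^2 else NULL
  fits <- list(
    sb_direct = fit_linear(q$yF, q$sb_direct, weights = w_of(q$sb_direct)),
    sb_indirect = fit_saturation(q$yF, q$sb_indirect,
                                 weights = w_of(q$sb_indirect)),
    bd_direct = fit_linear(q$yF, q$bd_direct, weights = w_of(q$bd_direct)),
    bd_indirect = fit_saturation(q$yF, q$bd_indirect,
                                 weights = w_of(q$bd_indirect)),
    ds_dsb = fit_linear_quadratic(q$yF, q$ds_dsb, weights = w_of(q$ds_dsb))
  )
  gamma <- fit_gamma_trend(
    data.frame(yF = q$yF, a = q$gamma_a, b = q$gamma_b),
    abscissa = abscissa,
    valid_range_keV_um = range(pretty_range(q$yF)),
    weights = if (weighting == "relative") "relative" else NULL
  )
  out <- mgm_parameters(
    sb = list(k_direct = fits$sb_direct$parameters[["k_direct"]],
              N_max = fits$sb_indirect$parameters[["N_max"]],
              a_sat = fits$sb_indirect$parameters[["a_sat"]]),
    bd = list(k_direct = fits$bd_direct$parameters[["k_direct"]],
              N_max = fits$bd_indirect$parameters[["N_max"]],
              a_sat = fits$bd_indirect$parameters[["a_sat"]]),
    ds_dsb = list(c1 = fits$ds_dsb$parameters[["c1"]],
                  c2 = fits$ds_dsb$parameters[["c2"]]),
    gamma = gamma,
    provenance = provenance
  )
  attr(out, "fits") <- c(fits, list(gamma_trend = attr(gamma, "fits")))
  out
}

# Calibration data rarely span exactly [2, 200]; keep the canonical range
# when the data lie inside it, otherwise widen to cover the data.
pretty_range <- function(yF) {
  c(min(2, floor(min(yF))), max(200, ceiling(max(yF))))
}
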