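#' Per-track direct damage yield
#'
#' Direct damage induced by a single track is proportional to the energy the
#' track deposits, hence linear in the frequency-mean lineal energy.
#'
#' @param yF Lineal energy, keV/um, > 0 (a warning is issued outside the
#'   2-200 keV/um validity range).
#' @param k_direct Slope, lesions per track per (keV/um).
#' @param valid_range Validity range in keV/um used for the warning.
#' @return Expected direct lesions per track, `k_direct * yF`.
#' @export
n_direct <- function(yF, k_direct, valid_range = c(2, 200)) {
  if (any(yF <= 0)) stop("yF must be > 0", call. = FALSE)
  check_validity_range(yF, valid_range)
  k_direct * yF
}

#' Per-track indirect damage yield (ROS saturation law)
#'
#' Indirect (radical-mediated) damage saturates as ionization density grows,
#' because neighbouring hydroxyl radicals recombine before reaching the DNA:
#' `N_I(yF) = N_max * (1 - exp(-a_sat * yF))`. Monotone increasing and
#' bounded by `N_max`.
#'
#' @inheritParams n_direct
#' @param N_max Saturation level, lesions per track.
#' @param a_sat Saturation rate, (keV/um)^-1.
#' @return Expected indirect lesions per track.
#' @export
n_indirect <- function(yF, N_max, a_sat, valid_range = c(2, 200)) {
  if (any(yF <= 0)) stop("yF must be > 0", call. = FALSE)
  check_validity_range(yF, valid_range)
  N_max * (1 - exp(-a_sat * yF))
}

#' Per-track yield of DSB-containing damage sites
#'
#' The number of damage sites holding at least one double-strand break per
#' track follows a linear-quadratic dependence on yF (ionization positions
#' along a track are strongly correlated): `c1*yF + c2*yF^2`, forced
#' through the origin.
#'
#' @inheritParams n_direct
#' @param c1 Linear coefficient, sites per track per (keV/um).
#' @param c2 Quadratic coefficient, sites per track per (keV/um)^2.
#' @return Expected DSB-containing sites per track.
#' @export
n_ds_with_dsb <- function(yF, c1, c2, valid_range = c(2, 200)) {
  if (any(yF <= 0)) stop("yF must be > 0", call. = FALSE)
  check_validity_range(yF, valid_range)
  c1 * yF + c2 * yF^2
}

#' Gamma complexity-law parameters as polynomial trends in yF
#'
#' The complexity of DSB-containing damage sites at a given radiation
#' quality follows a Gamma distribution whose shape `a(yF)` and rate `b(yF)`
#' vary smoothly with lineal energy; both trends are modelled as
#' second-order polynomials, either in yF directly or in log10(yF)
#' (the abscissa mode is recorded so serialized parameters are unambiguous).
#'
#' @param poly_a,poly_b Ascending polynomial coefficients `c(p0, p1, p2)`
#'   for the shape and rate trends.
#' @param abscissa `"yF"` (default) or `"log10yF"`: the variable the
#'   polynomials are evaluated in.
#' @param valid_range_keV_um Validity range of the trends, keV/um.
#' @return An object of class `gamma_complexity_params`.
#' @export
gamma_complexity_params <- function(poly_a, poly_b, abscissa = c("yF", "log10yF"),
                                    valid_range_keV_um = c(2, 200)) {
  abscissa <- match.arg(abscissa)
  stopifnot(length(poly_a) == 3L, length(poly_b) == 3L,
            length(valid_range_keV_um) == 2L,
            valid_range_keV_um[1] > 0,
            valid_range_keV_um[1] < valid_range_keV_um[2])
  obj <- structure(
    list(poly_a = as.numeric(poly_a), poly_b = as.numeric(poly_b),
         abscissa = abscissa,
         valid_range_keV_um = as.numeric(valid_range_keV_um)),
    class = "gamma_complexity_params"
  )
  grid <- seq(valid_range_keV_um[1], valid_range_keV_um[2], length.out = 101)
  ab <- gamma_params_at(grid, obj, check_positive = FALSE)
  if (any(ab$a <= 0) || any(ab$b <= 0))
    warning("a(yF) or b(yF) is non-positive somewhere on the validity range",
            call. = FALSE)
  obj
}

#' Evaluate the Gamma parameters at a lineal energy
#'
#' @param yF Lineal energy, keV/um.
#' @param gamma A [gamma_complexity_params()].
#' @param check_positive Error when an evaluated parameter is non-positive
#'   (default); internal callers may disable this.
#' @return A list with vectors `a` (shape) and `b` (rate).
#' @export
gamma_params_at <- function(yF, gamma, check_positive = TRUE) {
  stopifnot(inherits(gamma, "gamma_complexity_params"))
  x <- if (gamma$abscissa == "log10yF") log10(yF) else yF
  a <- polyval_asc(gamma$poly_a, x)
  b <- polyval_asc(gamma$poly_b, x)
  if (check_positive && (any(a <= 0) || any(b <= 0))) {
    bad <- yF[which(a <= 0 | b <= 0)[1]]
    stop(sprintf("Gamma parameters non-positive at yF = %g keV/um", bad),
         call. = FALSE)
  }
  list(a = a, b = b)
}

#' Gamma probability density of damage complexity
#'
#' Density of the complexity law `f(C; yF)` with shape `a(yF)` and rate
#' `b(yF)` taken from the polynomial trends. Complexity is the total lesion
#' count of a DSB-containing site, so the support of interest starts at 2,
#' but the fitted law is a continuous Gamma on C > 0.
#'
#' @param C Complexity values, > 0.
#' @param yF Lineal energy, keV/um (scalar).
#' @param gamma A [gamma_complexity_params()].
#' @return Density values.
#' @export
complexity_pdf <- function(C, yF, gamma) {
  if (any(C <= 0)) stop("complexity must be > 0", call. = FALSE)
  p <- gamma_params_at(yF, gamma)
  dgamma(C, shape = p$a, rate = p$b)
}

#' Sample damage-site complexities
#'
#' Draws iid complexities from the Gamma law at the given lineal energy.
#' With `discretize = TRUE` (default) draws are rounded to the nearest
#' integer and clamped to a minimum of 2, matching the definition of
#' complexity as an integer lesion count with a simple DSB scoring 2.
#'
#' @param n Number of draws, >= 0.
#' @param yF Lineal energy, keV/um (scalar).
#' @param gamma A [gamma_complexity_params()].
#' @param seed Optional integer seed for reproducibility.
#' @param discretize Round and clamp to integers >= 2 (default `TRUE`).
#' @return Numeric (or integer-valued) vector of length `n`.
#' @export
sample_complexities <- function(n, yF, gamma, seed = NULL, discretize = TRUE) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- gamma_params_at(yF, gamma)
  x <- rgamma(n, shape = p$a, rate = p$b)
  if (discretize) x <- pmax(2, round(x))
  x
}

#' MGM parameter container
#'
#' Bundles every calibrated coefficient of the model: the per-track yield
#' laws for strand breaks (SB), base damages (BD) and DSB-containing damage
#' sites, plus the Gamma complexity trends. No default calibration ships
#' with the package: parameters come from [calibrate_mgm()] on damage
#' summaries or from [mgm_ground_truth()] for synthetic studies.
#'
#' @param sb,bd Lists with `k_direct`, `N_max`, `a_sat` for the strand-break
#'   and base-damage yield laws.
#' @param ds_dsb List with `c1`, `c2` for the DSB-containing-site law.
#' @param gamma A [gamma_complexity_params()].
#' @param provenance Free-form named list of metadata (simulator, damage
#'   criteria, ...), serialized verbatim.
#' @return An object of class `mgm_parameters`.
#' @export
mgm_parameters <- function(sb, bd, ds_dsb, gamma, provenance = list()) {
  check_yield <- function(p, what, fields) {
    missing_f <- setdiff(fields, names(p))
    if (length(missing_f))
      stop(what, " parameters missing: ", paste(missing_f, collapse = ", "),
           call. = FALSE)
    if (any(unlist(p[fields]) < 0))
      stop(what, " parameters must be non-negative", call. = FALSE)
    lapply(p[fields], as.numeric)
  }
  structure(
    list(
      sb = check_yield(sb, "sb", c("k_direct", "N_max", "a_sat")),
      bd = check_yield(bd, "bd", c("k_direct", "N_max", "a_sat")),
      ds_dsb = check_yield(ds_dsb, "ds_dsb", c("c1", "c2")),
      gamma = gamma,
      provenance = provenance
    ),
    class = "mgm_parameters"
  )
}

#' @export
print.mgm_parameters <- function(x, ...) {
  cat("MGM parameters (units: yF in keV/um, yields per track)\n")
  cat(sprintf("  SB:     k_direct = %.4g, N_max = %.4g, a_sat = %.4g\n",
              x$sb$k_direct, x$sb$N_max, x$sb$a_sat))
  cat(sprintf("  BD:     k_direct = %.4g, N_max = %.4g, a_sat = %.4g\n",
              x$bd$k_direct, x$bd$N_max, x$bd$a_sat))
  cat(sprintf("  DS+DSB: c1 = %.4g, c2 = %.4g\n", x$ds_dsb$c1, x$ds_dsb$c2))
  cat(sprintf("  Gamma:  a(%s) = %s;  b(%s) = %s\n",
              x$gamma$abscissa, paste(signif(x$gamma$poly_a, 4), collapse = ", "),
              x$gamma$abscissa, paste(signif(x$gamma$poly_b, 4), collapse = ", ")))
  invisible(x)
}

#' Read and write MGM parameters as YAML
#'
#' The serialization is lossless and records units and the polynomial
#' abscissa mode explicitly.
#'
#' @param params An [mgm_parameters()] object.
#' @param path File path (`.yaml`).
#' @return `write_mgm_parameters` returns `path` invisibly;
#'   `read_mgm_parameters` returns the deserialized [mgm_parameters()].
#' @export
write_mgm_parameters <- function(params, path) {
  stopifnot(inherits(params, "mgm_parameters"))
  yaml::write_yaml(list(
    units = list(yF = "keV/um", yields = "per track"),
    yields = list(sb = params$sb, bd = params$bd, ds_dsb = params$ds_dsb),
    gamma = list(
      poly_a = params$gamma$poly_a,
      poly_b = params$gamma$poly_b,
      abscissa = params$gamma$abscissa,
      valid_range_keV_um = params$gamma$valid_range_keV_um
    ),
    provenance = params$provenance
  ), path)
  invisible(path)
}

#' @rdname write_mgm_parameters
#' @export
read_mgm_parameters <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$yields) || is.null(y$gamma))
    stop("not an MGM parameter file: ", path, call. = FALSE)
  mgm_parameters(
    sb = y$yields$sb, bd = y$yields$bd, ds_dsb = y$yields$ds_dsb,
    gamma = gamma_complexity_params(
      poly_a = unlist(y$gamma$poly_a),
      poly_b = unlist(y$gamma$poly_b),
      abscissa = y$gamma$abscissa %||% "yF",
      valid_range_keV_um = unlist(y$gamma$valid_range_keV_um) %||% c(2, 200)
    ),
    provenance = y$provenance %||% list()
  )
}
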