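#' Mean chord length of a sphere
#'
#' Cauchy's formula for a convex body gives 4V/S; for a sphere this is
#' two-thirds of the diameter, the normalizing length used to define lineal
#' energy.
#'
#' @param diameter_um Sphere diameter in micrometres, > 0.
#' @return Mean chord length in micrometres.
#' @examples
#' mean_chord_length(1)     # 2/3 um
#' mean_chord_length(9.65)  # 6.4333 um, the default nucleus
#' @export
mean_chord_length <- function(diameter_um) {
  if (any(diameter_um <= 0)) stop("diameter must be > 0", call. = FALSE)
  (2 / 3) * diameter_um
}

#' Spherical microdosimetric site
#'
#' Geometry container for yF/zF conversions: a liquid-water sphere with its
#' derived mean chord length and mass.
#'
#' @param diameter_um Site diameter in micrometres, > 0.
#' @param density_kg_m3 Material density; 1000 kg/m3 (liquid water) by
#'   default.
#' @return An object of class `microdosimetric_site` with fields
#'   `diameter_um`, `density_kg_m3`, `mean_chord_um` and `mass_kg`.
#' @export
microdosimetric_site <- function(diameter_um = 1, density_kg_m3 = 1000) {
  if (diameter_um <= 0) stop("diameter must be > 0", call. = FALSE)
  if (density_kg_m3 <= 0) stop("density must be > 0", call. = FALSE)
  structure(
    list(
      diameter_um = diameter_um,
      density_kg_m3 = density_kg_m3,
      mean_chord_um = mean_chord_length(diameter_um),
      mass_kg = density_kg_m3 * (pi / 6) * (diameter_um * 1e-6)^3
    ),
    class = "microdosimetric_site"
  )
}

#' @export
print.microdosimetric_site <- function(x, ...) {
  cat(sprintf(
    "microdosimetric site: d = %g um, mean chord = %g um, mass = %.4g kg\n",
    x$diameter_um, x$mean_chord_um, x$mass_kg))
  invisible(x)
}

#' Convert between frequency-mean lineal and specific energy
#'
#' For a spherical site, the single-event frequency means of lineal energy
#' (`yF`, keV/um) and specific energy (`zF`, Gy) are proportional:
#' `zF = yF * mean_chord * k / mass`, with `k` the keV-to-joule factor.
#' The two functions are exact inverses.
#'
#' @param yF_keV_um Frequency-mean lineal energy, keV/um, > 0.
#' @param zF_Gy Frequency-mean specific energy, Gy, > 0.
#' @param site A [microdosimetric_site()].
#' @return `yF_to_zF` returns zF in Gy; `zF_to_yF` returns yF in keV/um.
#' @examples
#' yF_to_zF(1, microdosimetric_site(1))  # ~0.204 Gy
#' @export
yF_to_zF <- function(yF_keV_um, site = microdosimetric_site()) {
  if (any(yF_keV_um <= 0)) stop("yF must be > 0", call. = FALSE)
  yF_keV_um * site$mean_chord_um * .kev_to_joule / site$mass_kg
}

#' @rdname yF_to_zF
#' @export
zF_to_yF <- function(zF_Gy, site = microdosimetric_site()) {
  if (any(zF_Gy <= 0)) stop("zF must be > 0", call. = FALSE)
  zF_Gy * site$mass_kg / (site$mean_chord_um * .kev_to_joule)
}

#' Beam spectrum as weighted yF components
#'
#' A mixed beam is described as a weighted list of spectral components, each
#' characterized by its own frequency-mean lineal energy under the
#' track-segment (short-track) condition. Weights are normalized to sum to
#' one and are interpreted downstream as dose fractions.
#'
#' @param yF Component lineal energies, keV/um, all > 0.
#' @param weights Non-negative component weights (default: equal).
#' @return An object of class `beam_spectrum`: a data frame with columns
#'   `weight` and `yF`.
#' @export
beam_spectrum <- function(yF, weights = rep(1, length(yF))) {
  if (length(yF) < 1L) stop("a beam needs at least one component", call. = FALSE)
  if (length(weights) != length(yF))
    stop("weights and yF must have equal length", call. = FALSE)
  if (any(yF <= 0)) stop("all component yF must be > 0", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (sum(weights) == 0) stop("weights must not all be zero", call. = FALSE)
  structure(
    data.frame(weight = weights / sum(weights), yF = yF),
    class = c("beam_spectrum", "data.frame")
  )
}

#' Moments of a beam spectrum
#'
#' Weighted first and second moments of the component lineal energies and
#' the derived dose-mean lineal energy `yD = <yF^2> / <yF>`. By
#' Cauchy-Schwarz `yD >= <yF>`, with equality only for a single-component
#' beam.
#'
#' @param spectrum A [beam_spectrum()].
#' @return A list with `yF_mean`, `yF2_mean`, and `yD` (all keV/um; the
#'   second moment in (keV/um)^2).
#' @export
beam_averages <- function(spectrum) {
  stopifnot(inherits(spectrum, "beam_spectrum"))
  m1 <- sum(spectrum$weight * spectrum$yF)
  m2 <- sum(spectrum$weight * spectrum$yF^2)
  list(yF_mean = m1, yF2_mean = m2, yD = m2 / m1)
}

#' Read a beam spectrum from CSV or YAML
#'
#' CSV files must have columns `weight` and `yF`; YAML files either a
#' top-level `components` list of `{weight, yF}` mappings or parallel
#' `weight`/`yF` sequences.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` vs
#'   anything else treated as CSV).
#' @return A [beam_spectrum()].
#' @export
read_beam_spectrum <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$components)) {
      w <- vapply(y$components, function(c) as.numeric(c$weight %||% 1), numeric(1))
      v <- vapply(y$components, function(c) as.numeric(c$yF), numeric(1))
    } else {
      w <- as.numeric(y$weight)
      v <- as.numeric(y$yF)
    }
    return(beam_spectrum(v, w))
  }
  df <- read.csv(path)
  if (!all(c("weight", "yF") %in% names(df)))
    stop("beam CSV must have columns 'weight' and 'yF'", call. = FALSE)
  beam_spectrum(df$yF, df$weight)
}
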