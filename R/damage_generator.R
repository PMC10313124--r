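#' Spherical nucleus geometry
#'
#' The generator's target volume: a liquid-water sphere representing the
#' cell nucleus, 9.65 um in diameter by default.
#'
#' @param diameter_um Nucleus diameter, micrometres, > 0.
#' @param density_kg_m3 Density, kg/m3 (default liquid water).
#' @return An object of class `nucleus_geometry` (a
#'   [microdosimetric_site()] with an extra class).
#' @export
nucleus_geometry <- function(diameter_um = 9.65, density_kg_m3 = 1000) {
  site <- microdosimetric_site(diameter_um, density_kg_m3)
  class(site) <- c("nucleus_geometry", class(site))
  site
}

#' Sample track chords through the nucleus
#'
#' Tracks traverse the nucleus uniformly across its projection: the entry
#' point is uniform on the projected disk, giving a chord of length
#' `2*sqrt(R^2 - r^2)` at impact radius `r` ("mu-randomness", whose mean is
#' Cauchy's `2d/3`). In `"parallel"` mode (default) all tracks run along
#' +z; `"isotropic"` mode applies an independent uniform random rotation to
#' each chord, for internal-emitter geometries.
#'
#' @param n Number of chords.
#' @param nucleus A [nucleus_geometry()].
#' @param mode `"parallel"` or `"isotropic"`.
#' @param seed Optional integer seed.
#' @return A data frame with entry point (`x0_um`, `y0_um`, `z0_um`),
#'   direction cosines (`dx`, `dy`, `dz`) and `length_um`.
#' @export
sample_chord <- function(n, nucleus = nucleus_geometry(),
                         mode = c("parallel", "isotropic"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  R <- nucleus$diameter_um / 2
  r <- R * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  half <- sqrt(pmax(0, R^2 - r^2))
  ch <- data.frame(
    x0_um = r * cos(phi), y0_um = r * sin(phi), z0_um = -half,
    dx = 0, dy = 0, dz = 1, length_um = 2 * half
  )
  if (mode == "isotropic" && n > 0) {
    # rotate each chord by an independent uniform rotation of the sphere
    u <- runif(n, -1, 1); th <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    axis_dx <- s * cos(th); axis_dy <- s * sin(th); axis_dz <- u
    # new frame: chord direction = sampled axis; entry rotated consistently
    # by mapping (0,0,1) -> axis via the rotation about their cross product
    for (i in seq_len(n)) {
      Rm <- rotation_from_z(c(axis_dx[i], axis_dy[i], axis_dz[i]))
      p <- Rm %*% c(ch$x0_um[i], ch$y0_um[i], ch$z0_um[i])
      d <- Rm %*% c(0, 0, 1)
      ch$x0_um[i] <- p[1]; ch$y0_um[i] <- p[2]; ch$z0_um[i] <- p[3]
      ch$dx[i] <- d[1]; ch$dy[i] <- d[2]; ch$dz[i] <- d[3]
    }
  }
  ch
}

# Rotation matrix taking the +z axis onto unit vector v.
rotation_from_z <- function(v) {
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- c(z[2] * v[3] - z[3] * v[2], z[3] * v[1] - z[1] * v[3],
          z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Expected number of tracks for a dose
#'
#' Under the short-track condition a track deposits `yF * chord_length` keV
#' in the nucleus, so the single-event frequency-mean specific energy of
#' the nucleus is `zF = yF * mean_chord * k / mass` and the expected track
#' count at dose `D` is `D / zF`.
#'
#' @param dose_Gy Absorbed dose, Gy, > 0.
#' @param yF Lineal energy of the radiation, keV/um, > 0.
#' @param nucleus A [nucleus_geometry()].
#' @return Expected (real-valued) number of tracks.
#' @examples
#' expected_tracks(6, 115.3)  # ~23.8 alpha tracks for 6 Gy
#' @export
expected_tracks <- function(dose_Gy, yF, nucleus = nucleus_geometry()) {
  if (any(dose_Gy <= 0) || any(yF <= 0))
    stop("dose and yF must be > 0", call. = FALSE)
  dose_Gy / yF_to_zF(yF, nucleus)
}

#' Generate an explicit damage realization for a dose
#'
#' The generative use of the model: for each spectral component (weights
#' interpreted as dose fractions), the number of tracks is Poisson with
#' mean [expected_tracks()] at the component's dose share; each track gets
#' a chord through the nucleus; the number of DSB-containing sites on a
#' track is Poisson with mean [n_ds_with_dsb()] at the component's yF;
#' sites are placed uniformly along the chord ("damage in straight lines");
#' and each site's complexity is drawn from the Gamma law at that yF.
#' Fully reproducible given `seed`.
#'
#' @param dose_Gy Absorbed dose, Gy, >= 0.
#' @param beam A [beam_spectrum()].
#' @param params An [mgm_parameters()].
#' @param nucleus A [nucleus_geometry()].
#' @param seed Optional integer seed.
#' @param mode Chord geometry, `"parallel"` or `"isotropic"`.
#' @param discretize Discretize complexities (integer >= 2, default TRUE).
#' @return An object of class `damage_realization`: a list with `dose_Gy`,
#'   `seed`, `tracks` (component, yF, chord geometry) and `sites` (track
#'   index, position, complexity).
#' @export
generate_damage <- function(dose_Gy, beam, params,
                            nucleus = nucleus_geometry(), seed = NULL,
                            mode = c("parallel", "isotropic"),
                            discretize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(beam, "beam_spectrum"), inherits(params, "mgm_parameters"))
  if (dose_Gy < 0) stop("dose must be >= 0", call. = FALSE)
  check_validity_range(beam$yF, params$gamma$valid_range_keV_um)
  if (!is.null(seed)) set.seed(seed)

  tracks <- list(); sites <- list()
  track_offset <- 0L
  for (ci in seq_len(nrow(beam))) {
    w <- beam$weight[ci]; yF <- beam$yF[ci]
    dose_c <- w * dose_Gy
    n_tracks <- if (dose_c > 0) rpois(1, expected_tracks(dose_c, yF, nucleus)) else 0L
    if (n_tracks == 0L) next
    ch <- sample_chord(n_tracks, nucleus, mode = mode)
    ch <- cbind(track = track_offset + seq_len(n_tracks),
                component = ci, yF = yF, ch)
    tracks[[ci]] <- ch

    lambda_s <- suppressWarnings(
      n_ds_with_dsb(yF, params$ds_dsb$c1, params$ds_dsb$c2))
    n_sites <- rpois(n_tracks, lambda_s)
    total <- sum(n_sites)
    if (total > 0L) {
      tr <- rep(seq_len(n_tracks), n_sites)
      u <- runif(total)
      cx <- sample_complexities(total, yF, params$gamma, discretize = discretize)
      sites[[ci]] <- data.frame(
        track = track_offset + tr,
        component = ci,
        x_um = ch$x0_um[tr] + u * ch$length_um[tr] * ch$dx[tr],
        y_um = ch$y0_um[tr] + u * ch$length_um[tr] * ch$dy[tr],
        z_um = ch$z0_um[tr] + u * ch$length_um[tr] * ch$dz[tr],
        complexity = cx
      )
    }
    track_offset <- track_offset + n_tracks
  }
  structure(
    list(
      dose_Gy = dose_Gy,
      seed = seed,
      nucleus = nucleus,
      tracks = if (length(tracks)) do.call(rbind, tracks) else
        data.frame(track = integer(0), component = integer(0), yF = numeric(0),
                   x0_um = numeric(0), y0_um = numeric(0), z0_um = numeric(0),
                   dx = numeric(0), dy = numeric(0), dz = numeric(0),
                   length_um = numeric(0)),
      sites = if (length(sites)) do.call(rbind, sites) else
        data.frame(track = integer(0), component = integer(0),
                   x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                   complexity = numeric(0))
    ),
    class = "damage_realization"
  )
}

#' @export
print.damage_realization <- function(x, ...) {
  cat(sprintf(
    "damage realization: %.3g Gy, %d tracks, %d DSB-containing sites\n",
    x$dose_Gy, nrow(x$tracks), nrow(x$sites)))
  invisible(x)
}

#' Convert a damage realization to SDD records
#'
#' Each generated site becomes one damage-site record. The integer
#' complexity `C` is decomposed into a minimal lesion pattern: one strand
#' break per strand (the DSB itself) plus `C - 2` surplus lesions split
#' between strand breaks and base damages according to `sb_fraction`
#' (default an even split, surplus strand breaks alternating between
#' strands). Scoring the records with [complexity_score()] returns `C`
#' exactly. Genomic coordinates are synthetic placeholders (all sites on
#' chromosome 1, spaced ten windows apart) since the generator is spatial,
#' not genomic.
#'
#' @param realization A [generate_damage()] result with discretized
#'   complexities.
#' @param header An [sdd_header()] stub for the eventual file; dose is
#'   filled in from the realization if missing.
#' @param sb_fraction Fraction of surplus lesions assigned to strand
#'   breaks.
#' @param window_bp Site window length, base pairs.
#' @return A list with `header` and `records` ready for [write_sdd()].
#' @export
realization_to_sdd <- function(realization, header = sdd_header(),
                               sb_fraction = 0.5, window_bp = 10L) {
  stopifnot(inherits(realization, "damage_realization"))
  s <- realization$sites
  if (any(s$complexity != round(s$complexity) | s$complexity < 2))
    stop("realization complexities must be discretized (integers >= 2)",
         call. = FALSE)
  if (is.na(header$dose_or_fluence)) header$dose_or_fluence <- realization$dose_Gy
  if (nrow(s) == 0L)
    return(list(header = header, records = empty_damage_sites()))

  extra <- as.integer(s$complexity) - 2L
  extra_sb <- as.integer(round(extra * sb_fraction))
  extra_bd <- extra - extra_sb
  sb1 <- 1L + (extra_sb + 1L) %/% 2L
  sb2 <- 1L + extra_sb %/% 2L
  records <- damage_sites(
    track_id = s$track,
    chromosome_id = 1L,
    genomic_position_bp = (seq_len(nrow(s)) - 1L) * 10L * window_bp,
    x_um = s$x_um, y_um = s$y_um, z_um = s$z_um,
    n_sb_strand1 = sb1, n_sb_strand2 = sb2, n_bd = extra_bd,
    has_dsb = TRUE
  )
  list(header = header, records = records)
}
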