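#' Synthetic MGM ground truth
#'
#' A fully specified parameter set plus study design used to generate
#' synthetic calibration data, so that every fitting routine can be
#' validated by parameter recovery without external data. The default
#' design emulates a campaign of 15 monoenergetic radiation qualities
#' log-spaced over the 2-200 keV/um validity range. The default
#' coefficients are synthetic: order-of-magnitude plausible for per-track
#' damage yields in a mammalian nucleus, but not any published calibration.
#'
#' @param mgm An [mgm_parameters()] object used as truth (default: the
#'   synthetic set below).
#' @param yF_grid Radiation qualities, keV/um.
#' @param tracks_per_quality Tracks simulated per quality by
#'   [make_track_summaries()].
#' @param noise_sigma Multiplicative lognormal noise (sdlog) applied by
#'   [make_quality_yields()]; 0 gives exact model values.
#' @param seed Integer seed stored with the truth and used by all
#'   generators.
#' @return An object of class `mgm_ground_truth`.
#' @export
mgm_ground_truth <- function(mgm = default_truth_params(),
                             yF_grid = exp(seq(log(2), log(200),
                                               length.out = 15)),
                             tracks_per_quality = 200L,
                             noise_sigma = 0,
                             seed = 1L) {
  stopifnot(inherits(mgm, "mgm_parameters"), all(yF_grid > 0),
            tracks_per_quality >= 1, noise_sigma >= 0)
  structure(
    list(mgm = mgm, yF_grid = yF_grid,
         tracks_per_quality = as.integer(tracks_per_quality),
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "mgm_ground_truth"
  )
}

#' @rdname mgm_ground_truth
#' @export
default_truth_params <- function() {
  mgm_parameters(
    sb = list(k_direct = 0.9, N_max = 120, a_sat = 0.02),
    bd = list(k_direct = 1.1, N_max = 180, a_sat = 0.015),
    ds_dsb = list(c1 = 0.08, c2 = 0.003),
    gamma = gamma_complexity_params(
      poly_a = c(2.2, 0.025, -4e-5),
      poly_b = c(0.9, -0.0035, 8e-6)
    ),
    provenance = list(origin = "synthetic ground truth for validation")
  )
}

truth_yields_at <- function(truth, yF) {
  m <- truth$mgm
  gp <- gamma_params_at(yF, m$gamma)
  suppressWarnings(data.frame(
    yF = yF,
    sb_direct = n_direct(yF, m$sb$k_direct),
    sb_indirect = n_indirect(yF, m$sb$N_max, m$sb$a_sat),
    bd_direct = n_direct(yF, m$bd$k_direct),
    bd_indirect = n_indirect(yF, m$bd$N_max, m$bd$a_sat),
    ds_dsb = n_ds_with_dsb(yF, m$ds_dsb$c1, m$ds_dsb$c2),
    gamma_a = gp$a,
    gamma_b = gp$b
  ))
}

#' Per-quality mean yields with multiplicative noise
#'
#' Evaluates every truth function on the quality grid and perturbs each
#' value with iid multiplicative lognormal noise of sdlog
#' `truth$noise_sigma` (none when the sigma is 0, so the noiseless table
#' reproduces the truth functions exactly). This is the calibration input
#' consumed by [calibrate_mgm()].
#'
#' @param truth An [mgm_ground_truth()].
#' @return A data frame with one row per quality and the columns
#'   [calibrate_mgm()] expects.
#' @export
make_quality_yields <- function(truth) {
  stopifnot(inherits(truth, "mgm_ground_truth"))
  set.seed(truth$seed)
  q <- truth_yields_at(truth, truth$yF_grid)
  if (truth$noise_sigma > 0) {
    for (col in setdiff(names(q), "yF")) {
      q[[col]] <- q[[col]] * rlnorm(nrow(q), meanlog = 0,
                                    sdlog = truth$noise_sigma)
    }
  }
  q
}

#' Per-track damage summaries drawn from the truth
#'
#' Simulates the per-track observables of a damage campaign: for each
#' quality and track, direct and indirect strand-break and base-damage
#' counts are Poisson with the truth means, the DSB-containing site count
#' is Poisson with the linear-quadratic mean, and that many complexities
#' are drawn from the truth Gamma law (discretized, so every score is
#' >= 2). `n_ds_total` adds a Poisson number of DSB-free sites so that the
#' DSB-containing count never exceeds the total. Deterministic given
#' `truth$seed`.
#'
#' @param truth An [mgm_ground_truth()].
#' @return A data frame of class `track_summaries` with an extra `yF`
#'   column, `truth$tracks_per_quality` rows per quality.
#' @export
make_track_summaries <- function(truth) {
  stopifnot(inherits(truth, "mgm_ground_truth"))
  set.seed(truth$seed)
  n <- truth$tracks_per_quality
  per_quality <- lapply(truth$yF_grid, function(yF) {
    tm <- truth_yields_at(truth, yF)
    n_dsb <- rpois(n, tm$ds_dsb)
    # DSB-free sites: sites holding only SSBs or base damages
    n_free <- rpois(n, 0.5 * tm$ds_dsb + 0.5)
    cx <- sample_complexities(sum(n_dsb), yF, truth$mgm$gamma)
    idx <- rep.int(seq_len(n), n_dsb)
    out <- data.frame(
      yF = yF,
      track_id = seq_len(n),
      n_sb_direct = rpois(n, tm$sb_direct),
      n_sb_indirect = rpois(n, tm$sb_indirect),
      n_bd_direct = rpois(n, tm$bd_direct),
      n_bd_indirect = rpois(n, tm$bd_indirect),
      n_ds_with_dsb = n_dsb,
      n_ds_total = n_dsb + n_free
    )
    out$n_sb <- out$n_sb_direct + out$n_sb_indirect
    out$n_bd <- out$n_bd_direct + out$n_bd_indirect
    out$complexities <- unname(split(cx, factor(idx, levels = seq_len(n))))
    out
  })
  out <- do.call(rbind, per_quality)
  class(out) <- c("track_summaries", "data.frame")
  out
}

#' Write a synthetic SDD fixture drawn from the truth
#'
#' Generates explicit damage-site records for `n_tracks` tracks of one
#' radiation quality and writes them as an SDD file: per track a Poisson
#' number of DSB-containing sites with Gamma complexities (decomposed into
#' lesions as in [realization_to_sdd()]), plus DSB-free single-lesion
#' sites; lesions are attributed to the direct cause with the truth's
#' direct fraction at that quality. Site positions are placed along a
#' straight chord through the nucleus. The file is labelled as synthetic in
#' its header.
#'
#' @param truth An [mgm_ground_truth()].
#' @param quality_index Index into `truth$yF_grid`.
#' @param n_tracks Number of tracks to emit.
#' @param path Output SDD path.
#' @return Invisibly, the list(header, records) that was written.
#' @export
make_sdd_fixture <- function(truth, quality_index = 1L, n_tracks = 10L,
                             path) {
  stopifnot(inherits(truth, "mgm_ground_truth"),
            quality_index >= 1, quality_index <= length(truth$yF_grid))
  set.seed(truth$seed + quality_index)
  yF <- truth$yF_grid[quality_index]
  tm <- truth_yields_at(truth, yF)
  frac_direct <- tm$sb_direct / (tm$sb_direct + tm$sb_indirect)
  nucleus <- nucleus_geometry()

  rows <- list()
  for (t in seq_len(n_tracks)) {
    ch <- sample_chord(1, nucleus)
    n_dsb <- rpois(1, tm$ds_dsb)
    n_free <- rpois(1, 0.5 * tm$ds_dsb + 0.5)
    n_sites <- n_dsb + n_free
    if (n_sites == 0) next
    cx <- sample_complexities(n_dsb, yF, truth$mgm$gamma)
    is_dsb <- rep(c(TRUE, FALSE), c(n_dsb, n_free))
    extra <- ifelse(is_dsb, c(cx, rep(0, n_free)) - 2L, 0L)
    extra_sb <- as.integer(round(extra * 0.5))
    sb1 <- ifelse(is_dsb, 1L + (extra_sb + 1L) %/% 2L, 0L)
    sb2 <- ifelse(is_dsb, 1L + extra_sb %/% 2L, 0L)
    bd <- ifelse(is_dsb, extra - extra_sb, 1L)
    total <- sb1 + sb2 + bd
    direct <- rbinom(n_sites, total, frac_direct)
    u <- sort(runif(n_sites))
    rows[[t]] <- data.frame(
      track_id = t,
      genomic_position_bp = (seq_len(n_sites) - 1L) * 100L,
      x_um = ch$x0_um + u * ch$length_um * ch$dx,
      y_um = ch$y0_um + u * ch$length_um * ch$dy,
      z_um = ch$z0_um + u * ch$length_um * ch$dz,
      n_sb_strand1 = sb1, n_sb_strand2 = sb2, n_bd = bd,
      cause_direct = direct, cause_indirect = total - direct
    )
  }
  rows <- do.call(rbind, rows)
  records <- damage_sites(
    track_id = rows$track_id, chromosome_id = 1L,
    genomic_position_bp = rows$genomic_position_bp,
    x_um = rows$x_um, y_um = rows$y_um, z_um = rows$z_um,
    n_sb_strand1 = rows$n_sb_strand1, n_sb_strand2 = rows$n_sb_strand2,
    n_bd = rows$n_bd, has_dsb = NA,
    cause_direct = rows$cause_direct, cause_indirect = rows$cause_indirect
  )
  header <- sdd_header(
    simulator_name = "microgamma synthetic fixture",
    particle = sprintf("synthetic quality yF = %.4g keV/um", yF),
    free_fields = list(Origin = "synthetic ground truth, not simulation data")
  )
  write_sdd(header, records, path)
  invisible(list(header = header, records = records))
}
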