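# Small in-code fixtures shared across the test files.

# Two tracks x three sites with hand-chosen lesion counts; cause counts
# always sum to the site totals.
two_track_records <- function() {
  damage_sites(
    track_id = c(1L, 1L, 1L, 2L, 2L, 2L),
    chromosome_id = c(1L, 1L, 2L, 1L, 1L, 2L),
    genomic_position_bp = c(0L, 1000L, 500L, 40L, 2000L, 500L),
    x_um = c(0, 0.1, 0.2, 1, 1.1, 1.2),
    n_sb_strand1 = c(1L, 2L, 0L, 1L, 0L, 2L),
    n_sb_strand2 = c(1L, 1L, 0L, 1L, 0L, 1L),
    n_bd = c(0L, 2L, 1L, 1L, 2L, 0L),
    has_dsb = NA,
    cause_direct = c(2L, 3L, 0L, 1L, 2L, 3L),
    cause_indirect = c(0L, 2L, 1L, 2L, 0L, 0L)
  )
}

# Uniformly random valid records for property-style tests.
random_records <- function(n, seed, n_chrom = 3L, pos_max = 500L) {
  set.seed(seed)
  sb1 <- rpois(n, 0.8); sb2 <- rpois(n, 0.8); bd <- rpois(n, 1)
  empty <- sb1 + sb2 + bd == 0
  bd[empty] <- 1L
  total <- sb1 + sb2 + bd
  direct <- rbinom(n, total, 0.4)
  damage_sites(
    track_id = sample.int(4L, n, replace = TRUE),
    chromosome_id = sample.int(n_chrom, n, replace = TRUE),
    genomic_position_bp = sample.int(pos_max, n, replace = TRUE) - 1L,
    x_um = runif(n, -4, 4), y_um = runif(n, -4, 4), z_um = runif(n, -4, 4),
    n_sb_strand1 = sb1, n_sb_strand2 = sb2, n_bd = bd,
    has_dsb = NA, cause_direct = direct, cause_indirect = total - direct
  )
}

# A small ground truth used where full-scale calibration is not the point.
tiny_truth <- function(seed = 7L, noise_sigma = 0) {
  mgm_ground_truth(yF_grid = exp(seq(log(2), log(200), length.out = 8)),
                   tracks_per_quality = 50L,
                   noise_sigma = noise_sigma, seed = seed)
}
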