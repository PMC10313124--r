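#' Complexity score of damage sites
#'
#' The complexity of a damage site is the total number of strand breaks plus
#' base damages it contains, provided the site holds at least one
#' double-strand break; a simple DSB therefore scores 2, and sites without a
#' DSB carry no score (`NA`) and take no part in complexity distributions.
#'
#' @param records A [damage_sites()] data frame (or anything
#'   [validate_damage_sites()] accepts).
#' @return Integer vector, one score per record; `NA` where `has_dsb` is
#'   `FALSE`.
#' @examples
#' rec <- damage_sites(track_id = 1:2, n_sb_strand1 = c(1, 2),
#'                     n_sb_strand2 = c(1, 0), n_bd = c(0, 1))
#' complexity_score(rec)  # 2, NA
#' @export
complexity_score <- function(records) {
  records <- validate_damage_sites(records)
  total <- records$n_sb_strand1 + records$n_sb_strand2 + records$n_bd
  ifelse(records$has_dsb, as.integer(total), NA_integer_)
}

#' Summarize damage records per track
#'
#' Aggregates site records into per-track yields: strand breaks, base
#' damages, damage sites, DSB-containing sites, and the complexity scores of
#' the latter. Direct/indirect splits are computed from the per-site cause
#' counts; because cause is recorded per site (not per lesion type), a
#' site's direct fraction is apportioned to its SB and BD counts
#' proportionally, which is exact whenever a site carries a single lesion
#' type. When cause information is absent on any site the splits are
#' reported as `NA` and flagged via the `cause_available` attribute.
#'
#' @param records A [damage_sites()] data frame.
#' @return A data frame of class `track_summaries`, one row per track, with
#'   columns `track_id`, `n_sb`, `n_sb_direct`, `n_sb_indirect`, `n_bd`,
#'   `n_bd_direct`, `n_bd_indirect`, `n_ds_total`, `n_ds_with_dsb` and a
#'   list column `complexities`.
#' @export
summarize_tracks <- function(records) {
  records <- validate_damage_sites(records)
  scores <- complexity_score(records)
  n_sb_site <- records$n_sb_strand1 + records$n_sb_strand2
  total_site <- n_sb_site + records$n_bd
  has_cause <- !is.na(records$cause_direct) & !is.na(records$cause_indirect)
  cause_available <- all(has_cause)
  frac_direct <- ifelse(has_cause, records$cause_direct / total_site, NA_real_)

  ids <- sort(unique(records$track_id))
  one <- function(tid) {
    i <- records$track_id == tid
    sb_dir <- if (cause_available) sum(n_sb_site[i] * frac_direct[i]) else NA_real_
    bd_dir <- if (cause_available) sum(records$n_bd[i] * frac_direct[i]) else NA_real_
    data.frame(
      track_id = tid,
      n_sb = sum(n_sb_site[i]),
      n_sb_direct = sb_dir,
      n_sb_indirect = if (cause_available) sum(n_sb_site[i]) - sb_dir else NA_real_,
      n_bd = sum(records$n_bd[i]),
      n_bd_direct = bd_dir,
      n_bd_indirect = if (cause_available) sum(records$n_bd[i]) - bd_dir else NA_real_,
      n_ds_total = sum(i),
      n_ds_with_dsb = sum(records$has_dsb[i])
    )
  }
  out <- do.call(rbind, lapply(ids, one))
  out$complexities <- lapply(ids, function(tid)
    scores[records$track_id == tid & !is.na(scores)])
  attr(out, "cause_available") <- cause_available
  class(out) <- c("track_summaries", "data.frame")
  out
}

#' Accumulate damage from independent tracks
#'
#' Damage deposited at the same genomic site by different tracks
#' accumulates: records on the same chromosome whose site windows (of
#' `window_bp` base pairs, starting at each record's genomic position)
#' overlap are merged — transitively — into a single site by summing lesion
#' and cause counts. The merged record keeps the minimum start coordinate
#' (and that record's spatial position and track id), and `has_dsb` is
#' re-derived from the summed strand-break counts, so two single-strand
#' breaks on opposite strands from different tracks can combine into a DSB.
#'
#' Interval merging is delegated to `IRanges::reduce`.
#'
#' @param records A [damage_sites()] data frame spanning one or more tracks.
#' @param window_bp Site window length in base pairs (default 10).
#' @return A [damage_sites()] data frame with at most `nrow(records)` rows;
#'   total counts of each lesion type are conserved.
#' @export
accumulate_tracks <- function(records, window_bp = 10L) {
  records <- validate_damage_sites(records)
  if (nrow(records) < 2L) return(records)

  group <- integer(nrow(records))
  offset <- 0L
  for (chrom in unique(records$chromosome_id)) {
    i <- which(records$chromosome_id == chrom)
    ir <- IRanges::IRanges(start = records$genomic_position_bp[i] + 1L,
                           width = window_bp)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    group[i] <- offset + S4Vectors::subjectHits(hits)
    offset <- offset + length(red)
  }

  merge_group <- function(idx) {
    first <- idx[which.min(records$genomic_position_bp[idx])]
    any_cause <- !anyNA(records$cause_direct[idx]) &&
      !anyNA(records$cause_indirect[idx])
    data.frame(
      track_id = records$track_id[first],
      chromosome_id = records$chromosome_id[first],
      genomic_position_bp = records$genomic_position_bp[first],
      x_um = records$x_um[first], y_um = records$y_um[first],
      z_um = records$z_um[first],
      n_sb_strand1 = sum(records$n_sb_strand1[idx]),
      n_sb_strand2 = sum(records$n_sb_strand2[idx]),
      n_bd = sum(records$n_bd[idx]),
      cause_direct = if (any_cause) sum(records$cause_direct[idx]) else NA_integer_,
      cause_indirect = if (any_cause) sum(records$cause_indirect[idx]) else NA_integer_
    )
  }
  merged <- do.call(rbind, lapply(split(seq_len(nrow(records)), group), merge_group))
  merged <- merged[order(merged$chromosome_id, merged$genomic_position_bp), ]
  damage_sites(
    track_id = merged$track_id, chromosome_id = merged$chromosome_id,
    genomic_position_bp = merged$genomic_position_bp,
    x_um = merged$x_um, y_um = merged$y_um, z_um = merged$z_um,
    n_sb_strand1 = merged$n_sb_strand1, n_sb_strand2 = merged$n_sb_strand2,
    n_bd = merged$n_bd, has_dsb = NA,
    cause_direct = merged$cause_direct, cause_indirect = merged$cause_indirect
  )
}

#' Bootstrap damage yields per Gy
#'
#' Resamples whole tracks with replacement (`tracks_per_dose` tracks per
#' resample, `n_bootstrap` resamples) and reports the mean and variance of
#' each per-Gy yield, emulating the bootstrap used to estimate damage yields
#' and their uncertainty from track-by-track simulation output. The yield of
#' a resample is the summed observable divided by `dose_Gy`, the nominal
#' dose delivered by `tracks_per_dose` tracks.
#'
#' @param summaries A [summarize_tracks()] result.
#' @param dose_Gy Nominal dose of one resample, Gy, > 0.
#' @param tracks_per_dose Number of tracks drawn per resample, >= 1.
#' @param n_bootstrap Number of resamples (default 40).
#' @param seed Optional integer seed; fixing it makes the result
#'   bit-reproducible.
#' @return A data frame with one row per observable: `observable`, `mean`,
#'   `variance` (both per Gy), `n_bootstrap`, `dose_Gy`.
#' @export
bootstrap_yields <- function(summaries, dose_Gy, tracks_per_dose,
                             n_bootstrap = 40L, seed = NULL) {
  stopifnot(inherits(summaries, "track_summaries"))
  if (nrow(summaries) == 0L) stop("no track summaries supplied", call. = FALSE)
  stopifnot(dose_Gy > 0, tracks_per_dose >= 1, n_bootstrap >= 1)
  if (!is.null(seed)) set.seed(seed)

  obs <- c("n_sb", "n_sb_direct", "n_sb_indirect",
           "n_bd", "n_bd_direct", "n_bd_indirect",
           "n_ds_total", "n_ds_with_dsb")
  # direct/indirect splits are NA when cause information was absent
  obs <- obs[vapply(obs, function(o) !anyNA(summaries[[o]]), logical(1))]
  est <- matrix(NA_real_, nrow = n_bootstrap, ncol = length(obs),
                dimnames = list(NULL, obs))
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(nrow(summaries), tracks_per_dose, replace = TRUE)
    est[b, ] <- vapply(obs, function(o) sum(summaries[[o]][idx]) / dose_Gy,
                       numeric(1))
  }
  data.frame(
    observable = obs,
    mean = colMeans(est),
    variance = apply(est, 2, function(x) mean((x - mean(x))^2)),
    n_bootstrap = n_bootstrap,
    dose_Gy = dose_Gy,
    row.names = NULL
  )
}

#' Normalized complexity histogram
#'
#' Bins complexity scores into unit-width (by default) bins centered on
#' integers and normalizes the masses to sum to one.
#'
#' @param complexities Numeric vector of scores, all >= 2, non-empty.
#' @param bin_width Bin width (default 1).
#' @return A data frame of class `complexity_histogram` with columns `mid`
#'   (bin center) and `mass` (probability mass, summing to 1).
#' @export
complexity_histogram <- function(complexities, bin_width = 1) {
  if (length(complexities) == 0L) stop("no complexities supplied", call. = FALSE)
  if (any(complexities < 2)) stop("complexities must be >= 2", call. = FALSE)
  lo <- floor(min(complexities) / bin_width) * bin_width - bin_width / 2
  hi <- (floor(max(complexities) / bin_width) + 1) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(findInterval(complexities, breaks), nbins = length(breaks) - 1)
  structure(
    data.frame(mid = breaks[-length(breaks)] + bin_width / 2,
               mass = counts / sum(counts)),
    class = c("complexity_histogram", "data.frame")
  )
}

#' RMSE between two complexity histograms
#'
#' Aligns both histograms on the union of their bin grids (zero-filling
#' missing bins) and returns the root mean square difference of the bin
#' masses. Symmetric; zero iff the histograms coincide.
#'
#' @param hist_a,hist_b [complexity_histogram()] results (or data frames
#'   with `mid` and `mass` columns).
#' @return Non-negative scalar.
#' @export
distribution_rmse <- function(hist_a, hist_b) {
  grid <- sort(union(hist_a$mid, hist_b$mid))
  at <- function(h) {
    m <- rep(0, length(grid))
    m[match(h$mid, grid)] <- h$mass
    m
  }
  sqrt(mean((at(hist_a) - at(hist_b))^2))
}
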