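test_that("complexity scoring follows the DSB-gated lesion count", {
  rec <- damage_sites(
    track_id = 1:3,
    n_sb_strand1 = c(1L, 2L, 2L),
    n_sb_strand2 = c(1L, 1L, 0L),
    n_bd = c(0L, 2L, 1L)
  )
  # simple DSB scores 2; 2+1 SB and 2 BD scores 5; no DSB scores nothing
  expect_identical(complexity_score(rec), c(2L, 5L, NA_integer_))
  expect_identical(is.na(complexity_score(rec)), !rec$has_dsb)
})

test_that("per-track summaries match a hand tally of the fixture", {
  rec <- two_track_records()
  s <- summarize_tracks(rec)
  expect_equal(s$n_ds_total, c(3L, 3L))
  expect_equal(s$n_ds_with_dsb, c(2L, 2L))
  expect_equal(s$n_sb, c(5L, 5L))
  expect_equal(s$n_bd, c(3L, 3L))
  # track 1 complexities: sites (1,1,0) -> 2 and (2,1,2) -> 5
  expect_equal(s$complexities[[1]], c(2L, 5L))
  # direct + indirect recompose the totals
  expect_equal(s$n_sb_direct + s$n_sb_indirect, as.numeric(s$n_sb))
  expect_equal(s$n_bd_direct + s$n_bd_indirect, as.numeric(s$n_bd))
})

test_that("all-direct records give zero indirect counts", {
  rec <- damage_sites(track_id = 1L, n_sb_strand1 = 2L, n_sb_strand2 = 1L,
                      n_bd = 0L, cause_direct = 3L, cause_indirect = 0L)
  s <- summarize_tracks(rec)
  expect_equal(s$n_sb_indirect, 0)
  expect_equal(s$n_sb_direct, 3)
})

test_that("summaries without cause information flag the splits unavailable", {
  rec <- damage_sites(track_id = 1L, n_sb_strand1 = 1L, n_sb_strand2 = 1L)
  s <- summarize_tracks(rec)
  expect_false(attr(s, "cause_available"))
  expect_true(is.na(s$n_sb_direct))
  expect_equal(s$n_sb, 2L)
})

test_that("opposite single-strand breaks from two tracks merge into a DSB", {
  rec <- damage_sites(
    track_id = 1:2, chromosome_id = 1L, genomic_position_bp = c(100L, 105L),
    n_sb_strand1 = c(1L, 0L), n_sb_strand2 = c(0L, 1L)
  )
  merged <- accumulate_tracks(rec)
  expect_equal(nrow(merged), 1L)
  expect_true(merged$has_dsb)
  expect_equal(complexity_score(merged), 2L)
  expect_equal(merged$genomic_position_bp, 100L)
})

test_that("sites on different chromosomes never merge", {
  rec <- damage_sites(
    track_id = 1:2, chromosome_id = c(1L, 2L), genomic_position_bp = 100L,
    n_sb_strand1 = 1L, n_sb_strand2 = 0L
  )
  expect_equal(nrow(accumulate_tracks(rec)), 2L)
})

test_that("accumulation conserves every lesion and cause count", {
  for (seed in c(3, 17, 91)) {
    rec <- random_records(150, seed = seed, n_chrom = 2L, pos_max = 300L)
    merged <- accumulate_tracks(rec)
    expect_lte(nrow(merged), nrow(rec))
    for (col in c("n_sb_strand1", "n_sb_strand2", "n_bd",
                  "cause_direct", "cause_indirect"))
      expect_equal(sum(merged[[col]]), sum(rec[[col]]))
    # merging is transitively closed: surviving windows are disjoint
    for (chrom in unique(merged$chromosome_id)) {
      pos <- sort(merged$genomic_position_bp[merged$chromosome_id == chrom])
      if (length(pos) > 1) expect_true(all(diff(pos) >= 10))
    }
  }
})

test_that("track bootstrap is seed-reproducible with sane mean and variance", {
  truth <- tiny_truth()
  s <- make_track_summaries(truth)
  s5 <- s[s$yF == truth$yF_grid[5], ]
  class(s5) <- class(s)
  y1 <- bootstrap_yields(s5, dose_Gy = 2, tracks_per_dose = 30, seed = 5)
  y2 <- bootstrap_yields(s5, dose_Gy = 2, tracks_per_dose = 30, seed = 5)
  expect_identical(y1, y2)
  expect_true(all(y1$variance >= 0))
  # bootstrap mean ~ plug-in estimate within 3 bootstrap standard errors
  plug_in <- 30 * mean(s5$n_ds_with_dsb) / 2
  row <- y1[y1$observable == "n_ds_with_dsb", ]
  se <- sqrt(row$variance / row$n_bootstrap)
  expect_lt(abs(row$mean - plug_in), 3 * se + 1e-9)
})

test_that("identical tracks bootstrap to zero variance", {
  rec <- damage_sites(track_id = 1L, n_sb_strand1 = 1L, n_sb_strand2 = 1L)
  s <- summarize_tracks(rec)
  y <- bootstrap_yields(s, dose_Gy = 1, tracks_per_dose = 10,
                        n_bootstrap = 5, seed = 1)
  expect_equal(y$variance, rep(0, nrow(y)))
  y1 <- bootstrap_yields(s, dose_Gy = 1, tracks_per_dose = 10,
                         n_bootstrap = 1, seed = 1)
  expect_equal(y1$mean[y1$observable == "n_sb"], 20)
})

test_that("complexity histograms normalize and align for the RMSE", {
  h <- complexity_histogram(c(2, 2, 3))
  expect_equal(sum(h$mass), 1)
  expect_equal(h$mass[h$mid == 2], 2 / 3)
  expect_equal(h$mass[h$mid == 3], 1 / 3)
  expect_equal(complexity_histogram(c(4, 4, 4))$mass, 1)

  # closed-form two-bin case and symmetry
  ha <- complexity_histogram(rep(2, 10))
  hb <- complexity_histogram(rep(3, 10))
  expect_equal(distribution_rmse(ha, hb), 1)
  expect_equal(distribution_rmse(ha, ha), 0)
  set.seed(2)
  hc <- complexity_histogram(pmax(2, round(rgamma(500, 4, 1))))
  hd <- complexity_histogram(pmax(2, round(rgamma(500, 5, 1))))
  expect_equal(distribution_rmse(hc, hd), distribution_rmse(hd, hc))
  expect_error(complexity_histogram(numeric(0)), "no complexities")
})

test_that("large gamma-discretized samples put the histogram mean near the sample mean", {
  set.seed(9)
  x <- pmax(2, round(rgamma(20000, shape = 5, rate = 0.9)))
  h <- complexity_histogram(x)
  expect_equal(sum(h$mid * h$mass), mean(x), tolerance = 1e-9)
})
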