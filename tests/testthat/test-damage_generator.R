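test_that("chord geometry matches the sphere", {
  nuc <- nucleus_geometry()
  expect_equal(nuc$diameter_um, 9.65)
  # central and grazing chords
  ch <- sample_chord(2000, nuc, seed = 3)
  expect_true(all(ch$length_um <= 9.65 + 1e-12))
  expect_true(all(ch$length_um^2 / 4 + ch$x0_um^2 + ch$y0_um^2 -
                    (9.65 / 2)^2 < 1e-9))
  # Cauchy-formula oracle: mean mu-random chord = 2d/3
  big <- sample_chord(2e5, nuc, seed = 13)
  mc_err <- 4 * sd(big$length_um) / sqrt(nrow(big))
  expect_lt(abs(mean(big$length_um) - mean_chord_length(9.65)), mc_err)
  # isotropic mode keeps chords inside the sphere
  iso <- sample_chord(200, nuc, mode = "isotropic", seed = 5)
  mid <- with(iso, cbind(x0_um + length_um / 2 * dx,
                         y0_um + length_um / 2 * dy,
                         z0_um + length_um / 2 * dz))
  expect_true(all(sqrt(rowSums(mid^2)) <= 9.65 / 2 + 1e-9))
})

test_that("expected track counts follow the microdosimetric dose link", {
  # 6 Gy of yF = 115.3 keV/um radiation in the 9.65 um nucleus
  expect_equal(expected_tracks(6, 115.3), 23.755, tolerance = 1e-4)
  expect_equal(yF_to_zF(115.3, nucleus_geometry()), 0.2526, tolerance = 1e-3)
  # linear in dose, 1/zF ~ d^2 scaling with diameter
  expect_equal(expected_tracks(4, 50), 2 * expected_tracks(2, 50))
  expect_equal(expected_tracks(2, 50, nucleus_geometry(4 * 9.65)),
               16 * expected_tracks(2, 50), tolerance = 1e-12)
})

test_that("zero dose generates an empty realization", {
  truth <- default_truth_params()
  real <- generate_damage(0, beam_spectrum(50), truth, seed = 1)
  expect_equal(nrow(real$tracks), 0L)
  expect_equal(nrow(real$sites), 0L)
})

test_that("generation is reproducible and geometrically contained", {
  truth <- default_truth_params()
  beam <- beam_spectrum(yF = c(10.95, 115.3), weights = c(0.5, 0.5))
  r1 <- generate_damage(2, beam, truth, seed = 42)
  r2 <- generate_damage(2, beam, truth, seed = 42)
  expect_identical(r1$sites, r2$sites)
  # every site lies inside the nucleus sphere
  rad <- with(r1$sites, sqrt(x_um^2 + y_um^2 + z_um^2))
  expect_true(all(rad <= 9.65 / 2 + 1e-9))
  expect_gte(min(r1$sites$complexity), 2)
})

test_that("site counts scale with dose as the Poisson means dictate", {
  truth <- default_truth_params()
  yF <- 115.3
  beam <- beam_spectrum(yF)
  dose <- 2
  mu <- expected_tracks(dose, yF) *
    n_ds_with_dsb(yF, truth$ds_dsb$c1, truth$ds_dsb$c2)
  set.seed(99)
  counts <- vapply(1:300, function(i)
    nrow(generate_damage(dose, beam, truth)$sites), numeric(1))
  # compound Poisson variance: lambda_T * (lambda_s + lambda_s^2)
  lam_s <- n_ds_with_dsb(yF, truth$ds_dsb$c1, truth$ds_dsb$c2)
  v <- expected_tracks(dose, yF) * (lam_s + lam_s^2)
  expect_lt(abs(mean(counts) - mu), 4 * sqrt(v / 300))
})

test_that("energy bookkeeping recovers the dose from the track list", {
  truth <- default_truth_params()
  yF <- 115.3
  nuc <- nucleus_geometry()
  real <- generate_damage(6, beam_spectrum(yF), truth, nucleus = nuc, seed = 7)
  imparted_J <- sum(yF * real$tracks$length_um) * 1.602176634e-16
  dose_rec <- imparted_J / nuc$mass_kg
  # Poisson relative error on ~24 tracks, plus chord-length spread
  expect_lt(abs(dose_rec - 6) / 6, 4 / sqrt(nrow(real$tracks)))
})

test_that("mixture beams pool the component Gamma laws", {
  truth <- default_truth_params()
  beam <- beam_spectrum(yF = c(10, 150), weights = c(0.5, 0.5))
  set.seed(17)
  pooled <- unlist(lapply(1:40, function(i)
    generate_damage(3, beam, truth)$sites$complexity))
  # direct mixture sampling with the same per-component expected site share
  lam <- vapply(seq_len(2), function(ci)
    expected_tracks(0.5 * 3, beam$yF[ci]) *
      n_ds_with_dsb(beam$yF[ci], truth$ds_dsb$c1, truth$ds_dsb$c2), numeric(1))
  w <- lam / sum(lam)
  n <- length(pooled)
  comp <- sample(1:2, n, replace = TRUE, prob = w)
  direct <- unlist(lapply(1:2, function(ci)
    sample_complexities(sum(comp == ci), beam$yF[ci], truth$gamma)))
  ks <- suppressWarnings(stats::ks.test(pooled, direct))
  expect_gt(ks$p.value, 1e-4)
})

test_that("realizations export to SDD and re-score identically", {
  truth <- default_truth_params()
  real <- generate_damage(1.5, beam_spectrum(115.3), truth, seed = 23)
  sdd <- realization_to_sdd(real)
  expect_equal(nrow(sdd$records), nrow(real$sites))
  expect_identical(as.integer(complexity_score(sdd$records)),
                   as.integer(real$sites$complexity))
  # C = 2 decomposes to the minimal DSB: one break per strand, nothing else
  simple <- sdd$records[real$sites$complexity == 2, ]
  expect_true(all(simple$n_sb_strand1 == 1 & simple$n_sb_strand2 == 1 &
                    simple$n_bd == 0))
  # file round trip preserves the scores
  f <- withr::local_tempfile(fileext = ".sdd")
  write_sdd(sdd$header, sdd$records, f)
  back <- read_sdd(f)
  expect_identical(complexity_score(back$records), complexity_score(sdd$records))
})
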