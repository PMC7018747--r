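test_that("the VLP phantom places subunits on the sphere deterministically", {
  ph <- make_vlp_phantom(dim_vox = 64, radius_nm = 40, n_subunits = 80,
                         voxel_size = 21.28, seed = 3)
  tr <- ph$subunit_truth
  expect_equal(nrow(tr), 80)
  r <- sqrt((tr$x - ph$vlp_center[1])^2 + (tr$y - ph$vlp_center[2])^2 +
              (tr$z - ph$vlp_center[3])^2)
  expect_true(all(abs(r - ph$vlp_radius_vox) < 0.02 * ph$vlp_radius_vox))

  # determinism: identical bytes for identical seeds
  ph2 <- make_vlp_phantom(dim_vox = 64, radius_nm = 40, n_subunits = 80,
                          voxel_size = 21.28, seed = 3)
  expect_identical(ph$density, ph2$density)

  # bare shell when no subunits are requested
  ph0 <- make_vlp_phantom(dim_vox = 48, radius_nm = 30, n_subunits = 0,
                          voxel_size = 21.28, seed = 1)
  expect_equal(nrow(ph0$subunit_truth), 0)
  expect_true(all(is.finite(ph0$density)))

  expect_error(make_vlp_phantom(dim_vox = 32, radius_nm = 60,
                                voxel_size = 10.64), "too small")
})

test_that("subunit packing is quasi-uniform", {
  ph <- make_vlp_phantom(dim_vox = 96, radius_nm = 60, n_subunits = 120,
                         voxel_size = 1.33 * 12, seed = 5)
  P <- as.matrix(ph$subunit_truth[, c("x", "y", "z")])
  nn <- vapply(seq_len(nrow(P)), function(i) {
    d <- sqrt(colSums((t(P[-i, ]) - P[i, ])^2))
    min(d)
  }, 0)
  expect_lt(sd(nn) / mean(nn), 0.3)  # nearest-neighbour CV bound
})

test_that("noise-free untilted simulation matches the direct projection", {
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 25, n_subunits = 30,
                         voxel_size = 21.28, seed = 2)
  et <- assign_dose(generate_continuous(increment_policy("constant", 3, 0)))
  ctf <- ctf_params(defocus = -3)
  ts <- simulate_tilt_series(ph, et, ctf = ctf, th = NULL, ce = NULL,
                             noise_sigma = 0, true_shift_range = 0, seed = 1)
  k <- tiltbench:::freq_grid_2d(c(48, 48), ph$voxel_size)
  direct <- tiltbench:::apply_filter_2d(project_volume(ph$density, 0),
                                        ctf_eval(k, ctf))
  expect_gt(cor(as.numeric(ts$images[, , 1]), as.numeric(direct)), 0.999)
})

test_that("projection conserves density and the stack is deterministic", {
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 25, n_subunits = 30,
                         voxel_size = 21.28, seed = 2)
  et <- assign_dose(generate_dose_symmetric(const_policy()))
  ts <- simulate_tilt_series(ph, et, ctf = NULL, th = NULL, ce = NULL,
                             noise_sigma = 0, true_shift_range = 0, seed = 1)
  total <- sum(ph$density)
  sums <- apply(ts$images, 3, sum)
  expect_true(all(abs(sums - total) / total < 0.01))  # 1% integration tolerance

  ts2 <- simulate_tilt_series(ph, et, ctf = NULL, th = NULL, ce = NULL,
                              noise_sigma = 0, true_shift_range = 0, seed = 1)
  expect_identical(ts$images, ts2$images)
})

test_that("schemes over the same angles differ only by the dose filter", {
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 25, n_subunits = 30,
                         voxel_size = 21.28, seed = 2)
  ce <- critical_exposure_model()
  eDS <- assign_dose(generate_dose_symmetric(const_policy()))
  eCT <- assign_dose(generate_continuous(const_policy()))
  tsDS <- simulate_tilt_series(ph, eDS, ctf = NULL, th = NULL, ce = ce,
                               noise_sigma = 0, true_shift_range = 0, seed = 1)
  tsCT <- simulate_tilt_series(ph, eCT, ctf = NULL, th = NULL, ce = ce,
                               noise_sigma = 0, true_shift_range = 0, seed = 1)
  # compare the 30-degree image: radial spectral ratio must match the ratio
  # of the dose attenuations at the two schemes' pre-doses for that angle
  iDS <- which(abs(tsDS$meta$angle - 30) < 1e-9)
  iCT <- which(abs(tsCT$meta$angle - 30) < 1e-9)
  fDS <- abs(fft(tsDS$images[, , iDS]))
  fCT <- abs(fft(tsCT$images[, , iCT]))
  k <- tiltbench:::freq_grid_2d(c(48, 48), ph$voxel_size)
  band <- k > 0.005 & k < 0.02
  measured <- sum(fDS[band]) / sum(fCT[band])
  kb <- mean(k[band])
  predicted <- dose_attenuation(kb, tsDS$meta$pre_dose[iDS], ce) /
    dose_attenuation(kb, tsCT$meta$pre_dose[iCT], ce)
  expect_lt(abs(measured / predicted - 1), 0.05)
})

test_that("the 0-degree image keeps more high-frequency power under DS order", {
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 25, n_subunits = 30,
                         voxel_size = 21.28, seed = 2)
  ce <- critical_exposure_model(a = 0.245 * 16^-1.665)  # band-scaled damage
  eDS <- assign_dose(generate_dose_symmetric(const_policy()))
  eCT <- assign_dose(generate_continuous(const_policy()))
  tsDS <- simulate_tilt_series(ph, eDS, ctf = NULL, ce = ce, noise_sigma = 0,
                               true_shift_range = 0, seed = 1)
  tsCT <- simulate_tilt_series(ph, eCT, ctf = NULL, ce = ce, noise_sigma = 0,
                               true_shift_range = 0, seed = 1)
  k <- tiltbench:::freq_grid_2d(c(48, 48), ph$voxel_size)
  hi <- k > 0.015
  pDS <- sum(abs(fft(tsDS$images[, , tsDS$meta$angle == 0]))[hi]^2)
  pCT <- sum(abs(fft(tsCT$images[, , tsCT$meta$angle == 0]))[hi]^2)
  expect_gt(pDS, pCT)
})

test_that("alignment perturbation is exact in magnitude and isotropic", {
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 25, n_subunits = 10,
                         voxel_size = 21.28, seed = 2)
  et <- assign_dose(generate_dose_symmetric(const_policy()))
  ts <- simulate_tilt_series(ph, et, ctf = NULL, noise_sigma = 0, seed = 1)

  ts0 <- perturb_alignment(ts, 0, seed = 4)
  expect_equal(ts0$alignment_perturbed, ts$alignment)

  ts2 <- perturb_alignment(ts, 2, seed = 4)
  d <- sqrt((ts2$alignment_perturbed$shift_x - ts$alignment$shift_x)^2 +
              (ts2$alignment_perturbed$shift_y - ts$alignment$shift_y)^2)
  expect_equal(d, rep(2, nrow(ts$meta)), tolerance = 1e-12)

  # isotropy of the direction draw at large n
  set.seed(11)
  phi <- runif(1e4, 0, 2 * pi)
  expect_lt(sqrt(mean(cos(phi))^2 + mean(sin(phi))^2), 0.03)
  m <- colMeans(cbind(cos(phi), sin(phi)))
  expect_true(all(abs(m) < 0.02))
})

test_that("tilt-series metadata exports include alignment and exposure", {
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 25, n_subunits = 10,
                         voxel_size = 21.28, seed = 2)
  et <- assign_dose(generate_dose_symmetric(const_policy()))
  ts <- simulate_tilt_series(ph, et, noise_sigma = 0.5, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_series_csv(ts, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 41)
  expect_true(all(c("acq_index", "angle", "pre_dose", "defocus",
                    "shift_x", "shift_y") %in% names(tab)))
  expect_equal(tab$angle, et$angle)
})
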