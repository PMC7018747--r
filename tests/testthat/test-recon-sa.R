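test_that("backprojection geometry places a point source correctly", {
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 8, n_subunits = 0,
                         voxel_size = 21.28, seed = 1, shell_amp = 0)
  ph$density[30, 20, 26] <- 1
  et <- assign_dose(generate_continuous(increment_policy("constant", 3, 0)))
  ts <- simulate_tilt_series(ph, et, ctf = NULL, th = NULL, ce = NULL,
                             noise_sigma = 0, true_shift_range = 0, seed = 1)
  tomo <- reconstruct_wbp(ts, ctf_correct = FALSE)
  am <- which(tomo$density == max(tomo$density), arr.ind = TRUE)
  expect_equal(unname(am[1, 1:2]), c(30, 20))
})

test_that("a noise-free series reconstructs the wedge-limited phantom", {
  d <- rep(48L, 3)
  ph <- make_vlp_phantom(dim_vox = 48, radius_nm = 8, n_subunits = 0,
                         voxel_size = 21.28, seed = 1, shell_amp = 0)
  ph$density <- spherical_mask(d, 12, soft_width = 3)
  et <- assign_dose(generate_continuous(const_policy()))
  ts <- simulate_tilt_series(ph, et, ctf = NULL, th = NULL, ce = NULL,
                             noise_sigma = 0, true_shift_range = 0, seed = 1)
  tomo <- reconstruct_wbp(ts, ctf_correct = FALSE)
  # the +/-60 degree missing wedge caps what any reconstruction can recover;
  # the oracle is the phantom restricted to the measured wedge
  kx <- tiltbench:::fft_freq(48)
  ang <- atan2(abs(array(rep(kx, each = 48 * 48), d)),
               abs(array(kx, d)))
  wedge_ph <- Re(fft(fft(ph$density) * (ang <= 60 * pi / 180),
                     inverse = TRUE)) / prod(d)
  m <- spherical_mask(d, 14) > 0.5
  expect_gt(cor(tomo$density[m], wedge_ph[m]), 0.95)
  expect_gt(cor(tomo$density[m], ph$density[m]), 0.85)

  # misaligned reconstruction is strictly worse than the true alignment
  tsp <- perturb_alignment(ts, 2, seed = 3)
  tp <- reconstruct_wbp(tsp, use_alignment = "perturbed", ctf_correct = FALSE)
  expect_lt(cor(tp$density[m], ph$density[m]),
            cor(tomo$density[m], ph$density[m]))

  expect_error(reconstruct_wbp(ts, use_alignment = "perturbed"), "missing")
})

test_that("subtomogram extraction respects bounds and bookkeeping", {
  vol <- array(rnorm(32^3), rep(32, 3))
  parts <- data.frame(id = 1:4,
                      x = c(16, 16, 3, 30), y = c(16, 20, 16, 16),
                      z = c(16, 16, 16, 16))
  ex <- extract_subtomograms(vol, parts, box = 8)
  expect_equal(ex$kept_ids, c(1L, 2L))
  expect_equal(ex$n_skipped, 2L)
  expect_equal(length(ex$subvolumes), nrow(parts) - ex$n_skipped)
  # the sub's centre voxel matches the tomogram at the particle position
  expect_equal(ex$subvolumes[[1]][4, 4, 4], vol[16 - 4 + 4, 16 - 4 + 4, 16 - 4 + 4])
  expect_error(extract_subtomograms(vol, parts, box = 64), "larger")
})

test_that("local refinement recovers constructed shifts and rotations", {
  ref <- asymmetric_blob(16, seed = 2)
  expect_error(refine_local(ref, array(0, dim(ref))), "empty")

  idf <- refine_local(ref, ref, max_shift = 2)
  expect_equal(idf$shift, c(0, 0, 0), tolerance = 1e-6)
  expect_gt(idf$score, 0.999)

  sh <- c(2, -1, 1)
  shifted <- align_to_common(ref, 0, 0, 0, -sh)
  fit <- refine_local(shifted, ref, max_shift = 3)
  expect_true(all(abs(fit$shift - sh) <= 0.5))

  # rotation recovery needs an object with off-centre structure so a
  # 10-degree turn moves density by more than the interpolation width
  set.seed(2)
  box <- 24
  wide <- array(0, rep(box, 3))
  ctr <- rep((box + 1) / 2, 3)
  for (i in 1:6) {
    p <- ctr + runif(3, -box / 3, box / 3)
    wide <- tiltbench:::add_blob(wide, p, runif(1, 0.6, 1.1),
                                 runif(1, 0.5, 1.5))
  }
  rot <- rotate_volume(wide, euler_zyz(10, 0, 0))
  fit2 <- refine_local(rot, wide, max_shift = 1, max_angle = 15,
                       angle_step = 2)
  # a1/a3 both rotate about z at tilt 0, so compare their sum
  expect_lt(abs((fit2$rot + fit2$psi) - 10), 2 + 1e-9)
  expect_gt(fit2$score, 0.98)
})

test_that("symmetrized averaging is linear and respects half splits", {
  ref <- render_subunit(16)
  subs <- replicate(6, ref, simplify = FALSE)
  names(subs) <- as.character(1:6)
  poses <- data.frame(id = 1:6, rot = 0, tilt = 0, psi = 0)
  hm <- average_symmetrized(subs, poses, sym = 1)
  expect_equal(hm$half_a, ref, tolerance = 1e-12)
  expect_equal(hm$half_b, ref, tolerance = 1e-12)
  expect_equal(hm$n_a + hm$n_b, 6L)
  expect_lte(abs(hm$n_a - hm$n_b), 1L)

  # linearity: pooled average equals the weighted mean of subset averages
  set.seed(8)
  noisy <- lapply(1:6, function(i) ref + array(rnorm(16^3, sd = 0.3),
                                               rep(16, 3)))
  names(noisy) <- as.character(1:6)
  pooled <- Reduce(`+`, noisy) / 6
  hmA <- average_symmetrized(noisy[1:4], poses[1:4, ], sym = 1)
  avgA <- (hmA$half_a * hmA$n_a + hmA$half_b * hmA$n_b) / 4
  hmB <- average_symmetrized(noisy[5:6], poses[5:6, ], sym = 1)
  avgB <- (hmB$half_a * hmB$n_a + hmB$half_b * hmB$n_b) / 2
  expect_equal((avgA * 4 + avgB * 2) / 6, pooled, tolerance = 1e-12)

  expect_error(average_symmetrized(subs[1], poses[1, ], sym = 1), "at least 2")
})

test_that("C6 symmetrization is idempotent on a C6-symmetric volume", {
  ref <- render_subunit(20)           # built C6-symmetric about z
  sym <- symmetrize_volume(ref, 6)
  expect_gt(cor(as.numeric(sym), as.numeric(ref)), 0.999)
})

test_that("C6 averaging resolves at least as well as C1 at matched n", {
  cfg <- benchmark_config(dim_vox = 72, voxel_size = 1.33 * 16, box = 20,
                          mask_radius_frac = 0.3, seed = 3)
  ph <- make_vlp_phantom(dim_vox = 72, radius_nm = 60, n_subunits = 120,
                         voxel_size = 1.33 * 16, seed = 6)
  ds <- simulate_scheme_dataset(
    generate_dose_symmetric(const_policy(), name = "DS"), ph, cfg)
  m1 <- tiltbench:::measure_resolutions(ds$subs, ds$poses, 1, cfg)
  m6 <- tiltbench:::measure_resolutions(ds$subs, ds$poses, 6, cfg)
  expect_lte(m6$res_05, m1$res_05)
})

test_that("fourier cropping preserves the mean and low frequencies", {
  set.seed(4)
  vol <- array(0, rep(32, 3))
  vol <- tiltbench:::add_blob(vol, c(16, 16, 16), 5, 1)
  half <- fourier_crop(vol, 2)
  expect_equal(dim(half), rep(16L, 3))
  expect_equal(mean(half), mean(vol), tolerance = 1e-10)
  # smooth content survives binning: correlate with direct subsampling
  expect_gt(cor(as.numeric(half), as.numeric(vol[seq(1, 32, 2),
                                                 seq(1, 32, 2),
                                                 seq(1, 32, 2)])), 0.98)
  expect_error(fourier_crop(vol, 3))
})

test_that("MRC volumes round-trip through the writer and reader", {
  vol <- array(rnorm(16 * 12 * 8), c(16, 12, 8))
  path <- tempfile(fileext = ".mrc")
  write_mrc(vol, path, voxel_size = 10.64)
  back <- read_mrc(path)
  expect_equal(dim(back), dim(vol))
  expect_equal(as.numeric(back), as.numeric(vol), tolerance = 1e-6)
  expect_equal(attr(back, "voxel_size"), 10.64, tolerance = 1e-5)
})
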