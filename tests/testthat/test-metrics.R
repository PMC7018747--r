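test_that("FSC identities hold for equal, negated and noise volumes", {
  set.seed(2)
  a <- asymmetric_blob(24, seed = 5)
  expect_error(fsc(a, array(0, rep(16, 3))), "differ")

  same <- fsc(a, a)
  expect_true(all(same$fsc > 1 - 1e-9))
  anti <- fsc(a, -a)
  expect_true(all(anti$fsc < -1 + 1e-9))

  # symmetry and scale invariance
  b <- asymmetric_blob(24, seed = 6)
  expect_equal(fsc(a, b)$fsc, fsc(b, a)$fsc, tolerance = 1e-12)
  expect_equal(fsc(3 * a, 3 * b)$fsc, fsc(a, b)$fsc, tolerance = 1e-9)

  # independent white noise: per-shell correlations stay near zero
  n1 <- array(rnorm(24^3), rep(24, 3))
  n2 <- array(rnorm(24^3), rep(24, 3))
  wn <- fsc(n1, n2)
  expect_lt(abs(mean(wn$fsc)), 3 / sqrt(sum(wn$n_voxels)))
  expect_true(all(diff(wn$frequency) > 0))
})

test_that("phase randomization keeps amplitudes and randomizes phases", {
  a <- asymmetric_blob(24, seed = 7)
  set.seed(3)
  ar <- phase_randomize(a, beyond = 0.15, voxel_size = 1)
  Fa <- abs(fft(a))
  Far <- abs(fft(ar))
  expect_equal(Far, Fa, tolerance = 1e-9)          # amplitude spectrum kept
  k <- tiltbench:::freq_grid_3d(rep(24, 3), 1)
  lo <- k <= 0.15
  expect_equal(fft(ar)[lo], fft(a)[lo], tolerance = 1e-9)  # low-k untouched
  expect_gt(max(abs(fft(ar)[!lo] - fft(a)[!lo])), 0)       # high-k changed
})

test_that("gold-standard correction suppresses mask-induced correlation", {
  set.seed(4)
  d <- rep(24L, 3)
  signal <- asymmetric_blob(24, seed = 8)
  half_a <- signal + array(rnorm(prod(d), sd = 0.6), d)
  half_b <- signal + array(rnorm(prod(d), sd = 0.6), d)

  # no mask: the correction is a no-op up to Monte-Carlo noise
  raw <- fsc(half_a, half_b)
  cor0 <- gold_standard_fsc(half_a, b = half_b, mask = NULL,
                            randomize_beyond = 0.2, seed = 1)
  expect_equal(cor0$fsc, raw$fsc, tolerance = 0.1)

  # identical halves under a soft mask stay at full correlation below cutoff
  mask <- spherical_mask(d, 7, soft_width = 3)
  idc <- gold_standard_fsc(signal, b = signal, mask = mask, seed = 1)
  expect_true(all(idc$fsc[idc$frequency < attr(idc, "randomize_beyond")] >
                    0.99))

  # pure-noise halves under a tight mask: masking inflates the raw FSC and
  # the phase-randomization correction must remove the inflation
  n1 <- array(rnorm(prod(d)), d)
  n2 <- array(rnorm(prod(d)), d)
  tight <- spherical_mask(d, 4, soft_width = 2)
  masked <- fsc(n1, n2, mask = tight)
  corr <- gold_standard_fsc(n1, b = n2, mask = tight,
                            randomize_beyond = 0.1, n_rand = 5, seed = 2)
  beyond <- corr$frequency > 0.1
  expect_gt(mean(abs(masked$fsc[beyond])), mean(abs(corr$fsc[beyond])) - 0.05)
  expect_lt(abs(mean(corr$fsc[beyond])), 0.15)
  # conservativeness: corrected never exceeds masked where FSC_rand > 0
  pos <- beyond & corr$fsc_rand > 0
  expect_true(all(corr$fsc[pos] <= corr$fsc_masked[pos] + 1e-9))
})

test_that("resolution readout interpolates the threshold crossing", {
  curve <- structure(data.frame(frequency = c(0.05, 0.10, 0.15, 0.20),
                                fsc = c(1, 1, 1, 1), n_voxels = 10),
                     class = c("fsc_curve", "data.frame"))
  r <- resolution_at(curve, 0.143)
  expect_equal(as.numeric(r), 1 / 0.20)
  expect_true(attr(r, "nyquist_limited"))

  curve$fsc <- c(1, 0.5, 0.143, 0.05)
  expect_equal(as.numeric(resolution_at(curve, 0.143)), 1 / 0.15)

  # step curve: hand-solved linear interpolation lands mid-shell
  curve$fsc <- c(1, 1, 0, 0)
  expect_equal(as.numeric(resolution_at(curve, 0.5)), 1 / 0.125)

  # monotone: a pointwise-lower curve never reports better resolution
  lower <- curve
  lower$fsc <- curve$fsc - 0.2
  expect_gte(as.numeric(resolution_at(lower, 0.3)),
             as.numeric(resolution_at(curve, 0.3)))
})

test_that("reference FSC flags low-pass cutoffs and degrades with noise", {
  ref <- asymmetric_blob(32, seed = 9)
  expect_error(fsc_to_reference(ref, array(0, rep(16, 3))), "grids differ")

  ident <- fsc_to_reference(ref, ref, voxel_size = 3)
  expect_true(attr(ident$resolution, "nyquist_limited"))

  # low-pass the reference at 10 A and expect the 0.5 crossing nearby
  k <- tiltbench:::freq_grid_3d(rep(32, 3), 3)
  lp <- Re(fft(fft(ref) * (k <= 1 / 10), inverse = TRUE)) / 32^3
  res <- fsc_to_reference(lp, ref, voxel_size = 3)$resolution
  shell <- 1 / (32 * 3)
  expect_lt(abs(1 / as.numeric(res) - 1 / 10), 1.5 * shell)

  set.seed(5)
  noisy <- ref + array(rnorm(32^3, sd = 2), rep(32, 3))
  res_noisy <- fsc_to_reference(noisy, ref, voxel_size = 3)$resolution
  expect_gt(as.numeric(res_noisy), as.numeric(res) * 0 + 6)  # worse than clean
})

test_that("B-factor fits recover known decay constants", {
  B <- 100
  N <- c(1100, 2980, 8100, 15000)
  d <- 1 / sqrt((2 / B) * log(N) + 0.001)
  fit <- bfactor_fit(data.frame(N = N, d = d))
  expect_equal(fit$B, 100, tolerance = 1e-6)
  expect_false(fit$degenerate)

  # Monte-Carlo with 5% jitter on d: the median recovered B is within 15%
  set.seed(21)
  Bs <- replicate(200, {
    dn <- d * (1 + rnorm(length(d), sd = 0.05))
    bfactor_fit(data.frame(N = N, d = dn))$B
  })
  expect_lt(abs(median(Bs) - B) / B, 0.15)

  expect_error(bfactor_fit(data.frame(N = c(10, 10, 20), d = c(5, 5, 4))),
               "duplicate")
  expect_error(bfactor_fit(data.frame(N = c(10, 20), d = c(5, 4))),
               "at least 3")
  expect_error(bfactor_fit(data.frame(N = c(10, 20, 30), d = c(5, -4, 3))),
               "positive")
  flat <- bfactor_fit(data.frame(N = c(10, 20, 40), d = c(5, 5, 5)))
  expect_true(flat$degenerate)
})

test_that("FSC curves export to CSV with correction columns", {
  a <- asymmetric_blob(16, seed = 10)
  set.seed(6)
  b <- a + array(rnorm(16^3, sd = 0.3), rep(16, 3))
  cv <- gold_standard_fsc(a, b = b, mask = spherical_mask(rep(16, 3), 5),
                          seed = 1)
  path <- tempfile(fileext = ".csv")
  write_fsc_csv(cv, path)
  tab <- read.csv(path)
  expect_true(all(c("frequency_1_per_A", "correlation",
                    "correlation_masked", "correlation_randomized") %in%
                    names(tab)))
  expect_equal(tab$correlation, cv$fsc, tolerance = 1e-9)
})
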