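# Experiment drivers reproducing the study design at desk scale: the scheme
# benchmark, best-subset selection, the symmetry / particle-number
# experiments and alignment-error injection. Every driver is a pure
# function of (config, seed).

#' Desk-scale benchmark configuration
#'
#' Bundles the phantom, acquisition and analysis settings shared by the
#' experiment drivers. Defaults describe the benchmark conditions scaled to
#' desk size: a 120 nm VLP in a 128^3 grid at 8x-binned pixels (10.64 A),
#' 41 projections over +/-60 degrees at 3.5 e/A^2 per projection.
#'
#' @param dim_vox Phantom / tomogram cubic side in voxels.
#' @param voxel_size Voxel size in Angstrom.
#' @param radius_nm VLP radius in nm.
#' @param n_subunits Subunits on the VLP.
#' @param step,max_angle Constant-increment scheme parameters (degrees).
#' @param dose_per_projection Incident dose per projection, e/A^2.
#' @param noise_sigma Base additive-noise sigma of the simulator.
#' @param defocus Per-series defocus in um (negative = underfocus); `NA`
#'   draws one from the acquisition grid via [sample_defocus()].
#' @param phase_shift CTF phase shift in degrees (0 = no phase plate).
#' @param box Subtomogram box side in voxels.
#' @param pick_jitter SD (voxels) of the position error added to ground-truth
#'   picks before extraction/refinement.
#' @param refine Logical; run constrained local refinement of each particle
#'   against the subunit reference before averaging.
#' @param max_shift Refinement shift bound (voxels).
#' @param symmetries Symmetry orders evaluated.
#' @param mask_radius_frac Spherical FSC mask radius as a fraction of the
#'   box.
#' @param dose_freq_scale Frequency scale applied inside the critical-exposure
#'   model. The simulation runs on binned voxels, so its frequency band is a
#'   scaled model of the full-resolution band of the real acquisition; dose
#'   damage within the simulated band is made to behave like the
#'   high-resolution regime by evaluating the critical exposure at
#'   `k * dose_freq_scale`. The default is the binning factor
#'   `voxel_size / 1.33` so that the simulation Nyquist maps onto the
#'   detector Nyquist. Set to 1 for the unscaled literature model.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(dim_vox = 128, voxel_size = 1.33 * 8,
                             radius_nm = 60, n_subunits = 120,
                             step = 3, max_angle = 60,
                             dose_per_projection = 3.5,
                             noise_sigma = 1.5, defocus = -3,
                             phase_shift = 0, box = 16, pick_jitter = 0.5,
                             refine = FALSE, max_shift = 2,
                             symmetries = c(1, 2, 3, 6),
                             mask_radius_frac = 0.42,
                             dose_freq_scale = voxel_size / 1.33,
                             seed = 1) {
  structure(as.list(environment()), class = "benchmark_config")
}

#' Critical-exposure model of a benchmark configuration
#'
#' The literature model with its scale coefficient folded together with the
#' configured frequency scale: `a (k s)^b + c = (a s^b) k^b + c`.
#'
#' @param config A [benchmark_config()].
#' @return A [critical_exposure_model()].
#' @export
config_ce_model <- function(config) {
  base <- critical_exposure_model()
  critical_exposure_model(a = base$a * config$dose_freq_scale^base$b,
                          b = base$b, c = base$c)
}

# Deterministic per-stage seed derived from the master seed (kept far below
# .Machine$integer.max).
stage_seed <- function(seed, stage, i = 0L) {
  (seed * 1009L + stage * 97L + i) %% 1000000007L
}

#' Simulate, reconstruct and harvest particles for one scheme
#'
#' The single-scheme leg of the benchmark: dose assignment, tilt-series
#' simulation, weighted backprojection, particle picking at jittered
#' ground-truth positions, subtomogram extraction and (optionally)
#' constrained local refinement against the subunit reference.
#'
#' @param scheme A `tilt_scheme`.
#' @param phantom A `vlp_phantom` (shared across schemes for matched
#'   comparisons).
#' @param config A [benchmark_config()].
#' @return List with `subs`, `poses`, `tilt_series`, `tomogram`, `n_skipped`.
#' @export
simulate_scheme_dataset <- function(scheme, phantom, config) {
  exposure <- assign_dose(scheme, config$dose_per_projection)
  defocus <- config$defocus
  if (is.na(defocus)) {
    set.seed(stage_seed(config$seed, 1L))
    defocus <- sample_defocus()
  }
  ctf <- ctf_params(defocus = defocus, phase_shift = config$phase_shift)
  ts <- simulate_tilt_series(phantom, exposure, ctf = ctf,
                             ce = config_ce_model(config),
                             noise_sigma = config$noise_sigma,
                             seed = stage_seed(config$seed, 2L))
  tomo <- reconstruct_wbp(ts, ctf_correct = TRUE,
                          dose_weight = config_ce_model(config))
  truth <- phantom$subunit_truth
  set.seed(stage_seed(config$seed, 3L))
  picks <- truth
  picks$x <- picks$x + stats::rnorm(nrow(picks), sd = config$pick_jitter)
  picks$y <- picks$y + stats::rnorm(nrow(picks), sd = config$pick_jitter)
  picks$z <- picks$z + stats::rnorm(nrow(picks), sd = config$pick_jitter)
  ex <- extract_subtomograms(tomo, picks, box = config$box)
  keep <- truth$id %in% ex$kept_ids
  poses <- truth[keep, c("id", "rot", "tilt", "psi")]
  # residual displacement of the true particle centre from the box centre
  # (even boxes have their centre half a voxel above the rounded pick)
  off <- if (config$box %% 2 == 0) 0.5 else 0
  poses$sx <- truth$x[keep] - (ex$centers[, 1] + off)
  poses$sy <- truth$y[keep] - (ex$centers[, 2] + off)
  poses$sz <- truth$z[keep] - (ex$centers[, 3] + off)
  if (config$refine) {
    ref <- render_subunit(config$box)
    for (i in seq_along(ex$subvolumes)) {
      fit <- refine_local(ex$subvolumes[[i]],
                          align_to_common(ref, -poses$psi[i], -poses$tilt[i],
                                          -poses$rot[i]),
                          max_shift = config$max_shift)
      poses[i, c("sx", "sy", "sz")] <- as.list(fit$shift)
    }
  }
  list(subs = ex$subvolumes, poses = poses, tilt_series = ts,
       tomogram = tomo, n_skipped = ex$n_skipped)
}

# Average one dataset at one symmetry and measure resolutions.
measure_resolutions <- function(subs, poses, sym, config, seed_offset = 0L) {
  hm <- average_symmetrized(subs, poses, sym = sym)
  mask <- spherical_mask(dim(hm$half_a),
                         config$mask_radius_frac * config$box, soft_width = 2)
  curve <- gold_standard_fsc(hm, mask = mask, voxel_size = config$voxel_size,
                             seed = stage_seed(config$seed, 5L, seed_offset))
  list(res_05 = as.numeric(resolution_at(curve, 0.5)),
       res_143 = as.numeric(resolution_at(curve, 0.143)),
       curve = curve, half_maps = hm)
}

#' Run the tilt-scheme benchmark
#'
#' Simulates matched datasets (same phantom, same noise seeds) for each
#' scheme, runs the desk-scale averaging workflow at every configured
#' symmetry, and measures gold-standard FSC resolutions at the 0.5 and 0.143
#' criteria. The analytic transfer-model ranking over the same exposure
#' tables is attached for cross-checking.
#'
#' @param schemes Named list of `tilt_scheme` objects (default: continuous,
#'   bidirectional and dose-symmetric at the configured step).
#' @param config A [benchmark_config()].
#' @return A `scheme_benchmark_report`: list with `resolutions` (data frame:
#'   scheme, sym, res_05, res_143), `transfer_ranking`, `config`, and
#'   `datasets` (per-scheme particle data for reuse).
#' @export
run_scheme_benchmark <- function(config = benchmark_config(),
                                 schemes = NULL) {
  if (is.null(schemes)) {
    pc <- increment_policy("constant", config$step, config$max_angle)
    schemes <- list(continuous = generate_continuous(pc),
                    bidirectional = generate_bidirectional(pc),
                    DS = generate_dose_symmetric(pc))
  }
  phantom <- make_vlp_phantom(dim_vox = config$dim_vox,
                              radius_nm = config$radius_nm,
                              n_subunits = config$n_subunits,
                              voxel_size = config$voxel_size,
                              seed = stage_seed(config$seed, 0L))
  rows <- list()
  datasets <- list()
  curves <- list()
  for (nm in names(schemes)) {
    ds <- simulate_scheme_dataset(schemes[[nm]], phantom, config)
    datasets[[nm]] <- ds[c("subs", "poses")]
    for (sym in config$symmetries) {
      m <- measure_resolutions(ds$subs, ds$poses, sym, config)
      curves[[paste(nm, sym, sep = "|")]] <- m$curve
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = nm, sym = sym, res_05 = m$res_05, res_143 = m$res_143)
    }
  }
  exposures <- lapply(schemes, assign_dose, config$dose_per_projection)
  ranking <- if (length(exposures) >= 2L)
    rank_schemes(exposures, k_eval = 0.8 / (2 * config$voxel_size),
                 ce = config_ce_model(config)) else NULL
  structure(list(resolutions = do.call(rbind, rows),
                 transfer_ranking = ranking, curves = curves,
                 config = config, datasets = datasets),
            class = "scheme_benchmark_report")
}

#' @export
print.scheme_benchmark_report <- function(x, ...) {
  cat("<scheme_benchmark_report>\n")
  print(x$resolutions, row.names = FALSE)
  invisible(x)
}

#' Replicated scheme benchmark with curve averaging
#'
#' Runs [run_scheme_benchmark()] `n_rep` times with replicate-specific
#' seeds (each replicate is a paired design: schemes share the phantom and
#' noise fields). Per scheme and symmetry the corrected FSC curves are
#' averaged across replicates and the resolution is read from the mean
#' curve — a steadier estimate of the expected resolution than averaging
#' per-replicate crossings.
#'
#' @param config A [benchmark_config()]; its `seed` seeds the replicates.
#' @param n_rep Number of replicates.
#' @param schemes As in [run_scheme_benchmark()].
#' @return List with `resolutions` (scheme, sym, mean-curve `res_05` /
#'   `res_143`), `per_replicate` (per-replicate resolution table) and
#'   `transfer_ranking`.
#' @export
run_scheme_benchmark_replicated <- function(config = benchmark_config(),
                                            n_rep = 5, schemes = NULL) {
  per <- list()
  curves <- list()
  ranking <- NULL
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- stage_seed(config$seed, 9L, r)
    rep_r <- run_scheme_benchmark(cfg, schemes = schemes)
    ranking <- rep_r$transfer_ranking
    tab <- rep_r$resolutions
    tab$replicate <- r
    per[[r]] <- tab
    for (key in names(rep_r$curves))
      curves[[key]] <- c(curves[[key]], list(rep_r$curves[[key]]))
  }
  rows <- lapply(names(curves), function(key) {
    cs <- curves[[key]]
    mean_curve <- cs[[1]]
    mean_curve$fsc <- rowMeans(vapply(cs, function(x) x$fsc,
                                      numeric(nrow(cs[[1]]))))
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    data.frame(scheme = parts[1], sym = as.integer(parts[2]),
               res_05 = as.numeric(resolution_at(mean_curve, 0.5)),
               res_143 = as.numeric(resolution_at(mean_curve, 0.143)))
  })
  list(resolutions = do.call(rbind, rows),
       per_replicate = do.call(rbind, per),
       transfer_ranking = ranking)
}

#' Refit-style alignment residuals under injected shift error
#'
#' Emulates the fiducial-model residual bookkeeping: each image observes
#' `n_fiducials` marker displacements equal to its injected shift plus
#' isotropic tracking noise; a rigid low-order trend (quadratic in tilt
#' angle, per shift component) is refitted and the per-marker residual norms
#' summarised. With zero injected error the mean residual reflects pure
#' tracking noise (`sigma_track * sqrt(pi/2)`).
#'
#' @param angles Tilt angles (degrees) of the series.
#' @param injected Per-image injected shift matrix (n x 2, pixels).
#' @param sigma_track Tracking noise SD per coordinate in pixels
#'   (default 0.47, matching a ~0.59 px baseline residual).
#' @param n_fiducials Markers per image (default 5).
#' @param seed Integer seed.
#' @return List with `mean_residual` and `sd_residual` (pixels).
#' @export
alignment_residuals <- function(angles, injected, sigma_track = 0.47,
                                n_fiducials = 5, seed = 1) {
  set.seed(seed)
  n <- length(angles)
  obs_x <- rep(injected[, 1], each = n_fiducials) +
    stats::rnorm(n * n_fiducials, sd = sigma_track)
  obs_y <- rep(injected[, 2], each = n_fiducials) +
    stats::rnorm(n * n_fiducials, sd = sigma_track)
  a <- rep(angles, each = n_fiducials)
  rx <- stats::residuals(stats::lm(obs_x ~ a + I(a^2)))
  ry <- stats::residuals(stats::lm(obs_y ~ a + I(a^2)))
  r <- sqrt(rx^2 + ry^2)
  list(mean_residual = mean(r), sd_residual = stats::sd(r))
}

#' Run the alignment-error injection experiment
#'
#' Simulates a dose-symmetric tilt-series, then for each shift magnitude
#' perturbs the alignment model by that many pixels in random per-image
#' directions, reconstructs with the perturbed alignment, and measures
#' half-map resolutions with C1 and C6 symmetry. Magnitude 0 uses the true
#' alignment and is the baseline. With `n_rep > 1` the whole experiment is
#' replicated with fresh phantom/noise/direction seeds and the corrected FSC
#' curves are averaged per magnitude before the resolution is read off.
#'
#' @param config A [benchmark_config()].
#' @param magnitudes Injected shift magnitudes in pixels (0 is prepended
#'   when absent).
#' @param n_rep Number of replicates averaged.
#' @return An `error_injection_report`: data frame with columns `magnitude`,
#'   `mean_residual`, `sd_residual`, `res_05_C1`, `res_05_C6`, `res_143_C1`,
#'   `res_143_C6`.
#' @export
run_error_injection <- function(config = benchmark_config(),
                                magnitudes = c(0.5, 1, 1.5, 2),
                                n_rep = 1) {
  stopifnot(all(magnitudes >= 0), n_rep >= 1)
  magnitudes <- sort(unique(c(0, magnitudes)))
  pc <- increment_policy("constant", config$step, config$max_angle)
  scheme <- generate_dose_symmetric(pc, name = "DS")
  ctf <- ctf_params(defocus = if (is.na(config$defocus)) -3 else config$defocus,
                    phase_shift = config$phase_shift)
  exposure <- assign_dose(scheme, config$dose_per_projection)
  curves <- list()
  resid_m <- resid_s <- matrix(0, n_rep, length(magnitudes))
  for (r in seq_len(n_rep)) {
    seed_r <- stage_seed(config$seed, 9L, r)
    phantom <- make_vlp_phantom(dim_vox = config$dim_vox,
                                radius_nm = config$radius_nm,
                                n_subunits = config$n_subunits,
                                voxel_size = config$voxel_size,
                                seed = stage_seed(seed_r, 0L))
    ts <- simulate_tilt_series(phantom, exposure, ctf = ctf,
                               ce = config_ce_model(config),
                               noise_sigma = config$noise_sigma,
                               seed = stage_seed(seed_r, 2L))
    truth <- phantom$subunit_truth
    cfg_r <- config
    cfg_r$seed <- seed_r
    for (j in seq_along(magnitudes)) {
      m <- magnitudes[j]
      variant <- "true"
      tsj <- ts
      if (m > 0) {
        tsj <- perturb_alignment(ts, m, seed = stage_seed(seed_r, 4L, j))
        variant <- "perturbed"
      }
      tomo <- reconstruct_wbp(tsj, use_alignment = variant,
                              ctf_correct = TRUE,
                              dose_weight = config_ce_model(config))
      ex <- extract_subtomograms(tomo, truth, box = config$box)
      keep <- truth$id %in% ex$kept_ids
      poses <- truth[keep, c("id", "rot", "tilt", "psi")]
      off <- if (config$box %% 2 == 0) 0.5 else 0
      poses$sx <- truth$x[keep] - (ex$centers[, 1] + off)
      poses$sy <- truth$y[keep] - (ex$centers[, 2] + off)
      poses$sz <- truth$z[keep] - (ex$centers[, 3] + off)
      for (sym in c(1, 6)) {
        mm <- measure_resolutions(ex$subvolumes, poses, sym, cfg_r)
        key <- paste(j, sym, sep = "|")
        curves[[key]] <- c(curves[[key]], list(mm$curve))
      }
      inj <- if (m > 0) {
        al <- tsj$alignment_perturbed
        cbind(al$shift_x - ts$alignment$shift_x,
              al$shift_y - ts$alignment$shift_y)
      } else matrix(0, nrow(ts$meta), 2)
      resid <- alignment_residuals(ts$meta$angle, inj,
                                   seed = stage_seed(seed_r, 6L, j))
      resid_m[r, j] <- resid$mean_residual
      resid_s[r, j] <- resid$sd_residual
    }
  }
  mean_curve_res <- function(j, sym, thr) {
    cs <- curves[[paste(j, sym, sep = "|")]]
    mc <- cs[[1]]
    mc$fsc <- rowMeans(vapply(cs, function(x) x$fsc, numeric(nrow(cs[[1]]))))
    as.numeric(resolution_at(mc, thr))
  }
  rows <- lapply(seq_along(magnitudes), function(j) data.frame(
    magnitude = magnitudes[j],
    mean_residual = mean(resid_m[, j]),
    sd_residual = mean(resid_s[, j]),
    res_05_C1 = mean_curve_res(j, 1, 0.5),
    res_05_C6 = mean_curve_res(j, 6, 0.5),
    res_143_C1 = mean_curve_res(j, 1, 0.143),
    res_143_C6 = mean_curve_res(j, 6, 0.143)))
  structure(do.call(rbind, rows),
            class = c("error_injection_report", "data.frame"))
}

#' Run the particle-number (B-factor) experiment
#'
#' For each subset size, draws a seeded random subset of the particles,
#' averages with the configured symmetry, and measures resolution at the 0.5
#' and 0.143 criteria; both series are fitted by [bfactor_fit()]. Subset
#' sizes must be strictly ascending (duplicates are an error). On synthetic
#' sets smaller than the published sizes, scale the sizes proportionally and
#' log the factor.
#'
#' @param subs,poses Particle subvolumes and poses (as from
#'   [simulate_scheme_dataset()]).
#' @param config A [benchmark_config()].
#' @param subset_sizes Ascending particle counts; defaults to the published
#'   ladder 1100/2980/8100 plus the full set, scaled down to the available
#'   particles.
#' @param sym Symmetry order used throughout (default 6).
#' @return List with `points_05`, `points_143` (data frames of `N`, `d`),
#'   `fit_05`, `fit_143` ([bfactor_fit()] objects), `scale_factor`.
#' @export
run_bfactor_experiment <- function(subs, poses, config = benchmark_config(),
                                   subset_sizes = NULL, sym = 6) {
  n_avail <- length(subs)
  scale_factor <- 1
  if (is.null(subset_sizes)) {
    full <- c(1100, 2980, 8100, 15000)
    scale_factor <- n_avail / 15000
    subset_sizes <- unique(pmax(4, round(full * scale_factor)))
  }
  if (any(diff(subset_sizes) <= 0))
    stop("subset sizes must be strictly ascending")
  if (max(subset_sizes) > n_avail)
    stop("largest subset exceeds available particles")
  p05 <- p143 <- data.frame(N = integer(0), d = numeric(0))
  for (j in seq_along(subset_sizes)) {
    set.seed(stage_seed(config$seed, 7L, j))
    keep <- sort(sample.int(n_avail, subset_sizes[j]))
    m <- measure_resolutions(subs[keep], poses[keep, , drop = FALSE], sym,
                             config, seed_offset = j)
    p05 <- rbind(p05, data.frame(N = subset_sizes[j], d = m$res_05))
    p143 <- rbind(p143, data.frame(N = subset_sizes[j], d = m$res_143))
  }
  list(points_05 = p05, points_143 = p143,
       fit_05 = bfactor_fit(p05), fit_143 = bfactor_fit(p143),
       scale_factor = scale_factor)
}

#' Select the best subset of k tomograms by resolution
#'
#' Enumerates all `choose(n, k)` combinations of tomograms; within each
#' combination every tomogram contributes the same number of particles
#' (seeded random down-sampling to the smallest member), the pooled
#' particles are averaged, and the resolution at the criterion is measured.
#' The winner is the combination with the best (smallest) resolution; exact
#' ties are broken by the lexicographically first id set.
#'
#' @param tomogram_particles List (one element per tomogram) of lists with
#'   `subs` and `poses`.
#' @param k Combination size (default 5).
#' @param criterion FSC threshold (default 0.143).
#' @param config A [benchmark_config()] (supplies voxel size, mask, seed).
#' @param sym Symmetry order for the averages.
#' @return A `subset_selection_result`: list with `combinations` (data
#'   frame: member ids, equalized count, resolution) and `winner` (row
#'   index), plus `winner_ids`.
#' @export
select_best_subset <- function(tomogram_particles, k = 5, criterion = 0.143,
                               config = benchmark_config(), sym = 1) {
  n <- length(tomogram_particles)
  if (k > n) stop("k exceeds the number of tomograms")
  combs <- utils::combn(n, k)
  rows <- list()
  for (ci in seq_len(ncol(combs))) {
    members <- combs[, ci]
    counts <- vapply(tomogram_particles[members],
                     function(t) length(t$subs), 0L)
    m <- min(counts)
    subs <- list()
    poses <- NULL
    for (t in members) {
      set.seed(stage_seed(config$seed, 8L, ci * 100L + t))
      keep <- sort(sample.int(length(tomogram_particles[[t]]$subs), m))
      subs <- c(subs, tomogram_particles[[t]]$subs[keep])
      poses <- rbind(poses,
                     tomogram_particles[[t]]$poses[keep, , drop = FALSE])
    }
    poses$id <- seq_len(nrow(poses))  # re-key to keep parity split balanced
    # common randomization draws across combinations: the comparison is
    # paired, so combination differences reflect their particles, not
    # correction-noise luck
    meas <- measure_resolutions(subs, poses, sym, config)
    rows[[ci]] <- data.frame(ids = paste(members, collapse = "+"),
                             n_per_tomogram = m,
                             resolution = if (criterion == 0.5) meas$res_05
                                          else meas$res_143)
  }
  tab <- do.call(rbind, rows)
  winner <- order(tab$resolution, tab$ids)[1]
  structure(list(combinations = tab, winner = winner,
                 winner_ids = tab$ids[winner]),
            class = "subset_selection_result")
}

#' @export
print.subset_selection_result <- function(x, ...) {
  cat(sprintf("<subset_selection_result> %d combinations, winner %s (%.1f A)\n",
              nrow(x$combinations), x$winner_ids,
              x$combinations$resolution[x$winner]))
  invisible(x)
}
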