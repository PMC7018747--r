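# Weighted backprojection reconstruction and subtomogram extraction.

# Ramp (radial) weighting along the direction perpendicular to the tilt
# axis, the standard WBP filter; a small floor keeps the DC term from
# vanishing entirely.
ramp_filter <- function(d) {
  fx <- abs(fft_freq(d[1]))
  matrix(rep(pmax(fx, fx[2] / 2), d[2]), d[1], d[2])
}

#' Weighted-backprojection reconstruction of a tilt-series
#'
#' Each image is optionally CTF phase-flipped (using its recorded defocus),
#' ramp-filtered along the direction perpendicular to the tilt axis, and
#' backprojected along its beam direction with the chosen alignment applied
#' by bilinear interpolation. Per-projection phase flipping stands in for
#' full 3D-CTF correction at simulation defocus and box sizes.
#'
#' @param ts A `tilt_series`.
#' @param use_alignment `"true"` or `"perturbed"` (requires
#'   [perturb_alignment()] to have been run).
#' @param ctf_correct Logical; apply per-image phase flipping before
#'   backprojection (skipped automatically for images simulated without CTF).
#' @param nz Thickness of the reconstructed volume in voxels (default: the
#'   image x-dimension, giving a cubic tomogram).
#' @param ctf A [ctf_params()] supplying voltage/Cs/amplitude contrast for
#'   phase flipping; defocus and phase shift are taken per image from the
#'   tilt-series metadata.
#' @param dose_weight A [critical_exposure_model()] to apply per-image
#'   exposure weighting `exp(-pre_dose / (2 d_crit(k)))` before
#'   backprojection (the standard dose-weighting preprocessing, which
#'   down-weights frequencies already destroyed by radiation in late
#'   projections), or `NULL` to skip.
#' @return A `tomogram`: list with `density` (3D array), `voxel_size`,
#'   `scheme`, `alignment_variant`, `ctf_corrected`.
#' @export
reconstruct_wbp <- function(ts, use_alignment = c("true", "perturbed"),
                            ctf_correct = TRUE, nz = dim(ts$images)[1],
                            ctf = ctf_params(), dose_weight = NULL) {
  stopifnot(inherits(ts, "tilt_series"), dim(ts$images)[3] >= 1)
  use_alignment <- match.arg(use_alignment)
  align <- if (use_alignment == "true") ts$alignment else ts$alignment_perturbed
  if (is.null(align)) stop("requested alignment variant is missing")
  d <- dim(ts$images)
  nxy <- d[1:2]
  n <- d[3]
  kgrid <- freq_grid_2d(nxy, ts$voxel_size)
  ramp <- ramp_filter(nxy)
  vol <- array(0, c(nxy[1], nxy[2], nz))
  ctrx <- (nxy[1] + 1) / 2
  ctrz <- (nz + 1) / 2
  g <- expand.grid(x = seq_len(nxy[1]), y = seq_len(nxy[2]), z = seq_len(nz))
  for (i in seq_len(n)) {
    img <- ts$images[, , i]
    filt <- ramp
    if (!is.null(dose_weight))
      filt <- filt * dose_attenuation(kgrid, ts$meta$pre_dose[i], dose_weight)
    if (ctf_correct && is.finite(ts$meta$defocus[i])) {
      p <- ctf
      p$defocus <- ts$meta$defocus[i]
      p$phase_shift <- ts$meta$phase_shift[i]
      filt <- filt * sign(ctf_eval(kgrid, p))
    }
    img <- apply_filter_2d(img, filt)
    theta <- ts$meta$angle[i] * pi / 180
    u <- ctrx + (g$x - ctrx) * cos(theta) + (g$z - ctrz) * sin(theta) +
      align$shift_x[i]
    v <- g$y + align$shift_y[i]
    vol <- vol + array(bilinear(img, u, v), dim(vol))
  }
  structure(list(density = vol * pi / (2 * n), voxel_size = ts$voxel_size,
                 scheme = ts$scheme, alignment_variant = use_alignment,
                 ctf_corrected = ctf_correct),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<tomogram> %s: %dx%dx%d @ %.2f A (%s alignment%s)\n",
              x$scheme, d[1], d[2], d[3], x$voxel_size, x$alignment_variant,
              if (x$ctf_corrected) ", phase-flipped" else ""))
  invisible(x)
}

#' Extract box-centred subvolumes at particle positions
#'
#' Particles whose box would leave the tomogram are skipped and counted;
#' positions are rounded to the nearest voxel (the subvoxel residual is the
#' refinement's job).
#'
#' @param tomo A `tomogram` (or bare 3D array).
#' @param particles A `particle_set` or data frame with columns `x`, `y`,
#'   `z` (voxels) and `id`.
#' @param box Box side in voxels; must not exceed any tomogram dimension.
#' @return List with `subvolumes` (list of box^3 arrays, named by particle
#'   id), `kept_ids`, `centers` (the rounded box-centre voxel per kept
#'   particle), `n_skipped`.
#' @export
extract_subtomograms <- function(tomo, particles, box = 16) {
  vol <- if (inherits(tomo, "tomogram")) tomo$density else tomo
  d <- dim(vol)
  if (any(box > d)) stop("box larger than tomogram")
  half_lo <- (box - 1) %/% 2
  half_hi <- box %/% 2
  subs <- list()
  kept <- integer(0)
  centers <- matrix(numeric(0), 0, 3)
  skipped <- 0L
  for (i in seq_len(nrow(particles))) {
    p <- round(c(particles$x[i], particles$y[i], particles$z[i]))
    lo <- p - half_lo
    hi <- p + half_hi
    if (any(lo < 1) || any(hi > d)) {
      skipped <- skipped + 1L
      next
    }
    subs[[length(subs) + 1L]] <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    kept <- c(kept, particles$id[i])
    centers <- rbind(centers, p)
  }
  names(subs) <- as.character(kept)
  list(subvolumes = subs, kept_ids = kept, centers = centers,
       n_skipped = skipped)
}
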