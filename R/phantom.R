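# Synthetic specimen: a virus-like particle modelled as a spherical lattice
# shell decorated with C6-symmetric subunits, emulating the immature HIV-1
# CA-SP1 benchmark sample (120 nm particle diameter in ~200 nm ice).

#' Quasi-uniform directions on the unit sphere
#'
#' Fibonacci spiral sampling followed by a random global rotation (seeded),
#' giving near-uniform nearest-neighbour spacing without lattice artefacts
#' aligned to the grid axes.
#'
#' @param n Number of directions.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (n > 1) {
    R <- euler_zyz(stats::runif(1, 0, 360), stats::runif(1, 0, 180),
                   stats::runif(1, 0, 360))
    dirs <- dirs %*% t(R)
  }
  dirs
}

# Add a Gaussian blob of integrated weight `amp` at world position `p`
# (voxels) into `vol`, truncated at 3 sigma.
add_blob <- function(vol, p, sigma, amp) {
  d <- dim(vol)
  lo <- pmax(1L, floor(p - 3 * sigma))
  hi <- pmin(d, ceiling(p + 3 * sigma))
  if (any(lo > hi)) return(vol)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- exp(-(xs - p[1])^2 / (2 * sigma^2))
  gy <- exp(-(ys - p[2])^2 / (2 * sigma^2))
  gz <- exp(-(zs - p[3])^2 / (2 * sigma^2))
  blob <- amp * outer(outer(gx, gy), gz)
  vol[xs, ys, zs] <- vol[xs, ys, zs] + blob
  vol
}

#' Build a virus-like-particle phantom
#'
#' A smooth spherical shell of density (the lipid/lattice envelope) decorated
#' with `n_subunits` identical C6-symmetric subunits placed quasi-uniformly
#' on the sphere. Each subunit is a hexamer-like cluster of Gaussian lobes:
#' six lobes arranged 60 degrees apart about the local z axis (the outward
#' surface normal) plus an apex lobe displaced outward along the normal. The
#' in-plane twist of each subunit is random but recorded, so ground-truth
#' poses are exact.
#'
#' @param dim_vox Cubic grid side in voxels (default 96).
#' @param radius_nm VLP radius in nm (default 60, i.e. the 120 nm benchmark
#'   particle).
#' @param n_subunits Number of lattice subunits (0 gives the bare shell).
#' @param voxel_size Voxel size in Angstrom (default 10.64, i.e. the 1.33 A
#'   detector pixel binned 8x).
#' @param seed Integer seed controlling subunit placement and twist.
#' @param shell_amp Shell density amplitude relative to the subunit lobes.
#' @param lobe_sigma Subunit lobe standard deviation in voxels.
#' @param lobe_radius In-plane lobe ring radius in voxels.
#' @param center VLP centre in voxels (defaults to the grid centre).
#' @return An object of class `vlp_phantom`: list with `density` (3D array),
#'   `voxel_size`, `vlp_center`, `vlp_radius_vox`, and `subunit_truth`, a
#'   data frame of ground-truth poses (`id`, `x`, `y`, `z` in voxels, ZYZ
#'   Euler angles `rot`, `tilt`, `psi` in degrees, `vlp_id`).
#' @export
make_vlp_phantom <- function(dim_vox = 96, radius_nm = 60, n_subunits = 120,
                             voxel_size = 1.33 * 8, seed = 1,
                             shell_amp = 0.15, lobe_sigma = 1.2,
                             lobe_radius = 2.2,
                             center = rep((dim_vox + 1) / 2, 3)) {
  stopifnot(radius_nm > 0, n_subunits >= 0)
  radius_vox <- radius_nm * 10 / voxel_size
  if (radius_vox + 4 * lobe_sigma + lobe_radius > dim_vox / 2)
    stop("grid too small for the requested VLP radius")
  set.seed(seed)
  d <- rep(as.integer(dim_vox), 3)
  vol <- array(0, d)

  # smooth shell
  if (shell_amp > 0) {
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
    vol <- vol + array(shell_amp * exp(-(r - radius_vox)^2 / (2 * 1.5^2)), d)
  }

  truth <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), rot = numeric(0), tilt = numeric(0),
                      psi = numeric(0), vlp_id = integer(0))
  if (n_subunits > 0) {
    dirs <- fibonacci_sphere(n_subunits)
    twist <- stats::runif(n_subunits, 0, 360)
    pos <- sweep(dirs * radius_vox, 2, center, "+")
    tilt <- acos(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi
    rot <- atan2(dirs[, 2], dirs[, 1]) * 180 / pi
    truth <- data.frame(id = seq_len(n_subunits), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], rot = rot, tilt = tilt, psi = twist,
                        vlp_id = 1L)
    lobes <- subunit_lobes(lobe_sigma, lobe_radius)
    for (i in seq_len(n_subunits)) {
      R <- euler_zyz(rot[i], tilt[i], twist[i])
      for (j in seq_len(nrow(lobes$offsets))) {
        p <- pos[i, ] + as.numeric(R %*% lobes$offsets[j, ])
        vol <- add_blob(vol, p, lobes$sigma[j], lobes$amp[j])
      }
    }
  }
  structure(list(density = vol, voxel_size = voxel_size, vlp_center = center,
                 vlp_radius_vox = radius_vox, subunit_truth = truth,
                 seed = seed),
            class = "vlp_phantom")
}

# Local-frame lobe layout of one subunit: a C6 ring about z plus an apex on
# the axis, offset outward so the subunit has a distinct polarity. Each ring
# lobe carries two finer satellite lobes so the subunit has density detail
# across several length scales (a broad spectrum, as real protein density
# does) rather than a single Gaussian falloff.
subunit_lobes <- function(lobe_sigma, lobe_radius) {
  ring <- t(vapply(0:5, function(j) {
    a <- j * 60 * pi / 180
    c(lobe_radius * cos(a), lobe_radius * sin(a), 0)
  }, numeric(3)))
  fine_out <- ring * (1 + 0.45 / lobe_radius)
  fine_out[, 3] <- 0.9
  fine_in <- ring * (1 - 0.55 / lobe_radius)
  fine_in[, 3] <- -0.7
  offsets <- rbind(ring, fine_out, fine_in, c(0, 0, 1.8))
  list(offsets = offsets,
       sigma = c(rep(lobe_sigma, 6), rep(lobe_sigma * 0.45, 12),
                 lobe_sigma * 0.8),
       amp = c(rep(1, 6), rep(0.55, 12), 1.4))
}

#' Render a single subunit in its local frame
#'
#' The same lobe model used by [make_vlp_phantom()], centred in a cubic box
#' with the symmetry axis along z. Used as the starting reference for
#' refinement and for oracle comparisons.
#'
#' @param box Box side in voxels.
#' @param lobe_sigma,lobe_radius As in [make_vlp_phantom()].
#' @return 3D array.
#' @export
render_subunit <- function(box = 16, lobe_sigma = 1.2, lobe_radius = 2.2) {
  vol <- array(0, rep(as.integer(box), 3))
  ctr <- rep((box + 1) / 2, 3)
  lobes <- subunit_lobes(lobe_sigma, lobe_radius)
  for (j in seq_len(nrow(lobes$offsets)))
    vol <- add_blob(vol, ctr + lobes$offsets[j, ], lobes$sigma[j],
                    lobes$amp[j])
  vol
}

#' @export
print.vlp_phantom <- function(x, ...) {
  cat(sprintf("<vlp_phantom> %d^3 voxels @ %.2f A, radius %.1f vox, %d subunits\n",
              dim(x$density)[1], x$voxel_size, x$vlp_radius_vox,
              nrow(x$subunit_truth)))
  invisible(x)
}

#' Write a phantom's ground-truth subunit table as CSV
#' @param phantom A `vlp_phantom`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(phantom, path) {
  utils::write.csv(phantom$subunit_truth, path, row.names = FALSE)
  invisible(path)
}
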