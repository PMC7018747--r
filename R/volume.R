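# Low-level grid utilities shared by the simulator, the reconstruction code
# and the metrics. Conventions: volumes are numeric arrays indexed [x, y, z],
# 1-based; the rotation/projection centre is at (dim + 1) / 2; the tilt axis
# is y (the second index); at 0 degrees the beam integrates along z.

#' ZYZ Euler angles (degrees) to rotation matrix
#'
#' `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)` maps particle-frame coordinates to
#' the world frame; the particle z-axis maps to the direction with polar
#' angle `tilt` and azimuth `rot`.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_zyz <- function(rot, tilt, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(rot) %*% ry(tilt) %*% rz(psi)
}

# Rotation about the tilt (y) axis by `theta` degrees.
rot_y <- function(theta) euler_zyz(0, theta, 0)

# Vectorised trilinear interpolation; coordinates outside the grid read 0.
# Coordinates exactly on the upper face are folded onto the last cell so the
# boundary plane is interpolated, not dropped.
trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  bx <- x0 == d[1] & fx == 0; x0[bx] <- d[1] - 1L; fx[bx] <- 1
  by <- y0 == d[2] & fy == 0; y0[by] <- d[2] - 1L; fy[by] <- 1
  bz <- z0 == d[3] & fz == 0; z0[bz] <- d[3] - 1L; fz[bz] <- 1
  ok <- x0 >= 1 & x0 < d[1] & y0 >= 1 & y0 < d[2] & z0 >= 1 & z0 < d[3]
  out <- numeric(length(x))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i000 <- x0 + (y0 - 1L) * d[1] + (z0 - 1L) * d[1] * d[2]
  dx <- 1L; dy <- d[1]; dz <- d[1] * d[2]
  v <- vol[i000]           * (1 - fx) * (1 - fy) * (1 - fz) +
       vol[i000 + dx]      * fx       * (1 - fy) * (1 - fz) +
       vol[i000 + dy]      * (1 - fx) * fy       * (1 - fz) +
       vol[i000 + dx + dy] * fx       * fy       * (1 - fz) +
       vol[i000 + dz]      * (1 - fx) * (1 - fy) * fz +
       vol[i000 + dx + dz] * fx       * (1 - fy) * fz +
       vol[i000 + dy + dz] * (1 - fx) * fy       * fz +
       vol[i000 + dx + dy + dz] * fx  * fy       * fz
  out[ok] <- v
  out
}

# Bilinear interpolation on a 2D image, zero outside.
bilinear <- function(img, x, y) {
  d <- dim(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  bx <- x0 == d[1] & fx == 0; x0[bx] <- d[1] - 1L; fx[bx] <- 1
  by <- y0 == d[2] & fy == 0; y0[by] <- d[2] - 1L; fy[by] <- 1
  ok <- x0 >= 1 & x0 < d[1] & y0 >= 1 & y0 < d[2]
  out <- numeric(length(x))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; fx <- fx[ok]; fy <- fy[ok]
  i00 <- x0 + (y0 - 1L) * d[1]
  out[ok] <- img[i00] * (1 - fx) * (1 - fy) + img[i00 + 1L] * fx * (1 - fy) +
    img[i00 + d[1]] * (1 - fx) * fy + img[i00 + 1L + d[1]] * fx * fy
  out
}

#' Rotate a volume about its centre
#'
#' Inverse-mapping resampling with trilinear interpolation:
#' `out(v) = vol(centre + R^-1 (v - centre))`.
#'
#' @param vol 3D array.
#' @param R 3x3 rotation matrix (world = R %*% particle).
#' @return Rotated array of the same dimensions.
#' @export
rotate_volume <- function(vol, R) {
  d <- dim(vol)
  ctr <- (d + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  p <- t(R) %*% rbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
  array(trilinear(vol, p[1, ] + ctr[1], p[2, ] + ctr[2], p[3, ] + ctr[3]), d)
}

#' Project a volume along the beam at a stage tilt
#'
#' Real-space line integration: the specimen is rotated by `theta` about the
#' y axis and summed along z. The projection of the untilted specimen is the
#' plain z-sum, so the total image intensity equals the total volume density
#' (up to interpolation loss at the grid boundary for tilted views).
#'
#' @param vol 3D array.
#' @param theta Stage tilt in degrees.
#' @param n_steps Number of integration steps along the beam (default:
#'   z-dimension of the volume).
#' @return 2D array of dimensions `dim(vol)[1:2]`.
#' @export
project_volume <- function(vol, theta, n_steps = dim(vol)[3]) {
  d <- dim(vol)
  ctr <- (d + 1) / 2
  if (abs(theta) < 1e-12) return(rowSums(vol, dims = 2))
  ct <- cos(theta * pi / 180); st <- sin(theta * pi / 180)
  g <- expand.grid(x = seq_len(d[1]) - ctr[1], y = seq_len(d[2]))
  img <- numeric(d[1] * d[2])
  ts <- seq_len(n_steps) - (n_steps + 1) / 2
  for (t in ts) {
    wx <- ctr[1] + g$x * ct + t * st
    wz <- ctr[3] - g$x * st + t * ct
    img <- img + trilinear(vol, wx, g$y, wz)
  }
  matrix(img, d[1], d[2])
}

# Centred frequency magnitudes for an FFT grid, in cycles per voxel
# (or 1/Angstrom when voxel_size is given in Angstrom).
fft_freq <- function(n) {
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / n
  f
}

# |k| grid for a 2D FFT, 1/Angstrom.
freq_grid_2d <- function(d, voxel_size = 1) {
  kx <- fft_freq(d[1]) / voxel_size
  ky <- fft_freq(d[2]) / voxel_size
  sqrt(outer(kx^2, ky^2, "+"))
}

# |k| grid for a 3D FFT, 1/Angstrom.
freq_grid_3d <- function(d, voxel_size = 1) {
  kx <- fft_freq(d[1]) / voxel_size
  ky <- fft_freq(d[2]) / voxel_size
  kz <- fft_freq(d[3]) / voxel_size
  k2 <- outer(kx^2, ky^2, "+")
  array(sqrt(outer(k2, kz^2, "+")), d)
}

#' Soft-edged spherical mask
#'
#' @param d Dimensions (length-3 integer).
#' @param radius Mask radius in voxels.
#' @param soft_width Width in voxels of the raised-cosine edge (0 = hard).
#' @param center Mask centre (defaults to the volume centre).
#' @return 3D array in `[0, 1]`.
#' @export
spherical_mask <- function(d, radius, soft_width = 3, center = (d + 1) / 2) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  m <- numeric(length(r))
  m[r <= radius] <- 1
  if (soft_width > 0) {
    edge <- r > radius & r <= radius + soft_width
    m[edge] <- 0.5 * (1 + cos(pi * (r[edge] - radius) / soft_width))
  }
  array(m, d)
}

#' Bin a volume by Fourier cropping
#'
#' Crops the Fourier transform to the central region and inverse-transforms,
#' preserving low-frequency amplitudes exactly (values are rescaled so that
#' the mean density is unchanged).
#'
#' @param vol 3D array with even dimensions.
#' @param factor Integer binning factor dividing every dimension.
#' @return Binned array of dimensions `dim(vol) / factor`.
#' @export
fourier_crop <- function(vol, factor) {
  d <- dim(vol)
  stopifnot(all(d %% factor == 0))
  dn <- d %/% factor
  F <- stats::fft(vol)
  keep <- function(n, m) c(seq_len(m / 2 + 1), seq(n - m / 2 + 2, n))
  Fc <- F[keep(d[1], dn[1]), keep(d[2], dn[2]), keep(d[3], dn[3])]
  # drop the (unpaired) Nyquist row imaginary leakage by symmetrising later
  out <- Re(stats::fft(Fc, inverse = TRUE)) / prod(d)
  array(out, dn)
}

#' Write a volume or image stack as an MRC2014 file
#'
#' Minimal MRC2014 writer (mode 2, 32-bit float) sufficient for exchanging
#' simulated volumes and tilt stacks with standard cryo-EM software.
#'
#' @param vol 2D or 3D numeric array.
#' @param path Output path.
#' @param voxel_size Voxel size in Angstrom written into the cell dimensions.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path, voxel_size = 1) {
  d <- dim(vol)
  if (length(d) == 2L) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4, endian = "little")
  writeBin(as.numeric(d * voxel_size), con, size = 4, endian = "little")  # cell A
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")   # angles
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")   # maps
  writeBin(as.numeric(c(min(vol), max(vol), mean(vol))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(100), con)                                   # extra (words 25-49)
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)          # little-endian stamp
  writeBin(as.numeric(stats::sd(as.numeric(vol))), con, size = 4, endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little") # nlabl
  writeBin(raw(800), con)                                    # labels
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC file written by [write_mrc()] (mode 2 only)
#'
#' @param path MRC file path.
#' @return 3D array with attribute `voxel_size`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (mode != 2L) stop("only mode 2 (float32) MRC files are supported")
  invisible(readBin(con, "integer", 6, size = 4, endian = "little"))
  cell <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024)
  vol <- array(readBin(con, "numeric", prod(d), size = 4, endian = "little"), d)
  attr(vol, "voxel_size") <- cell[1] / d[1]
  vol
}
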