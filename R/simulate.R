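# Tilt-series simulation: projection of the phantom at each scheme angle,
# CTF modulation, cumulative-dose low-pass filtering, tilt-dependent
# thickness attenuation, and additive noise, with parametric alignment.

#' Contrast transfer function parameters
#'
#' @param voltage Acceleration voltage in keV (default 300).
#' @param spherical_aberration Cs in mm (default 2.7).
#' @param amplitude_contrast Amplitude-contrast fraction (default 0.07).
#' @param defocus Defocus in micrometres, negative = underfocus (default
#'   -2.5). Use [sample_defocus()] to draw one per tilt-series from an
#'   acquisition grid.
#' @param phase_shift Additional phase shift in degrees (0 for standard
#'   imaging, ~90 for the Volta phase plate). Must lie in `[0, 180)`.
#' @return An object of class `ctf_params`.
#' @export
ctf_params <- function(voltage = 300, spherical_aberration = 2.7,
                       amplitude_contrast = 0.07, defocus = -2.5,
                       phase_shift = 0) {
  stopifnot(voltage > 0, phase_shift >= 0, phase_shift < 180)
  structure(list(voltage = voltage,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast,
                 defocus = defocus, phase_shift = phase_shift),
            class = "ctf_params")
}

#' Draw a per-tilt-series defocus from an acquisition grid
#'
#' Acquisition targets defocus on a discrete grid; the benchmark used
#' -1.5 to -4.0 um in 0.25 um steps for defocused schemes and
#' -1.0 to -3.0 um for the underfocused phase-plate scheme.
#'
#' @param range Length-2 numeric, defocus range in um (negative = underfocus).
#' @param step Grid step in um (default 0.25).
#' @return One defocus value (um) drawn uniformly from the grid.
#' @export
sample_defocus <- function(range = c(-4.0, -1.5), step = 0.25) {
  grid <- seq(min(range), max(range), by = step)
  sample(grid, 1)
}

# Relativistic electron wavelength in Angstrom for voltage in keV.
electron_wavelength <- function(voltage_kev) {
  v <- voltage_kev * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the CTF at spatial frequencies
#'
#' `CTF(k) = -sqrt(1 - A^2) sin(chi) - A cos(chi)` with
#' `chi = pi lambda dz k^2 - pi/2 Cs lambda^3 k^4 + phase_shift`, `dz` the
#' underfocus (positive for underfocused images).
#'
#' @param k Spatial frequency in 1/Angstrom (vectorised, arrays allowed).
#' @param params A [ctf_params()].
#' @return CTF values in `[-1, 1]`, same shape as `k`.
#' @export
ctf_eval <- function(k, params) {
  lambda <- electron_wavelength(params$voltage)
  dz <- -params$defocus * 1e4           # um underfocus -> Angstrom, positive
  cs <- params$spherical_aberration * 1e7
  chi <- pi * lambda * dz * k^2 - pi / 2 * cs * lambda^3 * k^4 +
    params$phase_shift * pi / 180
  a <- params$amplitude_contrast
  -sqrt(1 - a^2) * sin(chi) - a * cos(chi)
}

# Apply a radially defined Fourier filter to a 2D image.
apply_filter_2d <- function(img, filt) {
  Re(stats::fft(stats::fft(img) * filt, inverse = TRUE)) / length(img)
}

#' Simulate a tilt-series from a phantom under an exposure table
#'
#' Each projection is computed as
#' `thickness_attenuation(angle) * IFFT( FFT(projection) * CTF * dose_filter )`
#' plus additive Gaussian noise whose standard deviation is
#' `noise_sigma / thickness_attenuation(angle)` — high-tilt images are both
#' dimmer and noisier, as in real data. The dose filter at projection `i` is
#' `exp(-pre_dose_i / (2 d_crit(k)))`, so schemes differ only through the
#' acquisition order that sets `pre_dose` at each angle.
#'
#' @param phantom A [make_vlp_phantom()] object.
#' @param exposure An `exposure_table` from [assign_dose()].
#' @param ctf A [ctf_params()] or `NULL` to disable CTF modulation.
#' @param th A [thickness_model()] or `NULL` to disable thickness attenuation.
#' @param ce A [critical_exposure_model()] or `NULL` to disable dose
#'   filtering.
#' @param noise_sigma Base noise standard deviation (0 = noise-free).
#' @param true_shift_range Half-width in pixels of the uniform random
#'   per-image stage shift applied to every projection (recorded in the true
#'   alignment, as a fiducial alignment would recover it). Real acquisition
#'   positions are always fractional; 0 disables.
#' @param seed Integer seed for the noise generator.
#' @return A `tilt_series` object: list with `images` (array
#'   `nx x ny x n_proj` in acquisition order), `meta` (angle, pre_dose,
#'   defocus, phase_shift per image), `alignment` (true per-image shifts and
#'   in-plane rotations), `alignment_perturbed` (`NULL` until
#'   [perturb_alignment()]), `voxel_size`, `scheme`, `seed`.
#' @export
simulate_tilt_series <- function(phantom, exposure, ctf = ctf_params(),
                                 th = thickness_model(),
                                 ce = critical_exposure_model(),
                                 noise_sigma = 0, true_shift_range = 0.5,
                                 seed = 1) {
  stopifnot(inherits(phantom, "vlp_phantom"),
            inherits(exposure, "exposure_table"), nrow(exposure) > 0)
  set.seed(seed)
  d <- dim(phantom$density)
  n <- nrow(exposure)
  kgrid <- freq_grid_2d(d[1:2], phantom$voxel_size)
  ctf_vals <- if (is.null(ctf)) 1 else ctf_eval(kgrid, ctf)
  # noise fields are keyed to the sorted-angle (stack) order, not the
  # acquisition order: schemes over the same angle set then share identical
  # noise realizations (a paired design), so differences between schemes
  # come from the dose ordering, not from noise luck
  angle_rank <- rank(exposure$angle, ties.method = "first")
  noise <- if (noise_sigma > 0)
    array(stats::rnorm(d[1] * d[2] * n), c(d[1], d[2], n)) else NULL
  # per-image stage shifts, keyed to stack order like the noise fields
  shifts <- matrix(0, n, 2)
  if (true_shift_range > 0) {
    sh_stack <- matrix(stats::runif(2 * n, -true_shift_range,
                                    true_shift_range), n, 2)
    shifts <- sh_stack[angle_rank, , drop = FALSE]
  }
  kx <- fft_freq(d[1])
  ky <- fft_freq(d[2])
  images <- array(0, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    proj <- project_volume(phantom$density, exposure$angle[i])
    filt <- ctf_vals
    if (!is.null(ce))
      filt <- filt * dose_attenuation(kgrid, exposure$pre_dose[i], ce)
    if (any(shifts[i, ] != 0))
      filt <- filt * exp(-2i * pi * outer(kx * shifts[i, 1],
                                          ky * shifts[i, 2], "+"))
    if (!identical(filt, 1)) proj <- apply_filter_2d(proj, filt)
    w <- if (is.null(th)) 1 else thickness_attenuation(exposure$angle[i], th)
    img <- w * proj
    if (noise_sigma > 0)
      img <- img + noise[, , angle_rank[i]] * (noise_sigma / w)
    images[, , i] <- img
  }
  structure(list(
    images = images,
    meta = data.frame(angle = exposure$angle, pre_dose = exposure$pre_dose,
                      defocus = if (is.null(ctf)) NA_real_ else ctf$defocus,
                      phase_shift = if (is.null(ctf)) 0 else ctf$phase_shift),
    alignment = data.frame(shift_x = shifts[, 1], shift_y = shifts[, 2],
                           rotation = numeric(n)),
    alignment_perturbed = NULL,
    voxel_size = phantom$voxel_size,
    scheme = scheme_name(exposure) %||% "scheme",
    seed = seed), class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf("<tilt_series> %s: %d images %dx%d @ %.2f A%s\n",
              x$scheme, dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              x$voxel_size,
              if (!is.null(x$alignment_perturbed)) " (perturbed alignment)" else ""))
  invisible(x)
}

#' Inject alignment error into a tilt-series
#'
#' Displaces every image's alignment shift by `magnitude` pixels in an
#' independent uniformly random direction, emulating imprecision of the
#' fiducial-based alignment model. The true alignment is retained alongside,
#' so reconstructions can be run with either variant.
#'
#' @param ts A `tilt_series`.
#' @param magnitude Shift magnitude in pixels (`>= 0`).
#' @param seed Integer seed for the directions.
#' @return The tilt-series with `alignment_perturbed` filled in.
#' @export
perturb_alignment <- function(ts, magnitude, seed = 1) {
  stopifnot(inherits(ts, "tilt_series"), magnitude >= 0)
  set.seed(seed)
  n <- nrow(ts$alignment)
  phi <- stats::runif(n, 0, 2 * pi)
  pert <- ts$alignment
  pert$shift_x <- pert$shift_x + magnitude * cos(phi)
  pert$shift_y <- pert$shift_y + magnitude * sin(phi)
  ts$alignment_perturbed <- pert
  ts$perturbation_magnitude <- magnitude
  ts
}

#' Write a tilt-series metadata table as CSV
#'
#' Scheme-order columns plus defocus, phase shift and alignment shifts.
#'
#' @param ts A `tilt_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(ts, path) {
  out <- cbind(acq_index = seq_len(nrow(ts$meta)) - 1L, ts$meta,
               ts$alignment)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
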