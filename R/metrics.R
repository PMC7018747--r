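# Fourier shell correlation, gold-standard masking correction by phase
# randomization, resolution thresholds and B-factor analysis.

# Precompute shell assignment for a cubic grid: shell index per Fourier
# voxel, 1-based, shell width of one Fourier voxel by default.
shell_index <- function(d, shell_width = 1) {
  kx <- fft_freq(d[1]) * d[1]
  ky <- fft_freq(d[2]) * d[2]
  kz <- fft_freq(d[3]) * d[3]
  k2 <- outer(kx^2, ky^2, "+")
  r <- sqrt(array(outer(k2, kz^2, "+"), d))
  pmin(as.integer(floor(r / shell_width)) + 1L,
       as.integer(floor((min(d) / 2) / shell_width)) + 1L)
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients of two
#' (optionally real-space masked) volumes. Shells are one Fourier voxel wide
#' by default; frequencies are reported at shell centres in 1/Angstrom.
#'
#' @param a,b Equal-dimension 3D arrays.
#' @param mask Optional real-space mask applied to both volumes.
#' @param voxel_size Voxel size in Angstrom (sets the frequency scale).
#' @param shell_width Shell width in Fourier voxels.
#' @return An `fsc_curve` data frame: `frequency` (1/Angstrom), `fsc`,
#'   `n_voxels`, with attributes `voxel_size` and `variant`.
#' @export
fsc <- function(a, b, mask = NULL, voxel_size = 1, shell_width = 1) {
  if (!all(dim(a) == dim(b))) stop("volume dimensions differ")
  if (!is.null(mask)) {
    a <- a * mask
    b <- b * mask
  }
  d <- dim(a)
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  sh <- shell_index(d, shell_width)
  nshell <- as.integer(floor((min(d) / 2) / shell_width))
  sh_v <- as.integer(sh)
  num <- vapply(split(Re(Fa * Conj(Fb)), sh_v), sum, 0)
  da <- vapply(split(abs(Fa)^2, sh_v), sum, 0)
  db <- vapply(split(abs(Fb)^2, sh_v), sum, 0)
  cnt <- vapply(split(sh_v, sh_v), length, 0L)
  keep <- seq_len(min(nshell, length(num)))[-1]  # drop the DC shell
  corr <- num[keep] / sqrt(pmax(da[keep] * db[keep], .Machine$double.xmin))
  freq <- (as.integer(names(num)[keep]) - 1) * shell_width / (min(d) * voxel_size)
  structure(data.frame(frequency = freq, fsc = pmin(1, pmax(-1, corr)),
                       n_voxels = cnt[keep]),
            class = c("fsc_curve", "data.frame"),
            voxel_size = voxel_size, variant = "raw")
}

#' Randomize Fourier phases beyond a frequency cutoff
#'
#' Amplitudes are retained; phases beyond `beyond` are replaced by the
#' (Hermitian-consistent) phases of a white-noise volume, so the output is
#' real.
#'
#' @param vol 3D array.
#' @param beyond Cutoff frequency in 1/Angstrom.
#' @param voxel_size Voxel size in Angstrom.
#' @return Phase-randomized array (uses the current RNG state).
#' @export
phase_randomize <- function(vol, beyond, voxel_size = 1) {
  d <- dim(vol)
  F <- stats::fft(vol)
  k <- freq_grid_3d(d, voxel_size)
  Fr <- stats::fft(array(stats::rnorm(prod(d)), d))
  phase <- Fr / pmax(abs(Fr), .Machine$double.xmin)
  hi <- k > beyond
  F[hi] <- abs(F[hi]) * phase[hi]
  Re(stats::fft(F, inverse = TRUE)) / prod(d)
}

#' Gold-standard FSC with phase-randomization mask correction
#'
#' Computes the masked FSC of the two half maps and corrects it for
#' mask-induced correlation beyond a cutoff frequency:
#' `FSC_true = (FSC_masked - FSC_rand) / (1 - FSC_rand)`, where `FSC_rand`
#' is the mean masked FSC over `n_rand` independently phase-randomized
#' half-map pairs (curves are averaged before the correction). Below the
#' cutoff the masked FSC is returned unchanged. Shells where
#' `FSC_rand >= 1` are flagged and left uncorrected rather than divided.
#'
#' @param halves A `half_map_pair`, or `half_a` as a bare array (then `b`
#'   must be given).
#' @param mask Real-space mask; `NULL` for no masking (the correction then
#'   changes nothing beyond Monte-Carlo noise).
#' @param randomize_beyond Cutoff in 1/Angstrom; default (`NULL`) picks the
#'   frequency where the masked FSC first drops below 0.8.
#' @param n_rand Number of phase-randomized pairs averaged (default 5).
#' @param seed Integer seed for the randomizations.
#' @param voxel_size Voxel size in Angstrom.
#' @param b Second half map when `halves` is an array.
#' @return An `fsc_curve` with columns `frequency`, `fsc` (corrected),
#'   `fsc_masked`, `fsc_rand`, `n_voxels`; attribute `variant = "corrected"`
#'   and `randomize_beyond` records the cutoff used.
#' @export
gold_standard_fsc <- function(halves, mask = NULL, randomize_beyond = NULL,
                              n_rand = 5, seed = 1, voxel_size = 1, b = NULL) {
  if (inherits(halves, "half_map_pair")) {
    a <- halves$half_a
    b <- halves$half_b
  } else {
    a <- halves
    if (is.null(b)) stop("second half map required")
  }
  masked <- fsc(a, b, mask = mask, voxel_size = voxel_size)
  nyq <- max(masked$frequency)
  if (is.null(randomize_beyond)) {
    below <- which(masked$fsc < 0.8)
    randomize_beyond <- if (length(below) == 0) nyq
                        else masked$frequency[below[1]]
  }
  if (randomize_beyond > nyq) randomize_beyond <- nyq
  set.seed(seed)
  rand_curves <- replicate(n_rand, {
    ar <- phase_randomize(a, randomize_beyond, voxel_size)
    br <- phase_randomize(b, randomize_beyond, voxel_size)
    fsc(ar, br, mask = mask, voxel_size = voxel_size)$fsc
  })
  fsc_rand <- rowMeans(rand_curves)
  out <- masked
  out$fsc_masked <- masked$fsc
  out$fsc_rand <- fsc_rand
  beyond <- masked$frequency > randomize_beyond
  divisible <- beyond & fsc_rand < 1 - 1e-9
  out$fsc[divisible] <- (masked$fsc[divisible] - fsc_rand[divisible]) /
    (1 - fsc_rand[divisible])
  out$fsc <- pmin(1, pmax(-1, out$fsc))
  out$undivided <- beyond & !divisible
  attr(out, "variant") <- "corrected"
  attr(out, "randomize_beyond") <- randomize_beyond
  out
}

#' Resolution at an FSC threshold
#'
#' Locates the first crossing of the curve below the threshold by linear
#' interpolation between adjacent shells and returns the corresponding
#' resolution in Angstrom. A curve that never drops below the threshold is
#' Nyquist-limited: the Nyquist resolution is returned with attribute
#' `nyquist_limited = TRUE`.
#'
#' @param curve An `fsc_curve`.
#' @param threshold FSC criterion, typically 0.5 (conservative) or 0.143
#'   (gold-standard half maps).
#' @return Resolution in Angstrom (smaller is better).
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  stopifnot(nrow(curve) > 0)
  f <- curve$frequency
  y <- curve$fsc
  below <- which(y < threshold)
  if (length(below) == 0 || below[1] == 1) {
    if (length(below) > 0 && below[1] == 1)
      return(structure(1 / f[1], nyquist_limited = FALSE))
    return(structure(1 / f[length(f)], nyquist_limited = TRUE))
  }
  i <- below[1]
  f_cross <- f[i - 1] + (threshold - y[i - 1]) * (f[i] - f[i - 1]) /
    (y[i] - y[i - 1])
  structure(1 / f_cross, nyquist_limited = FALSE)
}

#' FSC of a map against a reference structure
#'
#' Plain (uncorrected) masked FSC against an external reference on a common
#' grid, with the conservative 0.5-criterion resolution, as used for
#' validating averages against previously determined maps.
#'
#' @param map,reference Equal-dimension 3D arrays.
#' @param mask Optional mask.
#' @param voxel_size Voxel size in Angstrom.
#' @return List with `curve` (an `fsc_curve`) and `resolution` (Angstrom at
#'   FSC = 0.5).
#' @export
fsc_to_reference <- function(map, reference, mask = NULL, voxel_size = 1) {
  if (!all(dim(map) == dim(reference)))
    stop("map and reference grids differ; resample first")
  curve <- fsc(map, reference, mask = mask, voxel_size = voxel_size)
  list(curve = curve, resolution = resolution_at(curve, 0.5))
}

#' B-factor fit of resolution versus particle number
#'
#' Fits the Rosenthal–Henderson relation: `1/d^2` is linear in `ln N`, and
#' the B-factor is `B = 2 / slope` (Angstrom^2). Small B means resolution
#' improves quickly as particles are added.
#'
#' @param points Data frame with columns `N` (particle count) and `d`
#'   (resolution in Angstrom at a fixed FSC criterion); at least 3 rows,
#'   distinct positive `N`, positive `d`.
#' @return A `bfactor_fit`: list with `slope`, `intercept`, `B`,
#'   `residuals`, `points`, `degenerate` (TRUE when the fit is meaningless,
#'   e.g. all resolutions equal because every point is Nyquist-limited).
#' @export
bfactor_fit <- function(points) {
  stopifnot(is.data.frame(points), all(c("N", "d") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 (N, d) points")
  if (any(points$N <= 0) || any(points$d <= 0))
    stop("particle counts and resolutions must be positive")
  if (anyDuplicated(points$N)) stop("duplicate particle counts")
  x <- log(points$N)
  y <- 1 / points$d^2
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  degenerate <- stats::sd(y) < 1e-12 || abs(slope) < 1e-12
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 B = if (degenerate) NA_real_ else 2 / slope,
                 residuals = unname(stats::residuals(fit)),
                 points = points, degenerate = degenerate),
            class = "bfactor_fit")
}

#' @export
print.bfactor_fit <- function(x, ...) {
  if (x$degenerate)
    cat("<bfactor_fit> degenerate (flat resolution series)\n")
  else
    cat(sprintf("<bfactor_fit> B = %.1f A^2 over %d points (slope %.3e)\n",
                x$B, nrow(x$points), x$slope))
  invisible(x)
}

#' Write an FSC curve to CSV
#' @param curve An `fsc_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fsc_csv <- function(curve, path) {
  out <- data.frame(frequency_1_per_A = curve$frequency,
                    correlation = curve$fsc,
                    variant = attr(curve, "variant") %||% "raw")
  if (!is.null(curve$fsc_masked)) out$correlation_masked <- curve$fsc_masked
  if (!is.null(curve$fsc_rand)) out$correlation_randomized <- curve$fsc_rand
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
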