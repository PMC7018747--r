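#' Critical-exposure model for dose-dependent information loss
#'
#' Radiation damage erases high-spatial-frequency information first. The
#' critical exposure at spatial frequency `k` (1/Angstrom) is modelled as
#' `d_crit(k) = a * k^b + c`, the empirical form fitted for cryo-EM exposure
#' weighting; the defaults are the published constants for 300 kV imaging
#' (a = 0.245, b = -1.665, c = 2.81). They are configuration, not physics the
#' package asserts.
#'
#' @param a Scale in e/A^2 (default 0.245).
#' @param b Dimensionless exponent (default -1.665).
#' @param c Offset in e/A^2 (default 2.81).
#' @return An object of class `critical_exposure_model`.
#' @export
critical_exposure_model <- function(a = 0.245, b = -1.665, c = 2.81) {
  m <- structure(list(a = a, b = b, c = c), class = "critical_exposure_model")
  if (critical_exposure(0.5, m) <= 0)
    stop("critical exposure must be positive up to Nyquist")
  m
}

#' Critical exposure at a spatial frequency
#' @param k Spatial frequency in 1/Angstrom (vectorised).
#' @param model A [critical_exposure_model()].
#' @return Critical exposure in e/A^2.
#' @export
critical_exposure <- function(k, model = critical_exposure_model()) {
  model$a * k^model$b + model$c
}

#' Dose attenuation weight at a spatial frequency
#'
#' The surviving signal fraction after `cum_dose` e/A^2 of pre-exposure is
#' `exp(-cum_dose / (2 * d_crit(k)))`: 1 at zero dose, monotone decreasing in
#' dose, and decreasing faster at higher frequency where the critical
#' exposure is smaller.
#'
#' @param k Spatial frequency in 1/Angstrom, `>= 0` (vectorised over `k` or
#'   `cum_dose`).
#' @param cum_dose Accumulated dose in e/A^2 before the exposure, `>= 0`.
#' @param model A [critical_exposure_model()].
#' @return Weight in `[0, 1]`.
#' @examples
#' dose_attenuation(0.25, 0)    # 1
#' dose_attenuation(0.25, 100)  # far below 1
#' @export
dose_attenuation <- function(k, cum_dose, model = critical_exposure_model()) {
  if (any(k < 0)) stop("spatial frequency must be non-negative")
  if (any(cum_dose < 0)) stop("cumulative dose must be non-negative")
  exp(-cum_dose / (2 * critical_exposure(k, model)))
}

#' Effective-thickness model
#'
#' A tilted slab of ice of thickness `t` presents an effective path length
#' `t / cos(theta)` to the beam; inelastic scattering attenuates the usable
#' signal as `exp(-t / (lambda * cos(theta)))` with `lambda` the inelastic
#' mean free path. Defaults describe the benchmark specimen: a 120 nm
#' virus-like particle in roughly 200 nm of vitreous ice.
#'
#' @param ice_thickness Slab thickness in nm (default 200).
#' @param mean_free_path Inelastic mean free path in nm (default 300).
#' @return An object of class `thickness_model`.
#' @export
thickness_model <- function(ice_thickness = 200, mean_free_path = 300) {
  stopifnot(ice_thickness > 0, mean_free_path > 0)
  structure(list(ice_thickness = ice_thickness,
                 mean_free_path = mean_free_path),
            class = "thickness_model")
}

#' Tilt-dependent thickness attenuation weight
#'
#' @param angle Tilt angle in degrees, `|angle| < 90` (vectorised).
#' @param model A [thickness_model()].
#' @return `exp(-t / (lambda * cos(angle)))`, strictly decreasing in
#'   `|angle|`; at 60 degrees the weight is the square of the 0-degree
#'   weight (path length doubles).
#' @export
thickness_attenuation <- function(angle, model = thickness_model()) {
  if (any(abs(angle) >= 90)) stop("|angle| must be below 90 degrees")
  exp(-model$ice_thickness /
        (model$mean_free_path * cos(angle * pi / 180)))
}

#' Per-projection, per-frequency transfer spectrum of a tilt scheme
#'
#' An analytic signal-to-noise proxy for how much information a scheme
#' retains at each spatial frequency: each projection contributes
#' `w_i(k) = dose_attenuation(k, pre_dose_i) * thickness_attenuation(angle_i)`
#' and the aggregate score is `S(k) = sum_i w_i(k)` (matched-filter sum) or
#' the root-sum-square when `quadrature = "rss"`. Schemes that place their
#' low-dose projections at low tilt (dose-symmetric ordering) score higher at
#' high frequency.
#'
#' @param exposure An `exposure_table` from [assign_dose()].
#' @param freqs Spatial frequency grid in 1/Angstrom.
#' @param ce A [critical_exposure_model()].
#' @param th A [thickness_model()].
#' @param quadrature `"sum"` (default) or `"rss"`.
#' @return A `transfer_spectrum`: list with `frequencies`, per-projection
#'   weight matrix `weights` (projections x frequencies), aggregate `score`,
#'   and the scheme name.
#' @export
scheme_transfer <- function(exposure, freqs = seq(0.01, 0.375, by = 0.005),
                            ce = critical_exposure_model(),
                            th = thickness_model(),
                            quadrature = c("sum", "rss")) {
  stopifnot(inherits(exposure, "exposure_table"))
  quadrature <- match.arg(quadrature)
  w_dose <- outer(exposure$pre_dose, freqs,
                  function(d, k) dose_attenuation(k, d, ce))
  w <- w_dose * thickness_attenuation(exposure$angle, th)
  score <- if (quadrature == "sum") colSums(w) else sqrt(colSums(w^2))
  structure(list(frequencies = freqs, weights = w, score = score,
                 scheme = scheme_name(exposure) %||% "scheme",
                 quadrature = quadrature),
            class = "transfer_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transfer_spectrum <- function(x, ...) {
  cat(sprintf("<transfer_spectrum> %s: %d projections, %d frequencies, S(max k)=%.3f\n",
              x$scheme, nrow(x$weights), length(x$frequencies),
              x$score[length(x$score)]))
  invisible(x)
}

#' Rank tilt schemes by transfer score at an evaluation frequency
#'
#' @param exposures Named list of `exposure_table` objects (at least 2).
#' @param k_eval Evaluation frequency in 1/Angstrom (default 0.2,
#'   i.e. 5 Angstrom).
#' @param ce,th Transfer model components.
#' @return Data frame with columns `scheme`, `score`, `rank`, `tied`, sorted
#'   by descending score; ties (scores equal within 1e-9 relative) are broken
#'   by name and flagged.
#' @export
rank_schemes <- function(exposures, k_eval = 0.2,
                         ce = critical_exposure_model(),
                         th = thickness_model()) {
  stopifnot(length(exposures) >= 2L)
  nm <- names(exposures)
  if (is.null(nm)) nm <- vapply(exposures, scheme_name, "")
  scores <- vapply(exposures, function(e)
    scheme_transfer(e, freqs = k_eval, ce = ce, th = th)$score, 0)
  ord <- order(-scores, nm)
  out <- data.frame(scheme = nm[ord], score = scores[ord],
                    rank = seq_along(ord), row.names = NULL)
  rel <- abs(diff(out$score)) <= 1e-9 * pmax(abs(out$score[-1]), 1e-300)
  out$tied <- c(FALSE, rel) | c(rel, FALSE)
  out
}

#' Export a transfer spectrum (or several) to CSV
#'
#' One row per frequency with a score column per scheme.
#'
#' @param spectra A `transfer_spectrum` or list of them on a common grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transfer_csv <- function(spectra, path) {
  if (inherits(spectra, "transfer_spectrum")) spectra <- list(spectra)
  out <- data.frame(frequency_1_per_A = spectra[[1]]$frequencies)
  for (sp in spectra) out[[sp$scheme]] <- sp$score
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot transfer scores versus spatial frequency
#'
#' @param spectra A `transfer_spectrum` or list of them.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the score matrix.
#' @export
plot_transfer <- function(spectra, ...) {
  if (inherits(spectra, "transfer_spectrum")) spectra <- list(spectra)
  f <- spectra[[1]]$frequencies
  m <- vapply(spectra, function(s) s$score, numeric(length(f)))
  graphics::matplot(f, m, type = "l", lty = 1,
                    xlab = "spatial frequency (1/A)",
                    ylab = "transfer score S(k)", ...)
  graphics::legend("topright", legend = vapply(spectra, function(s) s$scheme, ""),
                   col = seq_along(spectra), lty = 1, bty = "n")
  invisible(m)
}
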