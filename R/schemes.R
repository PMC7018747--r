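#' Angular increment policy for tilt-scheme generation
#'
#' Bundles the angular increment rule with the tilt range. Constant-increment
#' schemes advance by `base_step` degrees; the variable dose-symmetric schemes
#' advance by `base_step * cos(theta)` (decreasing increment) or
#' `base_step / cos(theta)` (increasing increment), where `theta` is the
#' current tilt angle of the branch in degrees.
#'
#' @param mode One of `"constant"`, `"decreasing"`, `"increasing"`.
#' @param base_step Angular step in degrees (for variable modes this is the
#'   initial step applied at 0 degrees). Must be positive.
#' @param max_angle Maximum absolute tilt angle in degrees. Must be positive
#'   (use `generate_continuous()` with `max_angle = 0` for the degenerate
#'   single-projection case).
#' @return An object of class `increment_policy`.
#' @examples
#' increment_policy("constant", 3, 60)
#' increment_policy("decreasing", 3.7, 60)
#' @export
increment_policy <- function(mode = c("constant", "decreasing", "increasing"),
                             base_step, max_angle) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(base_step), length(base_step) == 1L, base_step > 0,
            is.numeric(max_angle), length(max_angle) == 1L, max_angle >= 0)
  structure(list(mode = mode, base_step = base_step, max_angle = max_angle),
            class = "increment_policy")
}

#' @export
print.increment_policy <- function(x, ...) {
  cat(sprintf("<increment_policy> mode=%s step=%g deg max=%g deg\n",
              x$mode, x$base_step, x$max_angle))
  invisible(x)
}

# Angle comparisons throughout use a 0.01 degree tolerance; printed output is
# rounded to 0.1 degree only when written to disk.
.ANGLE_TOL <- 0.01

new_tilt_scheme <- function(name, angles, policy, scheme_kind,
                            offset = 0, group_size = 2L) {
  angles <- as.numeric(angles)
  if (any(abs(angles) > policy$max_angle + 1e-9))
    stop("tilt angle outside [-max_angle, max_angle]")
  if (length(angles) > 1L) {
    d <- abs(outer(angles, angles, "-"))
    diag(d) <- Inf
    if (min(d) < .ANGLE_TOL)
      stop("duplicate tilt angles (within 0.01 degrees)")
  }
  structure(list(name = name, angles = angles, policy = policy,
                 scheme_kind = scheme_kind, offset = offset,
                 group_size = as.integer(group_size)),
            class = "tilt_scheme")
}

#' @export
print.tilt_scheme <- function(x, ...) {
  n <- length(x$angles)
  shown <- if (n > 8) paste(c(sprintf("%.1f", x$angles[1:6]), "...",
                              sprintf("%.1f", x$angles[n])), collapse = ", ")
           else paste(sprintf("%.1f", x$angles), collapse = ", ")
  cat(sprintf("<tilt_scheme> %s (%s), %d projections\n  order: %s\n",
              x$name, x$scheme_kind, n, shown))
  invisible(x)
}

#' Number of projections in a tilt scheme
#' @param x A `tilt_scheme`.
#' @return Integer count of projections.
#' @export
n_projections <- function(x) length(x$angles)

# Constant-increment angle grid over [-max, max]; exact multiples of the step.
constant_grid <- function(policy) {
  k <- floor(policy$max_angle / policy$base_step + 1e-9)
  policy$base_step * seq.int(-k, k)
}

#' Generate a continuous (unidirectional) tilt scheme
#'
#' Projections are acquired by tilting strictly in one direction from
#' `-max_angle` to `+max_angle` in constant steps, e.g.
#' -60, -57, ..., 0, ..., 57, 60 for a 3 degree step. The first projections —
#' the only ones with low accumulated dose — are therefore acquired at high
#' tilt, where the effective specimen thickness is largest.
#'
#' @param policy An [increment_policy()] with `mode = "constant"`.
#' @param name Scheme name used in reports.
#' @return A `tilt_scheme` with angles in acquisition order.
#' @examples
#' generate_continuous(increment_policy("constant", 3, 60))
#' @export
generate_continuous <- function(policy, name = "continuous") {
  if (policy$mode != "constant")
    stop("continuous scheme requires a constant increment policy")
  new_tilt_scheme(name, constant_grid(policy), policy, "continuous")
}

#' Generate a bidirectional tilt scheme
#'
#' The first branch starts at `offset` (default 0) and proceeds downward to
#' `-max_angle`; the second branch returns to `offset + step` and proceeds
#' upward to `+max_angle`. Half of the total dose is accumulated before any
#' positive-branch projection is acquired.
#'
#' @param policy An [increment_policy()] with `mode = "constant"`.
#' @param offset Starting angle in degrees; must lie on the constant-increment
#'   grid (a multiple of `base_step`) within `(-max_angle, max_angle]`.
#'   Off-grid offsets are an error, not rounded.
#' @param name Scheme name.
#' @return A `tilt_scheme` in acquisition order.
#' @examples
#' s <- generate_bidirectional(increment_policy("constant", 3, 60))
#' s$angles[22]  # first positive-branch angle
#' @export
generate_bidirectional <- function(policy, offset = 0, name = "bidirectional") {
  if (policy$mode != "constant")
    stop("bidirectional scheme requires a constant increment policy")
  if (abs(offset / policy$base_step - round(offset / policy$base_step)) > 1e-9)
    stop("offset must be a multiple of base_step")
  if (offset <= -policy$max_angle - 1e-9 || offset > policy$max_angle + 1e-9)
    stop("offset outside (-max_angle, max_angle]")
  step <- policy$base_step
  branch1 <- seq(offset, -policy$max_angle, by = -step)
  branch2 <- if (offset + step <= policy$max_angle + 1e-9)
    seq(offset + step, policy$max_angle, by = step) else numeric(0)
  new_tilt_scheme(name, c(branch1, branch2), policy, "bidirectional",
                  offset = offset)
}

# Interleave per-side magnitude lists into the dose-symmetric acquisition
# order: 0 first, then a single negative step, then alternating groups of
# `group_size` angles of increasing magnitude, starting with the positive side.
ds_interleave <- function(side_mags, group_size) {
  pos <- side_mags
  neg <- -side_mags
  order <- c(0, neg[1L])
  ip <- 1L  # next positive index
  in_ <- 2L # next negative index
  take_pos <- TRUE
  while (ip <= length(pos) || in_ <= length(neg)) {
    if (take_pos && ip <= length(pos)) {
      k <- min(group_size, length(pos) - ip + 1L)
      order <- c(order, pos[ip:(ip + k - 1L)])
      ip <- ip + k
    } else if (!take_pos && in_ <= length(neg)) {
      k <- min(group_size, length(neg) - in_ + 1L)
      order <- c(order, neg[in_:(in_ + k - 1L)])
      in_ <- in_ + k
    }
    take_pos <- !take_pos
  }
  order
}

#' Generate a dose-symmetric (Hagen) tilt scheme
#'
#' Acquisition starts at 0 degrees and alternates sides in groups so that the
#' accumulated dose grows symmetrically with tilt magnitude:
#' 0, -3, 3, 6, -6, -9, 9, 12, -12, ..., 60, -60 for a 3 degree step and
#' group size 2. The best-preserved (lowest-dose) projections are acquired at
#' low tilt, where the effective thickness is minimal.
#'
#' @param policy An [increment_policy()] with `mode = "constant"`.
#' @param group_size Number of consecutive angles acquired per side before
#'   switching direction (default 2).
#' @param name Scheme name.
#' @return A `tilt_scheme` in acquisition order.
#' @examples
#' generate_dose_symmetric(increment_policy("constant", 3, 60))$angles[1:5]
#' @export
generate_dose_symmetric <- function(policy, group_size = 2L,
                                    name = "dose-symmetric") {
  if (policy$mode != "constant")
    stop("constant-increment dose-symmetric scheme requires mode = constant")
  if (group_size < 1L) stop("group_size must be >= 1")
  mags <- policy$base_step * seq_len(floor(policy$max_angle / policy$base_step + 1e-9))
  if (length(mags) == 0L)
    return(new_tilt_scheme(name, 0, policy, "dose_symmetric",
                           group_size = group_size))
  new_tilt_scheme(name, ds_interleave(mags, group_size), policy,
                  "dose_symmetric", group_size = group_size)
}

#' Per-side tilt magnitudes for a variable-increment recurrence
#'
#' Iterates `theta_{k+1} = theta_k + base_step * cos(theta_k)` (decreasing
#' increment) or `theta_{k+1} = theta_k + base_step / cos(theta_k)`
#' (increasing increment) from `theta_0 = 0`, in degrees, while the next angle
#' does not exceed `max_angle`. The final angle is not snapped to `max_angle`.
#'
#' @param policy An [increment_policy()] with a variable mode.
#' @return Numeric vector of positive tilt magnitudes (0 excluded), ascending.
#' @export
variable_increment_magnitudes <- function(policy) {
  if (policy$mode == "constant")
    stop("variable-increment recurrence requires mode decreasing or increasing")
  theta <- 0
  mags <- numeric(0)
  repeat {
    inc <- if (policy$mode == "decreasing")
      policy$base_step * cos(theta * pi / 180)
    else policy$base_step / cos(theta * pi / 180)
    nxt <- theta + inc
    if (nxt > policy$max_angle + 1e-9) break
    mags <- c(mags, nxt)
    theta <- nxt
  }
  mags
}

#' Generate a dose-symmetric scheme with variable angular increment
#'
#' Per-side magnitudes follow the decreasing- or increasing-increment
#' recurrence of [variable_increment_magnitudes()]; the acquisition order uses
#' the same side-alternating grouping as [generate_dose_symmetric()]. With the
#' benchmark settings (initial step 3.7 degrees decreasing, or 2.5 degrees
#' increasing, 60 degree limit) each variant yields 41 projections.
#'
#' @inheritParams generate_dose_symmetric
#' @return A `tilt_scheme` in acquisition order.
#' @examples
#' s <- generate_ds_variable(increment_policy("decreasing", 3.7, 60))
#' round(sort(s$angles[s$angles > 0]), 1)  # ends 57.9, 59.9
#' @export
generate_ds_variable <- function(policy, group_size = 2L,
                                 name = paste0("DS ", substr(policy$mode, 1, 3))) {
  mags <- variable_increment_magnitudes(policy)
  if (2L * length(mags) + 1L < 3L)
    stop("recurrence produced fewer than 3 angles")
  new_tilt_scheme(name, ds_interleave(mags, group_size), policy,
                  "dose_symmetric", group_size = group_size)
}

#' Attach cumulative exposure bookkeeping to a tilt scheme
#'
#' Each projection receives the same incident dose; the i-th acquired
#' projection has accumulated `(i - 1) * dose_per_projection` electrons per
#' square Angstrom before its own exposure. The benchmark default of
#' 3.5 e/A^2 over 41 projections gives a total dose of 143.5 e/A^2.
#'
#' @param scheme A `tilt_scheme`.
#' @param dose_per_projection Incident dose per projection in e/A^2
#'   (default 3.5).
#' @return An `exposure_table`: a data frame with columns `acq_index`
#'   (0-based), `angle`, `pre_dose`, `post_dose`, carrying the scheme name and
#'   dose rate as attributes.
#' @examples
#' et <- assign_dose(generate_dose_symmetric(increment_policy("constant", 3, 60)))
#' tail(et, 1)$post_dose  # 143.5
#' @export
assign_dose <- function(scheme, dose_per_projection = 3.5) {
  stopifnot(inherits(scheme, "tilt_scheme"),
            dose_per_projection > 0)
  n <- length(scheme$angles)
  tab <- data.frame(
    acq_index = seq_len(n) - 1L,
    angle = scheme$angles,
    pre_dose = (seq_len(n) - 1L) * dose_per_projection,
    post_dose = seq_len(n) * dose_per_projection
  )
  structure(tab, class = c("exposure_table", "data.frame"),
            scheme_name = scheme$name,
            scheme_kind = scheme$scheme_kind,
            dose_per_projection = dose_per_projection)
}

#' Scheme name stored on an exposure table
#' @param x An `exposure_table`.
#' @return Character scalar.
#' @export
scheme_name <- function(x) attr(x, "scheme_name")

#' Write tilt angles to an IMOD-style .tlt file
#'
#' One angle per line in sorted (stack) order, rounded to 0.1 degree.
#'
#' @param scheme A `tilt_scheme` or `exposure_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tlt <- function(scheme, path) {
  angles <- if (inherits(scheme, "tilt_scheme")) scheme$angles else scheme$angle
  writeLines(sprintf("%.1f", sort(angles)), path)
  invisible(path)
}

#' Read tilt angles from an IMOD-style .tlt file
#' @param path File with one angle per line.
#' @return Numeric vector of angles in stack (sorted) order.
#' @export
read_tlt <- function(path) as.numeric(readLines(path))

#' Write a scheme-order CSV
#'
#' Columns: `acq_index`, `angle_deg`, `pre_dose_e_per_A2`,
#' `post_dose_e_per_A2`, one row per projection in acquisition order.
#'
#' @param exposure An `exposure_table` from [assign_dose()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme_csv <- function(exposure, path) {
  stopifnot(inherits(exposure, "exposure_table"))
  out <- data.frame(acq_index = exposure$acq_index,
                    angle_deg = round(exposure$angle, 1),
                    pre_dose_e_per_A2 = exposure$pre_dose,
                    post_dose_e_per_A2 = exposure$post_dose)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a scheme-order CSV back into an exposure table
#' @param path CSV written by [write_scheme_csv()].
#' @param name Scheme name to attach.
#' @return An `exposure_table`.
#' @export
read_scheme_csv <- function(path, name = "scheme") {
  x <- utils::read.csv(path)
  dose <- x$post_dose_e_per_A2[1] - x$pre_dose_e_per_A2[1]
  tab <- data.frame(acq_index = x$acq_index, angle = x$angle_deg,
                    pre_dose = x$pre_dose_e_per_A2,
                    post_dose = x$post_dose_e_per_A2)
  structure(tab, class = c("exposure_table", "data.frame"),
            scheme_name = name, scheme_kind = NA_character_,
            dose_per_projection = dose)
}

#' The seven benchmarked tilt-schemes
#'
#' Convenience constructor for the full benchmark set: continuous,
#' bidirectional and dose-symmetric schemes at a constant 3 degree increment,
#' dose-symmetric schemes with decreasing (initial step 3.7 degrees) and
#' increasing (2.5 degrees) increments, and the two Volta-phase-plate
#' dose-symmetric variants (identical angular order to the constant
#' dose-symmetric scheme; they differ only in CTF parameters downstream).
#'
#' @param max_angle Tilt limit in degrees (default 60).
#' @param step Constant increment in degrees (default 3).
#' @return Named list of `tilt_scheme` objects.
#' @export
benchmark_schemes <- function(max_angle = 60, step = 3) {
  pc <- increment_policy("constant", step, max_angle)
  list(
    continuous    = generate_continuous(pc, name = "continuous"),
    bidirectional = generate_bidirectional(pc, name = "bidirectional"),
    DS            = generate_dose_symmetric(pc, name = "DS"),
    DS_dec        = generate_ds_variable(increment_policy("decreasing", 3.7, max_angle),
                                         name = "DS dec"),
    DS_inc        = generate_ds_variable(increment_policy("increasing", 2.5, max_angle),
                                         name = "DS inc"),
    DS_VPP_foc    = generate_dose_symmetric(pc, name = "DS VPP foc"),
    DS_VPP_def    = generate_dose_symmetric(pc, name = "DS VPP def")
  )
}
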