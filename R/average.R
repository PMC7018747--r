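# Constrained local refinement and symmetrized half-map averaging — the
# desk-scale stand-in for the iterative subtomogram-averaging protocol.

#' Resample a subtomogram into the common (reference) frame
#'
#' Applies the inverse of the particle pose: `out(v) = sub(c + R (v - c) + s)`
#' where `R = euler_zyz(rot, tilt, psi)` maps particle-frame to world
#' coordinates and `s` is the residual world-frame shift of the particle
#' centre relative to the box centre, in voxels.
#'
#' @param sub Cubic 3D array.
#' @param rot,tilt,psi ZYZ Euler angles of the particle pose, degrees.
#' @param shift Length-3 world-frame residual shift in voxels.
#' @return Array of the same dimensions, in the common frame.
#' @export
align_to_common <- function(sub, rot, tilt, psi, shift = c(0, 0, 0)) {
  d <- dim(sub)
  ctr <- (d + 1) / 2
  R <- euler_zyz(rot, tilt, psi)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  p <- R %*% rbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
  array(trilinear(sub, p[1, ] + ctr[1] + shift[1],
                  p[2, ] + ctr[2] + shift[2],
                  p[3, ] + ctr[3] + shift[3]), d)
}

#' n-fold symmetrization about the z axis
#'
#' @param vol Cubic 3D array in the common frame (symmetry axis = z through
#'   the centre).
#' @param n Symmetry order (1 returns the input).
#' @return Symmetrized array.
#' @export
symmetrize_volume <- function(vol, n) {
  if (n <= 1L) return(vol)
  acc <- vol
  for (j in seq_len(n - 1L))
    acc <- acc + rotate_volume(vol, euler_zyz(360 * j / n, 0, 0))
  acc / n
}

# Masked Pearson correlation between two equally sized arrays.
masked_cc <- function(a, b, mask) {
  w <- as.numeric(mask)
  sw <- sum(w)
  am <- sum(w * a) / sw; bm <- sum(w * b) / sw
  num <- sum(w * (a - am) * (b - bm))
  den <- sqrt(sum(w * (a - am)^2) * sum(w * (b - bm)^2))
  if (den == 0) return(0)
  num / den
}

#' Constrained local refinement of a subtomogram against a reference
#'
#' Grid search over small ZYZ Euler perturbations combined with an FFT
#' cross-correlation translation search (with parabolic sub-voxel peak
#' interpolation), maximizing masked correlation. The search is local by
#' construction: rotations are bounded by `max_angle` per Euler angle and
#' shifts by `max_shift` voxels.
#'
#' @param sub Subtomogram (cubic array).
#' @param reference Reference volume of the same dimensions.
#' @param max_shift Maximum |shift| per axis in voxels.
#' @param max_angle Maximum |Euler perturbation| in degrees.
#' @param angle_step Rotation grid step in degrees.
#' @param mask Optional real-space mask (default: soft sphere of radius
#'   0.4 * box).
#' @return List with `rot`, `tilt`, `psi` (best Euler perturbation, degrees),
#'   `shift` (length-3 voxels), `score` (masked correlation at the optimum).
#' @export
refine_local <- function(sub, reference, max_shift = 2, max_angle = 0,
                         angle_step = 5, mask = NULL) {
  stopifnot(max_shift >= 0, max_angle >= 0)
  if (all(reference == 0)) stop("empty reference")
  d <- dim(sub)
  if (is.null(mask)) mask <- spherical_mask(d, 0.4 * d[1], soft_width = 2)
  angles <- if (max_angle > 0) seq(-max_angle, max_angle, by = angle_step)
            else 0
  best <- list(score = -Inf)
  Fs <- stats::fft(sub * mask)
  for (a1 in angles) for (a2 in angles) for (a3 in angles) {
    ref_r <- if (a1 == 0 && a2 == 0 && a3 == 0) reference
             else rotate_volume(reference, euler_zyz(a1, a2, a3))
    cc <- Re(stats::fft(Fs * Conj(stats::fft(ref_r * mask)),
                        inverse = TRUE)) / length(sub)
    # admissible integer shifts: wrap-around indices within max_shift
    sh <- round(max_shift)
    idx <- c(1:(sh + 1), if (sh > 0) (d[1] - sh + 1):d[1])
    ccw <- cc[idx, idx, idx]
    m <- which(ccw == max(ccw), arr.ind = TRUE)[1, ]
    to_shift <- function(i, n, k) { v <- c(0:k, if (k > 0) -(k:1)); v[i] }
    s <- c(to_shift(m[1], d[1], sh), to_shift(m[2], d[2], sh),
           to_shift(m[3], d[3], sh))
    sc <- max(ccw)
    if (sc > best$score)
      best <- list(rot = a1, tilt = a2, psi = a3, shift = s, score = sc,
                   cc = cc)
  }
  # parabolic sub-voxel refinement of the translation peak
  s <- best$shift
  for (ax in 1:3) {
    i0 <- (s + dim(sub)) %% dim(sub) + 1
    pick <- function(off) {
      j <- i0; j[ax] <- (s[ax] + off + dim(sub)[ax]) %% dim(sub)[ax] + 1
      best$cc[j[1], j[2], j[3]]
    }
    y0 <- pick(-1); y1 <- pick(0); y2 <- pick(1)
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y0 - y2) / den
      if (abs(delta) <= 0.5) s[ax] <- s[ax] + delta
    }
  }
  s <- pmin(pmax(s, -max_shift), max_shift)
  norm_score <- masked_cc(sub, align_to_common(reference,
    -best$psi, -best$tilt, -best$rot, -s), mask)
  list(rot = best$rot, tilt = best$tilt, psi = best$psi,
       shift = s, score = norm_score)
}

#' Symmetrized half-map averaging
#'
#' Particles are split into two disjoint halves (by particle-id parity by
#' default, fixed before any refinement), each half is averaged in the common
#' frame using the supplied poses, and each average is n-fold symmetrized
#' about the subunit z axis. Running the benchmark with C1, C2, C3 and C6
#' effectively scales the number of contributing asymmetric units by the
#' symmetry order.
#'
#' @param subs List of cubic subvolumes (named by particle id, as produced by
#'   [extract_subtomograms()]).
#' @param poses Data frame with columns `id`, `rot`, `tilt`, `psi` and
#'   optionally `sx`, `sy`, `sz` (world-frame residual shifts, voxels).
#' @param sym Symmetry order (1, 2, 3 or 6 for the C6 benchmark lattice).
#' @param split_rule `"parity"` (even/odd id) or `"interleave"` (alternating
#'   rows).
#' @return A `half_map_pair`: list with `half_a`, `half_b`, `n_a`, `n_b`,
#'   `sym`.
#' @export
average_symmetrized <- function(subs, poses, sym = 1L,
                                split_rule = c("parity", "interleave")) {
  split_rule <- match.arg(split_rule)
  stopifnot(length(subs) == nrow(poses))
  if (length(subs) < 2L) stop("need at least 2 particles to form half sets")
  if (!all(c("sx", "sy", "sz") %in% names(poses)))
    poses[c("sx", "sy", "sz")] <- 0
  half_of <- if (split_rule == "parity") poses$id %% 2L
             else (seq_len(nrow(poses)) - 1L) %% 2L
  d <- dim(subs[[1]])
  acc <- list(array(0, d), array(0, d))
  n <- c(0L, 0L)
  for (i in seq_along(subs)) {
    h <- half_of[i] + 1L
    acc[[h]] <- acc[[h]] + align_to_common(subs[[i]], poses$rot[i],
                                           poses$tilt[i], poses$psi[i],
                                           c(poses$sx[i], poses$sy[i],
                                             poses$sz[i]))
    n[h] <- n[h] + 1L
  }
  if (any(n == 0L)) stop("one half set is empty; need particles of both parities")
  structure(list(half_a = symmetrize_volume(acc[[1]] / n[1], sym),
                 half_b = symmetrize_volume(acc[[2]] / n[2], sym),
                 n_a = n[1], n_b = n[2], sym = as.integer(sym)),
            class = "half_map_pair")
}

#' @export
print.half_map_pair <- function(x, ...) {
  cat(sprintf("<half_map_pair> C%d, halves %d + %d particles, box %d\n",
              x$sym, x$n_a, x$n_b, dim(x$half_a)[1]))
  invisible(x)
}
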