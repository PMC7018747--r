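# Lattice particle bookkeeping: sphere-oversampled seeding, ellipsoid-fit
# cleaning, distance cleaning and VLP-level filtering, with per-particle
# removal reasons retained throughout.

#' Construct a particle set
#'
#' @param df Data frame with at least `id`, `x`, `y`, `z`; optional
#'   `tomogram_id`, `vlp_id`, Euler angles `rot`, `tilt`, `psi`, `score`.
#' @return A `particle_set` data frame with bookkeeping columns `removed`
#'   (logical) and `removed_by` (factor-like character, `NA` while retained).
#' @export
particle_set <- function(df) {
  stopifnot(all(c("id", "x", "y", "z") %in% names(df)))
  if (anyDuplicated(df$id)) stop("particle ids must be unique")
  for (col in c("tomogram_id", "vlp_id"))
    if (is.null(df[[col]])) df[[col]] <- 1L
  for (col in c("rot", "tilt", "psi", "score"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df$removed <- FALSE
  df$removed_by <- NA_character_
  structure(df, class = c("particle_set", "data.frame"))
}

#' Retained particles of a set
#' @param p A `particle_set`.
#' @return The subset with `removed == FALSE`.
#' @export
retained <- function(p) p[!p$removed, , drop = FALSE]

#' Seed oversampled particle positions on a sphere
#'
#' Emulates lattice seeding from a picked VLP centre: `n_positions`
#' quasi-uniform points on the sphere (typically ~10x the assumed subunit
#' count), each with the outward surface normal as its orientation axis and
#' a random in-plane twist.
#'
#' @param center Length-3 sphere centre (voxels).
#' @param radius Sphere radius (voxels).
#' @param n_positions Number of seeds.
#' @param seed Integer RNG seed.
#' @param vlp_id,tomogram_id Identifiers attached to every seed.
#' @return A `particle_set` with provenance `seeded`.
#' @export
oversample_sphere <- function(center, radius, n_positions, seed = 1,
                              vlp_id = 1L, tomogram_id = 1L) {
  stopifnot(n_positions > 0, radius > 0)
  dirs <- fibonacci_sphere(n_positions, seed = seed)
  pos <- sweep(dirs * radius, 2, center, "+")
  df <- data.frame(
    id = seq_len(n_positions),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    rot = atan2(dirs[, 2], dirs[, 1]) * 180 / pi,
    tilt = acos(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi,
    psi = stats::runif(n_positions, 0, 360),
    score = NA_real_, tomogram_id = tomogram_id, vlp_id = vlp_id)
  df$provenance <- "seeded"
  particle_set(df)
}

#' Least-squares ellipsoid fit to particle positions
#'
#' Fits the general quadric `x'Ax + b'x = 1` by linear least squares and
#' converts it to centre / semi-axes / orientation form, rejecting fits that
#' are not ellipsoids. Per-particle deviations are computed when the input
#' carries orientations: the radial residual is the signed distance along
#' the ray from the centre between the particle and the ellipsoid surface,
#' and the angular deviation is the angle between the particle's symmetry
#' axis and the local outward surface normal.
#'
#' @param particles A `particle_set`, or a matrix / data frame of positions
#'   (columns x, y, z). At least 9 non-degenerate points are required.
#' @param trim_sd Optional robustification: after an initial fit, points
#'   whose absolute radial residual exceeds `trim_sd` standard deviations
#'   are dropped and the ellipsoid refitted (two passes). Residuals and
#'   deviations are still reported for every input point. `NULL` (default)
#'   fits all points once — a plain algebraic least-squares fit, which a
#'   few strong radial outliers can inflate by several percent.
#' @return An `ellipsoid_model`: list with `center`, `semi_axes` (descending),
#'   `orientation` (columns = principal axes), `radial_residual`,
#'   `angular_deviation` (degrees, `NA` without orientations), `residual_sd`,
#'   `angular_sd`.
#' @export
fit_ellipsoid <- function(particles, trim_sd = NULL) {
  P <- if (is.matrix(particles)) particles
       else as.matrix(particles[, c("x", "y", "z")])
  if (nrow(P) < 9) stop("need at least 9 points to fit an ellipsoid")

  fit_quadric <- function(P) {
    x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
    D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z, x, y, z)
    v <- tryCatch(solve(crossprod(D), crossprod(D, rep(1, nrow(P)))),
                  error = function(e) stop("degenerate point configuration"))
    A <- matrix(c(v[1], v[4], v[5],
                  v[4], v[2], v[6],
                  v[5], v[6], v[3]), 3, 3)
    b <- v[7:9]
    center <- tryCatch(as.numeric(solve(-2 * A, b)),
                       error = function(e) stop("degenerate point configuration"))
    scale <- 1 + as.numeric(t(center) %*% A %*% center)
    if (abs(scale) < 1e-12) stop("degenerate point configuration")
    An <- A / scale
    eig <- eigen(An, symmetric = TRUE)
    if (any(eig$values <= 0)) stop("fitted quadric is not an ellipsoid")
    list(center = center, An = An, eig = eig)
  }
  radial_resid <- function(q, P) {
    rel <- sweep(P, 2, q$center)
    rr <- sqrt(rowSums(rel^2))
    u <- rel / rr
    rr - 1 / sqrt(rowSums((u %*% q$An) * u))
  }

  q <- fit_quadric(P)
  if (!is.null(trim_sd)) {
    for (pass in 1:2) {
      res <- radial_resid(q, P)
      keep <- abs(res) <= trim_sd * stats::sd(res)
      if (sum(keep) >= 9 && sum(keep) < nrow(P))
        q <- fit_quadric(P[keep, , drop = FALSE])
    }
  }
  semi <- 1 / sqrt(q$eig$values)    # ascending eigenvalues -> descending axes
  ord <- order(semi, decreasing = TRUE)
  model <- list(center = q$center, semi_axes = semi[ord],
                orientation = q$eig$vectors[, ord, drop = FALSE], An = q$An)

  rel <- sweep(P, 2, q$center)
  rr <- sqrt(rowSums(rel^2))
  u <- rel / rr
  r_surf <- 1 / sqrt(rowSums((u %*% q$An) * u))
  model$radial_residual <- rr - r_surf
  model$residual_sd <- stats::sd(model$radial_residual)

  has_orient <- is.data.frame(particles) &&
    all(c("rot", "tilt", "psi") %in% names(particles)) &&
    !anyNA(particles$tilt)
  if (has_orient) {
    axes <- t(vapply(seq_len(nrow(P)), function(i)
      as.numeric(euler_zyz(particles$rot[i], particles$tilt[i],
                           particles$psi[i]) %*% c(0, 0, 1)), numeric(3)))
    nrm <- (u %*% q$An)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    cosang <- pmin(1, pmax(-1, rowSums(axes * nrm)))
    model$angular_deviation <- acos(cosang) * 180 / pi
    model$angular_sd <- stats::sd(model$angular_deviation)
  } else {
    model$angular_deviation <- rep(NA_real_, nrow(P))
    model$angular_sd <- NA_real_
  }
  structure(model, class = "ellipsoid_model")
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat(sprintf("<ellipsoid_model> centre (%.1f, %.1f, %.1f), semi-axes %.2f/%.2f/%.2f, sd(r)=%.3f\n",
              x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$residual_sd))
  invisible(x)
}

#' Remove particles deviating from the fitted ellipsoid
#'
#' A particle is removed when its absolute radial residual exceeds one
#' standard deviation of the residuals OR its angular deviation exceeds one
#' standard deviation of the angular deviations — the two criteria are
#' applied independently. Removal reasons are recorded as
#' `ellipsoid_radius` or `ellipsoid_angle`.
#'
#' @param particles A `particle_set` (only currently retained particles are
#'   examined).
#' @param model An [fit_ellipsoid()] model fitted on these particles.
#' @param radius_sd_mult,angle_sd_mult Threshold multipliers (default 1).
#' @return The `particle_set` with removal flags updated.
#' @export
ellipsoid_clean <- function(particles, model, radius_sd_mult = 1,
                            angle_sd_mult = 1) {
  idx <- which(!particles$removed)
  stopifnot(length(idx) == length(model$radial_residual))
  bad_r <- abs(model$radial_residual) > radius_sd_mult * model$residual_sd
  bad_a <- if (anyNA(model$angular_deviation)) rep(FALSE, length(idx))
           else model$angular_deviation > angle_sd_mult * model$angular_sd
  particles$removed[idx[bad_r]] <- TRUE
  particles$removed_by[idx[bad_r]] <- "ellipsoid_radius"
  also <- bad_a & !bad_r
  particles$removed[idx[also]] <- TRUE
  particles$removed_by[idx[also]] <- "ellipsoid_angle"
  particles
}

#' Distance cleaning of duplicate particles
#'
#' Refined particles that converged to the same lattice position are
#' de-duplicated: particles are visited greedily in ascending angular
#' deviation (ties broken by id), each retained particle claims its
#' neighbourhood, and any later particle within `min_dist` of a retained one
#' is removed with reason `distance`.
#'
#' @param particles A `particle_set`.
#' @param min_dist Minimum allowed separation (voxels).
#' @param angular_deviation Per-retained-particle angular deviations from the
#'   ellipsoid fit, used as quality ranking; defaults to zeros (pure id
#'   order) when absent.
#' @return The `particle_set` with duplicates flagged.
#' @export
distance_clean <- function(particles, min_dist, angular_deviation = NULL) {
  stopifnot(min_dist > 0)
  idx <- which(!particles$removed)
  if (length(idx) <= 1L) return(particles)
  if (is.null(angular_deviation)) angular_deviation <- rep(0, length(idx))
  stopifnot(length(angular_deviation) == length(idx))
  ord <- idx[order(angular_deviation, particles$id[idx])]
  P <- as.matrix(particles[, c("x", "y", "z")])
  kept <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    p <- P[i, ]
    if (nrow(kept) > 0 &&
        min(sqrt(colSums((t(kept) - p)^2))) < min_dist) {
      particles$removed[i] <- TRUE
      particles$removed_by[i] <- "distance"
    } else {
      kept <- rbind(kept, p)
    }
  }
  particles
}

#' Discard whole VLPs with excessive ellipsoid-cleaning losses
#'
#' Every particle of a VLP is removed (reason `vlp_filter`) when more than
#' half of that VLP's particles were removed by the ellipsoid-based cleaning.
#'
#' @param particles A `particle_set` with `vlp_id` assigned.
#' @param max_removed_fraction Threshold on the ellipsoid-removed fraction
#'   (default 0.5).
#' @return The `particle_set` with failing VLPs flagged.
#' @export
vlp_filter <- function(particles, max_removed_fraction = 0.5) {
  for (v in unique(particles$vlp_id)) {
    in_vlp <- particles$vlp_id == v
    frac <- mean(particles$removed_by[in_vlp] %in%
                   c("ellipsoid_radius", "ellipsoid_angle"))
    if (frac > max_removed_fraction) {
      hit <- in_vlp & !particles$removed
      particles$removed[hit] <- TRUE
      particles$removed_by[hit] <- "vlp_filter"
    }
  }
  particles
}

#' Per-VLP cleaning report
#'
#' @param particles A `particle_set` after cleaning.
#' @return Data frame with per-VLP totals and removal-reason counts.
#' @export
cleaning_report <- function(particles) {
  do.call(rbind, lapply(split(particles, particles$vlp_id), function(p) {
    data.frame(vlp_id = p$vlp_id[1], n_total = nrow(p),
               n_retained = sum(!p$removed),
               n_ellipsoid_radius = sum(p$removed_by %in% "ellipsoid_radius"),
               n_ellipsoid_angle = sum(p$removed_by %in% "ellipsoid_angle"),
               n_distance = sum(p$removed_by %in% "distance"),
               n_vlp_filter = sum(p$removed_by %in% "vlp_filter"))
  }))
}

#' Write / read particle tables as CSV
#'
#' Coordinates are voxels of the unbinned tomogram; orientations are ZYZ
#' Euler angles in degrees.
#'
#' @param particles A `particle_set`.
#' @param path CSV path.
#' @return `path` (writer) or a `particle_set` (reader).
#' @export
write_particles <- function(particles, path) {
  utils::write.csv(as.data.frame(particles), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  df <- utils::read.csv(path)
  cls <- particle_set(df[, setdiff(names(df), c("removed", "removed_by"))])
  if (!is.null(df$removed)) cls$removed <- as.logical(df$removed)
  if (!is.null(df$removed_by)) cls$removed_by <- as.character(df$removed_by)
  cls
}
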