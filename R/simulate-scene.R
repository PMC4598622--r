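#' Ground-truth vesicle scenes
#'
#' Builds a noise-free 3D scene mimicking a rough-ER vesicle densely decorated
#' with membrane-bound two-part particles: a spherical membrane shell, bound
#' particles whose membrane foot sits centered in the shell (foot axis along
#' the local membrane normal, with optional angular jitter), optional unbound
#' particles at random poses in the lumen or exterior, and high-density gold
#' fiducial spheres.  Every pose, class label and position is recorded so each
#' downstream stage has a recovery target.
#'
#' @param spec \code{phantom_spec}.
#' @param n scene cube edge (voxels, even).
#' @param voxel_size A/voxel.
#' @param vesicle_radius_A vesicle radius (default 500 A, i.e. a 100-nm
#'   vesicle, the small end of the 100-300 nm range seen for rER vesicles).
#' @param membrane_thickness_A Gaussian membrane shell FWHM (default 40 A).
#' @param n_particles number of particles to place.
#' @param bound_fraction fraction of particles bound to the membrane.
#' @param n_fiducials number of 10-nm colloidal-gold-like fiducial spheres.
#' @param orient_jitter_deg s.d. of the tilt of bound particles away from the
#'   membrane normal (default 5).
#' @param membrane_amp,fiducial_amp densities of shell and fiducials relative
#'   to the particle's unit peak.
#' @param max_retries placement retries before giving up.
#' @param seed integer seed; the scene is deterministic given it.
#' @return object of class \code{ground_truth_scene}: list with
#'   \code{volume} (\code{density_map}), \code{particles} (data.frame: pos_x/y/z
#'   in centered A coordinates, Euler angles phi/theta/psi (ZXZ, deg), bound
#'   flag, one has_<name> column per sub-density), \code{fiducials}
#'   (data.frame of positions), \code{vesicle} (center/radius/thickness),
#'   \code{phantom} (the per-variant blob layout), \code{voxel_size}.
#' @export
build_scene <- function(spec, n = 72, voxel_size = 21,
                        vesicle_radius_A = 500,
                        membrane_thickness_A = 40,
                        n_particles = 20, bound_fraction = 1,
                        n_fiducials = 0, orient_jitter_deg = 5,
                        membrane_amp = 0.4, fiducial_amp = 5,
                        max_retries = 2000, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), n %% 2 == 0)
  d <- spec$particle_diameter_A
  half <- n / 2 * voxel_size
  r_center <- vesicle_radius_A + 0.35 * d   # particle-center radius when bound
  if (r_center + 0.55 * d > half)
    stop("vesicle with bound particles does not fit the box: need half-box > ",
         r_center + 0.55 * d, " A, have ", half, " A")
  set.seed(seed)
  n_bound <- round(n_particles * bound_fraction)
  blobs <- phantom_blobs(spec, seed)
  subnames <- vapply(spec$subdensities, `[[`, "", "name")
  occup <- vapply(spec$subdensities, `[[`, 0, "occupancy")

  positions <- matrix(NA_real_, 0, 3)
  rots <- list()
  bound <- logical(0)
  place_ok <- function(p) {
    nrow(positions) == 0 || all(sqrt(rowSums(sweep(positions, 2, p)^2)) >= d)
  }
  tries <- 0
  while (length(rots) < n_particles) {
    tries <- tries + 1
    if (tries > max_retries)
      stop("could not place ", n_particles, " non-overlapping particles after ",
           max_retries, " retries")
    if (length(rots) < n_bound) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      p <- r_center * u
      if (!place_ok(p)) next
      R <- align_z_to(u) %*% rot_z(stats::runif(1, 0, 360))
      if (orient_jitter_deg > 0) {
        jax <- stats::rnorm(3); jax <- jax / sqrt(sum(jax^2))
        R <- axis_angle_matrix(jax, stats::rnorm(1, 0, orient_jitter_deg)) %*% R
      }
      is_b <- TRUE
    } else {
      # unbound: random pose in the lumen (clear of the membrane)
      r_max <- vesicle_radius_A - membrane_thickness_A - 0.55 * d
      if (r_max < 0.55 * d)
        stop("lumen too small for unbound particles")
      p <- stats::runif(3, -1, 1) * r_max
      if (sqrt(sum(p^2)) > r_max || !place_ok(p)) next
      R <- euler_to_matrix(stats::runif(1, 0, 360),
                           acos(stats::runif(1, -1, 1)) * 180 / pi,
                           stats::runif(1, 0, 360))
      is_b <- FALSE
    }
    positions <- rbind(positions, p)
    rots[[length(rots) + 1]] <- R
    bound <- c(bound, is_b)
  }

  has_sub <- matrix(FALSE, n_particles, length(subnames),
                    dimnames = list(NULL, subnames))
  for (j in seq_along(subnames))
    has_sub[, j] <- stats::runif(n_particles) < occup[j]

  # fiducials: 10-nm gold spheres anywhere clear of particles and shell
  fid <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(fid) < n_fiducials) {
    tries <- tries + 1
    if (tries > max_retries) stop("could not place fiducials")
    p <- stats::runif(3, -1, 1) * (half - 100)
    dist_part <- if (nrow(positions)) min(sqrt(rowSums(sweep(positions, 2, p)^2))) else Inf
    dist_shell <- abs(sqrt(sum(p^2)) - vesicle_radius_A)
    if (dist_part > 0.7 * d && dist_shell > 100 &&
        (nrow(fid) == 0 || min(sqrt(rowSums(sweep(fid, 2, p)^2))) > 150))
      fid <- rbind(fid, p)
  }

  # render: membrane shell + particles + fiducials
  idx <- voxel_index_grids(n)
  c0 <- vol_center(n)
  r_vox <- sqrt((idx$x - c0)^2 + (idx$y - c0)^2 + (idx$z - c0)^2) * voxel_size
  sig_m <- membrane_thickness_A / 2.355
  grid <- array(membrane_amp * exp(-((r_vox - vesicle_radius_A)^2) / (2 * sig_m^2)),
                dim = c(n, n, n))
  all_blobs <- list()
  for (i in seq_len(n_particles)) {
    present <- c("body", "foot_mobile", "foot_static", subnames[has_sub[i, ]])
    for (b in Filter(function(b) b$domain %in% present, blobs)) {
      b$pos <- positions[i, ] + as.numeric(rots[[i]] %*% b$pos)
      all_blobs[[length(all_blobs) + 1]] <- b
    }
  }
  for (i in seq_len(nrow(fid)))
    all_blobs[[length(all_blobs) + 1]] <-
      list(pos = fid[i, ], sigma = 50 / 2.355, amp = fiducial_amp,
           domain = "fiducial")
  grid <- grid + render_blobs(all_blobs, n, voxel_size)

  eul <- t(vapply(rots, matrix_to_euler, numeric(3)))
  particles <- data.frame(pos_x = positions[, 1], pos_y = positions[, 2],
                          pos_z = positions[, 3], phi = eul[, 1],
                          theta = eul[, 2], psi = eul[, 3], bound = bound)
  for (j in seq_along(subnames))
    particles[[paste0("has_", subnames[j])]] <- has_sub[, j]
  structure(list(volume = density_map(grid, voxel_size),
                 particles = particles,
                 fiducials = as.data.frame(stats::setNames(
                   as.data.frame(fid), c("pos_x", "pos_y", "pos_z"))),
                 vesicle = list(center = c(0, 0, 0),
                                radius_A = vesicle_radius_A,
                                thickness_A = membrane_thickness_A),
                 phantom = list(spec = spec, blobs = blobs, seed = seed),
                 voxel_size = voxel_size),
            class = "ground_truth_scene")
}

# rotation taking the +z axis to unit vector u
align_z_to <- function(u) {
  z <- c(0, 0, 1)
  c_ <- sum(z * u)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(rot_x(180))
  ax <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
          z[1] * u[2] - z[2] * u[1])
  axis_angle_matrix(ax, acos(c_) * 180 / pi)
}

#' Spherical membrane shell density
#'
#' Gaussian-profile shell used both by \code{\link{build_scene}} for the
#' vesicle and for building membrane-aware matching templates: for a particle
#' bound to a vesicle the local membrane is a spherical cap, and including it
#' in the template anchors both the position and the up-down orientation of
#' the match (a bare particle at low resolution is nearly symmetric).
#'
#' @param n cubic box size (voxels).
#' @param voxel_size Angstrom per voxel.
#' @param radius_A shell radius.
#' @param center_A shell center in Angstrom relative to the box center
#'   (length 3).
#' @param thickness_A full width at half maximum of the shell profile
#'   (default 40).
#' @param amp peak density of the shell (default 0.4).
#' @return \code{density_map}.
#' @export
render_membrane_shell <- function(n, voxel_size, radius_A,
                                  center_A = c(0, 0, 0),
                                  thickness_A = 40, amp = 0.4) {
  if (radius_A <= 0) stop("radius_A must be positive")
  idx <- voxel_index_grids(n)
  c0 <- vol_center(n)
  r <- sqrt(((idx$x - c0) * voxel_size - center_A[1])^2 +
            ((idx$y - c0) * voxel_size - center_A[2])^2 +
            ((idx$z - c0) * voxel_size - center_A[3])^2)
  sig <- thickness_A / 2.355
  density_map(array(amp * exp(-(r - radius_A)^2 / (2 * sig^2)), rep(n, 3)),
              voxel_size)
}
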