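#' Wedge-aware subtomogram alignment and averaging
#'
#' Pose convention: a particle's pose (R, t) maps the reference onto the
#' subtomogram, \code{subtomo ~ transform(reference; R, t)} with rotation
#' about the volume center and translation in Angstrom.  Averaging therefore
#' applies the inverse pose to each subtomogram.  Each subtomogram carries the
#' \code{wedge_spec} of the tilt range it was reconstructed from; in any
#' rotated frame its Fourier support is the wedge mask evaluated at rotated
#' frequencies (computed analytically, never interpolated).
#'
#' @name average
NULL

#' Missing-wedge mask of a rotated volume (analytic)
#'
#' If a volume with wedge support M is resampled as \code{y(x) = s(R(x-c)+c)},
#' its support is \code{M(R k)}; this evaluates that mask exactly on the
#' frequency grid.
#'
#' @param n cube edge.
#' @param wedge \code{wedge_spec}.
#' @param R 3x3 rotation applied to the volume contents' coordinates (use
#'   \code{t(pose$rotation)} for a particle rotated back to the reference
#'   frame).
#' @return 0/1 array in unshifted FFT order.
#' @export
rotated_wedge_mask <- function(n, wedge, R) {
  g <- freq_grids(n)
  kx <- R[1, 1] * g$kx + R[1, 2] * g$ky + R[1, 3] * g$kz
  ky <- R[2, 1] * g$kx + R[2, 2] * g$ky + R[2, 3] * g$kz
  kz <- R[3, 1] * g$kx + R[3, 2] * g$ky + R[3, 3] * g$kz
  m <- wedge_condition(kx, ky, kz, wedge)
  m[1] <- 1
  array(m, dim = c(n, n, n))
}

#' Constrained cross-correlation of two wedge-limited volumes
#'
#' Both volumes are soft-masked in real space; the correlation is computed
#' only over the Fourier region sampled by both wedges and inside the band,
#' normalized by each volume's energy restricted to the same region.
#' Symmetric in its arguments.
#'
#' @param a,b \code{density_map}s (same shape and voxel size).
#' @param wedge_a,wedge_b \code{wedge_spec} of each volume (NULL = fully
#'   sampled).
#' @param mask optional real-space \code{soft_mask}/array.
#' @param band optional length-2 c(low_res_A, high_res_A) resolution band.
#' @return correlation in [-1, 1].
#' @export
constrained_cc <- function(a, b, wedge_a = NULL, wedge_b = NULL, mask = NULL,
                           band = NULL) {
  ga <- as_grid(a); gb <- as_grid(b)
  stopifnot(identical(dim(ga), dim(gb)))
  n <- check_cubic(ga, "constrained_cc input")
  vs <- if (inherits(a, "density_map")) a$voxel_size else 1
  if (!is.null(mask)) {
    m <- as_mask_grid(mask)
    ga <- ga * m; gb <- gb * m
  }
  region <- rep(1, n^3)
  if (!is.null(wedge_a)) region <- region * as.vector(make_wedge_mask(n, wedge_a))
  if (!is.null(wedge_b)) region <- region * as.vector(make_wedge_mask(n, wedge_b))
  if (!is.null(band))
    region <- region * as.vector(band_mask(n, vs, band[1], band[2]) > 0.5)
  region[1] <- 0                            # exclude DC (mean term)
  if (sum(region) == 0) stop("empty Fourier overlap region")
  Fa <- as.vector(stats::fft(ga))[region > 0]
  Fb <- as.vector(stats::fft(gb))[region > 0]
  num <- Re(sum(Fa * Conj(Fb)))
  den <- sqrt(sum(Mod(Fa)^2) * sum(Mod(Fb)^2))
  if (den == 0) return(0)
  max(-1, min(1, num / den))
}

# 3D correlation peak with subpixel parabola fit, restricted to shifts within
# max_shift_vox of zero; cc is an unshifted-FFT-order correlation volume
cc_peak3d <- function(cc, max_shift_vox = NULL) {
  n <- dim(cc)[1]
  if (!is.null(max_shift_vox)) {
    f <- fft_freq(n) * n                    # signed voxel shifts
    allowed <- abs(f) <= max_shift_vox
    cc[!allowed, , ] <- -Inf
    cc[, !allowed, ] <- -Inf
    cc[, , !allowed] <- -Inf
  }
  i <- which.max(cc)
  pk <- as.integer(arrayInd(i, dim(cc)))
  sub <- numeric(3)
  val <- cc[i]
  for (ax in 1:3) {
    im <- ((pk[ax] - 2) %% n) + 1
    ip <- (pk[ax] %% n) + 1
    sel <- function(j) { q <- pk; q[ax] <- j; cc[q[1], q[2], q[3]] }
    y1 <- sel(im); y2 <- sel(pk[ax]); y3 <- sel(ip)
    if (!is.finite(y1) || !is.finite(y3)) next
    den <- y1 - 2 * y2 + y3
    # only the location is interpolated: a parabola-extrapolated peak VALUE
    # is a quadratic form of three noisy samples, and in the nearly flat
    # correlation landscapes typical of low-SNR subtomograms the added
    # variance scrambles orientation rankings far more than the half-voxel
    # sampling bias it would remove
    if (abs(den) > 1e-12)
      sub[ax] <- max(-0.5, min(0.5, 0.5 * (y1 - y3) / den))
  }
  s <- pk - 1
  s[s > n / 2] <- s[s > n / 2] - n
  list(shift_vox = s + sub, value = val)
}

# Exact band-limited evaluation of a cross-correlation at a fractional shift:
# given the cross-spectrum X (same unnormalized convention as
# Re(fft(X, inverse = TRUE))), returns sum_k X_k exp(2 pi i k.s / n) over
# signed frequencies k.  Unlike a parabola fit through noisy samples, this is
# the true off-grid value of the same band-limited field, so scores built
# from it vary smoothly as the peak drifts between voxels.
cc_value_fractional <- function(X, shift_vox, n) {
  f <- fft_freq(n) * n                        # signed integer frequencies
  ph <- function(s) exp(2i * pi * f * s / n)
  t1 <- ph(shift_vox[1]) %*% matrix(X, n, n * n)
  t2 <- ph(shift_vox[2]) %*% matrix(t1, n, n)
  Re(sum(t2 * ph(shift_vox[3])))
}

# local rotation set: identity + cone directions within range_deg at spacing
# step_deg, each with in-plane twists at the same spacing
local_rotation_set <- function(step_deg, range_deg) {
  twists <- unique(c(0, seq(step_deg, range_deg, by = step_deg),
                     -seq(step_deg, range_deg, by = step_deg)))
  dirs <- list(c(0, 0, 1))
  for (alpha in seq(step_deg, range_deg, by = step_deg)) {
    n_ring <- max(1, ceiling(2 * pi * sin(alpha * pi / 180) /
                               (step_deg * pi / 180)))
    for (j in seq_len(n_ring)) {
      az <- 2 * pi * (j - 1) / n_ring
      a <- alpha * pi / 180
      dirs[[length(dirs) + 1]] <- c(sin(a) * cos(az), sin(a) * sin(az), cos(a))
    }
  }
  rots <- list()
  for (d in dirs) for (tw in twists)
    rots[[length(rots) + 1]] <- align_z_to(d) %*% rot_z(tw)
  rots
}


# rotate a volume by sampling from its 2x Fourier-upsampled grid: same cost
# as plain trilinear at the output resolution, ~4x less interpolation bias
rotate_via_oversampled <- function(fine, n, factor, R, t_vox = c(0, 0, 0)) {
  c0 <- vol_center(n)
  idx <- voxel_index_grids(n)
  Rinv <- t(R)
  xs <- idx$x - c0 - t_vox[1]
  ys <- idx$y - c0 - t_vox[2]
  zs <- idx$z - c0 - t_vox[3]
  sx <- (Rinv[1, 1] * xs + Rinv[1, 2] * ys + Rinv[1, 3] * zs + c0 - 1) * factor + 1
  sy <- (Rinv[2, 1] * xs + Rinv[2, 2] * ys + Rinv[2, 3] * zs + c0 - 1) * factor + 1
  sz <- (Rinv[3, 1] * xs + Rinv[3, 2] * ys + Rinv[3, 3] * zs + c0 - 1) * factor + 1
  array(trilinear_sample(fine, sx, sy, sz, fill = mean(fine)), rep(n, 3))
}

# Precompute the reference side of the fast alignment path: rotated masked
# references and their FFTs for a shared local rotation set.
prepare_reference_set <- function(reference, rot_set, mask = NULL) {
  ref <- as_grid(reference)
  n <- dim(ref)[1]
  if (!is.null(mask)) ref <- ref * as_mask_grid(mask)
  ref <- ref - mean(ref)
  F <- vector("list", length(rot_set))
  P <- matrix(0, n^3, length(rot_set))      # power spectra for normalization
  fine <- fourier_upsample(ref, 2)
  for (j in seq_along(rot_set)) {
    rr <- rotate_via_oversampled(fine, n, 2, rot_set[[j]])
    Fj <- stats::fft(rr)
    F[[j]] <- Fj
    P[, j] <- as.vector(Mod(Fj)^2)
  }
  list(F = F, P = P, n = n)
}

#' Local alignment of one subtomogram against a reference
#'
#' Exhaustive local orientation search on a cone-and-twist grid at
#' \code{angular_step} within \code{angular_range} of the current pose; for
#' each orientation the translation is found as the constrained-CC peak via
#' FFT with subpixel parabola refinement.  Never returns a pose scoring below
#' the input pose.
#'
#' @param subtomo \code{density_map}.
#' @param wedge \code{wedge_spec} of the subtomogram.
#' @param reference \code{density_map} on the same grid.
#' @param pose current \code{rigid_transform} estimate.
#' @param angular_step,angular_range degrees.
#' @param band c(low_res_A, high_res_A) alignment bandpass (NULL = none).
#' @param mask real-space alignment mask in the reference frame.
#' @param max_shift_A translation search bound (default a quarter box).
#' @return list(pose, score).
#' @export
align_subtomogram <- function(subtomo, wedge, reference, pose = rigid_transform(),
                              angular_step = 10, angular_range = 20,
                              band = NULL, mask = NULL, max_shift_A = NULL,
                              polish = TRUE) {
  rot_set <- local_rotation_set(angular_step, angular_range)
  prep <- prepare_reference_set(reference, rot_set, mask)
  res <- align_one(subtomo, wedge, pose, rot_set, prep, band, mask, max_shift_A)
  if (polish)
    res <- refine_pose_local(subtomo, wedge, reference, res$pose, band, mask,
                             max_shift_A, scale_deg = angular_step / 2)
  # score the input pose under the same objective; fall back if better
  in_score <- score_pose(subtomo, wedge, reference, pose, band, mask)
  if (in_score > res$score) return(list(pose = pose, score = in_score))
  res
}

# Continuous local pose refinement in the particle frame: the reference is
# rotated to each trial orientation and compared against the raw subtomogram
# under its axis-aligned wedge mask, so the noisy data is never interpolated.
# Nelder-Mead over an axis-angle offset (degrees) composed onto the current
# rotation; translation from the CC peak at each trial rotation.
refine_pose_local <- function(subtomo, wedge, reference, pose, band, mask,
                              max_shift_A = NULL, scale_deg = 3, maxit = 60,
                              shell_weights = NULL) {
  g <- as_grid(subtomo)
  vs <- if (inherits(subtomo, "density_map")) subtomo$voxel_size else 1
  n <- dim(g)[1]
  if (is.null(max_shift_A)) max_shift_A <- n / 4 * vs
  ref <- as_grid(reference)
  if (!is.null(mask)) ref <- ref * as_mask_grid(mask)
  ref <- ref - mean(ref)
  fine <- fourier_upsample(ref, 2)
  R0 <- pose$rotation
  subm <- g
  if (!is.null(mask)) subm <- subm * as_mask_grid(mask)
  subm <- subm - mean(subm)
  W <- as.vector(make_wedge_mask(n, wedge))
  if (!is.null(band)) W <- W * as.vector(band_mask(n, vs, band[1], band[2]) > 0.5)
  if (!is.null(shell_weights)) W <- W * as.vector(shell_weights)
  W[1] <- 0
  Fs <- stats::fft(subm) * W
  ea <- sum(Mod(Fs)^2)
  eval_rot <- function(p) {
    r <- if (sqrt(sum(p^2)) < 1e-9) diag(3)
         else axis_angle_matrix(p, sqrt(sum(p^2)))
    Rc <- R0 %*% r
    rr <- rotate_via_oversampled(fine, n, 2, Rc)
    Fb <- stats::fft(rr)
    eb <- sum(Mod(Fb)^2 * W)
    if (eb <= 0) return(list(score = -1, Rc = Rc, shift = c(0, 0, 0)))
    X <- Fs * Conj(Fb)
    cc <- Re(stats::fft(X, inverse = TRUE))
    pk <- cc_peak3d(array(cc, rep(n, 3)), max_shift_vox = max_shift_A / vs)
    # score from the exact band-limited CC at the fractional peak: the
    # integer-peak value jumps as the optimum drifts between voxels, which
    # puts half-voxel-scale plateaus into the rotational score landscape
    val <- cc_value_fractional(X, pk$shift_vox, n)
    sc <- val / sqrt(ea * eb)
    if (!is.finite(sc)) sc <- -1
    list(score = sc, Rc = Rc, shift = pk$shift_vox)
  }
  # optim's Nelder-Mead builds its initial simplex at 0.1 * parscale, so
  # parscale is set to 10x the intended initial angular step
  if (ea <= 0)                              # no signal in the scored band
    return(list(pose = pose, score = -1))
  opt <- stats::optim(c(0, 0, 0), function(p) {
    if (!all(is.finite(p))) return(1)
    -eval_rot(p)$score
  }, method = "Nelder-Mead",
     control = list(maxit = maxit, reltol = 1e-7,
                    parscale = rep(10 * scale_deg, 3)))
  if (!all(is.finite(opt$par))) opt$par <- c(0, 0, 0)
  fin <- eval_rot(opt$par)
  list(pose = rigid_transform(fin$Rc, fin$shift * vs),
       score = max(-1, min(1, fin$score)))
}

# fast path shared across particles: subtomo rotated to reference frame once,
# correlated against precomputed rotated references
align_one <- function(subtomo, wedge, pose, rot_set, prep, band, mask,
                      max_shift_A = NULL) {
  g <- as_grid(subtomo)
  n <- prep$n
  vs <- if (inherits(subtomo, "density_map")) subtomo$voxel_size else 1
  if (is.null(max_shift_A)) max_shift_A <- n / 4 * vs
  R0 <- pose$rotation
  sub0 <- rotate_volume(density_map(g, vs), rigid_transform(t(R0)))$grid
  if (!is.null(mask)) sub0 <- sub0 * as_mask_grid(mask)
  sub0 <- sub0 - mean(sub0)
  # Fourier region: subtomo wedge rotated into the reference frame, plus band
  W <- as.vector(rotated_wedge_mask(n, wedge, R0))
  if (!is.null(band)) W <- W * as.vector(band_mask(n, vs, band[1], band[2]) > 0.5)
  W[1] <- 0
  Fa <- stats::fft(sub0) * W
  ea <- sum(Mod(Fa)^2)
  eb <- as.numeric(W %*% prep$P)            # reference energies in region
  best <- list(score = -Inf)
  for (j in seq_along(rot_set)) {
    if (eb[j] <= 0) next
    cc <- Re(stats::fft(Fa * Conj(prep$F[[j]]), inverse = TRUE))
    pk <- cc_peak3d(array(cc, rep(n, 3)), max_shift_vox = max_shift_A / vs)
    score <- pk$value / sqrt(ea * eb[j])
    if (score > best$score) best <- list(score = score, j = j, shift = pk$shift_vox)
  }
  # shift s satisfies sub0(x) ~ ref_j(x - s): pose R = R0 r_j, t = R0 s
  r_j <- rot_set[[best$j]]
  t_new <- as.numeric(R0 %*% (best$shift * vs))
  list(pose = rigid_transform(R0 %*% r_j, t_new),
       score = max(-1, min(1, best$score)))
}

# constrained-CC score of a subtomogram at a fixed pose
score_pose <- function(subtomo, wedge, reference, pose, band, mask) {
  g <- as_grid(subtomo)
  vs <- if (inherits(subtomo, "density_map")) subtomo$voxel_size else 1
  al <- rotate_volume(density_map(g, vs), invert_transform(pose))$grid
  n <- dim(al)[1]
  W <- rotated_wedge_mask(n, wedge, pose$rotation)
  ref <- as_grid(reference)
  if (!is.null(mask)) {
    m <- as_mask_grid(mask)
    al <- al * m; ref <- ref * m
  }
  al <- al - mean(al); ref <- ref - mean(ref)
  reg <- as.vector(W)
  if (!is.null(band)) reg <- reg * as.vector(band_mask(n, vs, band[1], band[2]) > 0.5)
  reg[1] <- 0
  Fa <- as.vector(stats::fft(al))[reg > 0]
  Fb <- as.vector(stats::fft(ref))[reg > 0]
  den <- sqrt(sum(Mod(Fa)^2) * sum(Mod(Fb)^2))
  if (den == 0) return(0)
  max(-1, min(1, Re(sum(Fa * Conj(Fb))) / den))
}

#' Particle record table constructor
#'
#' The per-particle bookkeeping currency of alignment, classification and
#' averaging: pose (ZXZ Euler degrees + translation in A), wedge bounds,
#' half-set membership, class label and score.
#'
#' @param n number of particles.
#' @param wedge \code{wedge_spec} shared by all particles (per-row bounds can
#'   be edited afterwards).
#' @return data.frame with columns particle, phi, theta, psi, tx, ty, tz,
#'   wedge_min, wedge_max, half_set, class_label, score.
#' @export
particle_records <- function(n, wedge = wedge_spec(-60, 60)) {
  data.frame(particle = seq_len(n), phi = 0, theta = 0, psi = 0,
             tx = 0, ty = 0, tz = 0,
             wedge_min = wedge$tilt_min, wedge_max = wedge$tilt_max,
             half_set = NA_integer_, class_label = NA_integer_, score = NA_real_)
}

record_pose <- function(records, i) {
  rigid_transform(euler_to_matrix(records$phi[i], records$theta[i],
                                  records$psi[i]),
                  c(records$tx[i], records$ty[i], records$tz[i]))
}

set_record_pose <- function(records, i, pose) {
  e <- matrix_to_euler(pose$rotation)
  records$phi[i] <- e[1]; records$theta[i] <- e[2]; records$psi[i] <- e[3]
  records$tx[i] <- pose$translation[1]
  records$ty[i] <- pose$translation[2]
  records$tz[i] <- pose$translation[3]
  records
}

#' Read/write particle tables as TSV
#' @param records particle data.frame.
#' @param path file path.
#' @return \code{read_particles} returns the data.frame.
#' @export
write_particles <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Wedge-compensated average of aligned subtomograms
#'
#' Each subtomogram is rotated/shifted to the reference frame (inverse pose),
#' its Fourier transform accumulated, and the sum divided voxelwise by the sum
#' of rotated wedge masks, floored at \code{eps_frac * N} to bound noise
#' amplification in never-sampled regions; the output is mean-free.
#'
#' @param subtomos list of \code{density_map}s (or 3D arrays).
#' @param records particle table (see \code{\link{particle_records}}); poses
#'   and wedge bounds are taken per row.
#' @param eps_frac wedge-sum floor as a fraction of the particle count.
#' @return \code{density_map} average.
#' @export
average_subtomograms <- function(subtomos, records, eps_frac = 1e-3) {
  N <- nrow(records)
  if (N < 1) stop("need at least one particle record")
  g1 <- as_grid(subtomos[[records$particle[1]]])
  n <- dim(g1)[1]
  vs <- if (inherits(subtomos[[records$particle[1]]], "density_map"))
    subtomos[[records$particle[1]]]$voxel_size else 1
  Fsum <- array(0 + 0i, rep(n, 3))
  Wsum <- array(0, rep(n, 3))
  for (r in seq_len(N)) {
    i <- records$particle[r]
    pose <- record_pose(records, r)
    # rotate the subtomogram to the reference frame through a 2x Fourier
    # oversampled copy: plain trilinear resampling attenuates exactly the
    # high-frequency shells the average is supposed to recover
    inv <- invert_transform(pose)
    fine <- fourier_upsample(as_grid(subtomos[[i]]), 2)
    al <- rotate_via_oversampled(fine, n, 2, inv$rotation,
                                 inv$translation / vs)
    W <- rotated_wedge_mask(n, wedge_spec(records$wedge_min[r],
                                          records$wedge_max[r]),
                            pose$rotation)
    Fsum <- Fsum + stats::fft(al) * W
    Wsum <- Wsum + W
  }
  avg <- Re(stats::fft(Fsum / pmax(Wsum, eps_frac * N), inverse = TRUE)) / n^3
  avg <- avg - mean(avg)
  density_map(avg, vs)
}

#' Iterative subtomogram alignment with resolution-adaptive sampling
#'
#' Conventional mode aligns all particles against a single reference each
#' iteration, measuring resolution as FSC = 0.5 between averages of two
#' random halves.  Gold-standard mode fixes a seeded random half-set split at
#' the start and aligns each half only against its own average, measuring
#' resolution as FSC = 0.143 between the half-maps.  The angular step for
#' iteration i is \code{max(1, atan(resolution_{i-1} / particle_diameter))}
#' degrees and the alignment low-pass is set to the previous resolution.
#' Iteration stops at \code{max_iterations}, when resolution improves by less
#' than one Fourier shell, or (with reversion) when it worsens.
#'
#' @param subtomos list of \code{density_map}s.
#' @param records particle table; in gold-standard mode half_set is assigned
#'   once from \code{seed} if unset.
#' @param reference initial reference \code{density_map}, low-pass filtered by
#'   the caller (the classic choice: an external map filtered to 20 A).
#' @param schedule list: max_iterations (default 6), mask, initial_res_A
#'   (default 2 * the reference low-pass, 40), range_factor (search range =
#'   range_factor * step, default 2), band_low_A (low-resolution alignment
#'   cutoff, default Inf), polish_passes (default 2), polish_scale (continuous
#'   polish search scale as a fraction of the angular step, default 0.5),
#'   step_decay (geometric angular-step decay floor across iterations, default
#'   1 = purely resolution-adaptive), fsc_mask.
#' @param mode "conventional" or "gold_standard".
#' @param particle_diameter_A particle diameter for the sampling rule.
#' @param seed integer; controls the half splits.
#' @return list(average, half_averages, history data.frame(iteration,
#'   resolution_A, angular_step_deg, mean_score), records).
#' @export
refine_iteratively <- function(subtomos, records, reference,
                               schedule = list(), mode = c("conventional",
                                                           "gold_standard"),
                               particle_diameter_A, seed = 1) {
  mode <- match.arg(mode)
  max_it <- schedule$max_iterations %||% 6
  mask <- schedule$mask
  range_factor <- schedule$range_factor %||% 2
  res_prev <- schedule$initial_res_A %||% 40
  band_low <- schedule$band_low_A %||% Inf
  vs <- subtomos[[records$particle[1]]]$voxel_size
  n <- dim(as_grid(subtomos[[records$particle[1]]]))[1]
  shell_A <- function(res) {
    # resolution of the next finer Fourier shell
    1 / (1 / res + 1 / (n * vs))
  }
  set.seed(seed)
  if (mode == "gold_standard" && all(is.na(records$half_set))) {
    records$half_set <- sample(rep(0:1, length.out = nrow(records)))
  }
  if (mode == "gold_standard" &&
      min(table(factor(records$half_set, levels = 0:1))) < 2)
    stop("gold-standard mode needs at least 2 particles per half")
  step_decay <- schedule$step_decay %||% 1
  history <- data.frame()
  refs <- if (mode == "gold_standard") list(`0` = reference, `1` = reference)
          else list(all = reference)
  best_state <- NULL
  step <- Inf
  for (it in seq_len(max_it)) {
    # angular step from the current resolution (sampling rule), with an
    # optional geometric decay floor: when the resolution estimate is pinned
    # at the box Nyquist the adaptive rule would never refine the grid
    step <- max(1, min(atan(res_prev / particle_diameter_A) * 180 / pi,
                       step * step_decay))
    band <- c(band_low, max(res_prev, 2 * vs))
    rot_set <- local_rotation_set(step, range_factor * step)
    scores <- numeric(nrow(records))
    for (half in names(refs)) {
      rows <- if (mode == "gold_standard")
        which(records$half_set == as.integer(half)) else seq_len(nrow(records))
      prep <- prepare_reference_set(refs[[half]], rot_set, mask)
      for (r in rows) {
        res_al <- align_one(subtomos[[records$particle[r]]],
                            wedge_spec(records$wedge_min[r], records$wedge_max[r]),
                            record_pose(records, r), rot_set, prep,
                            band, mask)
        records <- set_record_pose(records, r, res_al$pose)
        scores[r] <- res_al$score
      }
    }
    records$score <- scores
    # averages and resolution
    if (mode == "gold_standard") {
      h0 <- average_subtomograms(subtomos, records[records$half_set == 0, ])
      h1 <- average_subtomograms(subtomos, records[records$half_set == 1, ])
      refs <- list(`0` = h0, `1` = h1)
      thr <- 0.143
    } else {
      split <- sample(rep(0:1, length.out = nrow(records)))
      h0 <- if (any(split == 0))
        average_subtomograms(subtomos, records[split == 0, ]) else NULL
      h1 <- if (any(split == 1))
        average_subtomograms(subtomos, records[split == 1, ]) else NULL
      refs <- list(all = average_subtomograms(subtomos, records))
      thr <- 0.5
    }
    res_now <- if (is.null(h0) || is.null(h1)) {
      # too few particles to split: resolution unmeasurable, report the
      # Nyquist bound
      2 * vs
    } else {
      fsc <- fsc_curve(h0, h1, mask = schedule$fsc_mask)
      resolution_at_threshold(fsc, thr, vs)$resolution_A
    }
    if (!is.null(best_state) && res_now > best_state$resolution) {
      # worsened: revert to the best state and stop
      records <- best_state$records
      refs <- best_state$refs
      break
    }
    history <- rbind(history, data.frame(iteration = it,
                                         resolution_A = res_now,
                                         angular_step_deg = step,
                                         mean_score = mean(scores)))
    best_state <- list(records = records, refs = refs, resolution = res_now)
    improved <- res_prev - res_now
    res_prev <- res_now
    if (it > 1 && improved < (res_now - shell_A(res_now))) break
  }
  # Continuous polish passes: each particle's pose is refined against its
  # (half-set) average with a continuous local orientation search, the
  # averages are rebuilt, and the pass repeated.  Half-set independence is
  # preserved in gold-standard mode.
  n_pass <- schedule$polish_passes %||% 2
  polish_scale <- schedule$polish_scale %||% 0.5
  for (pass in seq_len(n_pass)) {
    step <- max(1, atan(res_prev / particle_diameter_A) * 180 / pi)
    band <- c(band_low, max(res_prev, 2 * vs))
    for (half in names(refs)) {
      rows <- if (mode == "gold_standard")
        which(records$half_set == as.integer(half)) else seq_len(nrow(records))
      ref_use <- if (mode == "gold_standard") refs[[half]] else refs$all
      for (r in rows) {
        p0 <- record_pose(records, r)
        pol <- refine_pose_local(subtomos[[records$particle[r]]],
                                 wedge_spec(records$wedge_min[r],
                                            records$wedge_max[r]),
                                 ref_use, p0, band, mask,
                                 scale_deg = polish_scale * step)
        if (!all(is.finite(pol$pose$rotation)) ||
            !all(is.finite(pol$pose$translation))) next
        # the local search starts at the current pose and its score against
        # the CURRENT reference never decreases, so the polished pose is
        # accepted as is; gating on the stored score would compare against a
        # value measured under an older reference, which is meaningless
        records <- set_record_pose(records, r, pol$pose)
        records$score[r] <- pol$score
      }
    }
    if (mode == "gold_standard") {
      h0 <- average_subtomograms(subtomos, records[records$half_set == 0, ])
      h1 <- average_subtomograms(subtomos, records[records$half_set == 1, ])
      refs <- list(`0` = h0, `1` = h1)
      fsc <- fsc_curve(h0, h1, mask = schedule$fsc_mask)
      res_now <- resolution_at_threshold(fsc, 0.143, vs)$resolution_A
      if (res_now <= res_prev) {
        history <- rbind(history,
                         data.frame(iteration = nrow(history) + 1,
                                    resolution_A = res_now,
                                    angular_step_deg = step,
                                    mean_score = mean(records$score)))
        res_prev <- res_now
      }
    } else {
      refs <- list(all = average_subtomograms(subtomos, records))
    }
  }
  final_avg <- average_subtomograms(subtomos, records)
  list(average = final_avg,
       half_averages = if (mode == "gold_standard") refs else NULL,
       history = history, records = records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
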