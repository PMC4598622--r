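#' Template matching in tomograms
#'
#' Six-dimensional (3 rotations x 3 translations) search for copies of a
#' template in a tomogram: rotations are sampled on a quasi-uniform SO(3)
#' grid, the rotated template is filtered with the tomogram's missing-wedge
#' mask, and a locally normalized cross-correlation over all positions is
#' computed via FFT.  The per-voxel maximum score over orientations and the
#' arg-max orientation index are returned.
#'
#' @name detect
NULL

#' Quasi-uniform SO(3) orientation grid
#'
#' Built as template-axis directions from a Fibonacci sphere spiral at the
#' target angular spacing, crossed with in-plane rotations at the same
#' spacing; returned as ZXZ Euler angles (degrees).
#'
#' @param increment_deg target angular spacing (> 0), e.g. 12.85.
#' @return data.frame with columns phi, theta, psi; one row per orientation.
#' @export
so3_grid <- function(increment_deg) {
  if (increment_deg <= 0) stop("angular increment must be positive")
  inc <- increment_deg * pi / 180
  n_sphere <- max(1, ceiling(4 * pi / inc^2))
  ga <- pi * (3 - sqrt(5))                  # golden angle
  i <- seq_len(n_sphere) - 0.5
  z <- 1 - 2 * i / n_sphere
  r <- sqrt(pmax(0, 1 - z^2))
  az <- ga * (seq_len(n_sphere) - 1)
  # direction (x,y,z) -> ZXZ angles rotating template +z onto it
  theta <- acos(pmax(-1, pmin(1, z))) * 180 / pi
  phi <- (atan2(sin(az) * r, cos(az) * r) * 180 / pi + 90) %% 360
  n_psi <- max(1, ceiling(360 / increment_deg))
  psi <- seq(0, 360, length.out = n_psi + 1)[seq_len(n_psi)]
  out <- expand.grid(psi = psi, node = seq_len(n_sphere))
  data.frame(phi = phi[out$node], theta = theta[out$node], psi = out$psi)
}

#' @rdname detect
#' @param tomogram \code{density_map}.
#' @param template cubic \code{density_map}, smaller than the tomogram, low-pass
#'   filtered by the caller to the matching resolution.
#' @param template_mask soft/binary mask on the template grid; a spherical
#'   mask keeps the local-normalization field orientation-independent.
#' @param angular_increment_deg SO(3) grid spacing in degrees.
#' @param wedge \code{wedge_spec} of the tomogram's tilt range.
#' @param verbose print progress every few hundred orientations.
#' @return list(scores = \code{density_map} of max normalized CC in [-1, 1],
#'   orient = integer array of arg-max orientation row indices, grid = the
#'   orientation data.frame).
#' @export
match_template <- function(tomogram, template, template_mask,
                           angular_increment_deg, wedge, verbose = FALSE) {
  tomo <- as_grid(tomogram)
  tmpl <- as_grid(template)
  msk <- as_mask_grid(template_mask)
  nt <- check_cubic(tmpl, "template")
  nv <- dim(tomo)
  if (any(nt >= nv)) stop("template must be smaller than the tomogram")
  if (sum(msk) <= 0) stop("template mask is empty")
  grid <- so3_grid(angular_increment_deg)
  wmask <- make_wedge_mask(nt, wedge)
  Ftomo <- stats::fft(tomo)
  npx <- prod(nv)

  # local mean/std of the tomogram under the (assumed spherical) mask
  mpad <- embed_centered(msk, nv)
  Fm <- Conj(stats::fft(mpad))
  nm <- sum(msk)
  loc_mean <- Re(stats::fft(Ftomo * Fm, inverse = TRUE)) / npx / nm
  loc_sq <- Re(stats::fft(stats::fft(tomo^2) * Fm, inverse = TRUE)) / npx / nm
  loc_sd <- sqrt(pmax(loc_sq - loc_mean^2, 0))
  # floor the denominator at a fraction of the global sd: featureless regions
  # score ~ 0 instead of 0/0, and affine intensity invariance is preserved
  loc_sd <- pmax(loc_sd, 0.05 * stats::sd(as.vector(tomo)))

  scores <- array(-Inf, nv)
  orient <- array(0L, nv)
  tmpl_dm <- density_map(tmpl, 1)
  msk_dm <- density_map(msk, 1)
  for (g in seq_len(nrow(grid))) {
    R <- euler_to_matrix(grid$phi[g], grid$theta[g], grid$psi[g])
    rt <- rotate_volume(tmpl_dm, rigid_transform(R))$grid
    rm <- pmin(pmax(rotate_volume(msk_dm, rigid_transform(R))$grid, 0), 1)
    rt <- apply_fourier_filter(rt, wmask)
    w <- sum(rm)
    mu <- sum(rt * rm) / w
    tn <- (rt - mu) * rm
    sdt <- sqrt(sum(tn^2) / w)
    tn <- tn / (sdt * w)
    cc <- Re(stats::fft(Ftomo * Conj(stats::fft(embed_centered(tn, nv))),
                        inverse = TRUE)) / npx
    sc <- cc / loc_sd
    upd <- sc > scores
    scores[upd] <- sc[upd]
    orient[upd] <- g
    if (verbose && g %% 500 == 0)
      message("  orientation ", g, "/", nrow(grid))
  }
  vs <- if (inherits(tomogram, "density_map")) tomogram$voxel_size else 1
  list(scores = density_map(pmin(pmax(scores, -1), 1), vs),
       orient = orient, grid = grid)
}

# place a small cube into a large volume so the small cube's rotation-center
# voxel lands at index (1,1,1) with circular wrap (correlation convention)
embed_centered <- function(small, big_dim) {
  ns <- dim(small)[1]
  out <- array(0, big_dim)
  out[seq_len(ns), seq_len(ns), seq_len(ns)] <- small
  c0 <- vol_center(ns)
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    out <- aperm(out, perm)
    d <- dim(out)
    roll <- c0 - 1
    out <- out[c((roll + 1):d[1], 1:roll), , , drop = FALSE]
    out <- aperm(out, order(perm))
  }
  out
}

#' Greedy peak extraction from a template-matching score volume
#'
#' Picks candidates in descending score order, suppressing a spherical
#' exclusion region around each pick; ties are broken by lexicographic voxel
#' order (the natural array order of which.max).
#'
#' @param scores \code{density_map} (or array) of match scores.
#' @param n_peaks maximum number of peaks (>= 1).
#' @param exclusion_radius_vox suppression radius in voxels; defaults should
#'   be near the template diameter.
#' @param orient optional orientation-index array from
#'   \code{\link{match_template}}; if given, the grid data.frame must be
#'   passed too and Euler angles are attached.
#' @param grid orientation grid data.frame.
#' @param subvoxel when \code{TRUE}, refine each peak position by a 1D
#'   parabola fit per axis through the score and its two neighbors (the
#'   returned x, y, z are then fractional).
#' @return data.frame with columns x, y, z (1-based voxel indices, fractional
#'   when \code{subvoxel}), score and, when orientations are available, phi,
#'   theta, psi.
#' @export
extract_peaks <- function(scores, n_peaks, exclusion_radius_vox,
                          orient = NULL, grid = NULL, subvoxel = FALSE) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  sc <- as_grid(scores)
  sc0 <- sc                                 # unsuppressed copy for interpolation
  d <- dim(sc)
  out <- vector("list", n_peaks)
  r2 <- exclusion_radius_vox^2
  for (p in seq_len(n_peaks)) {
    i <- which.max(sc)
    if (!is.finite(sc[i])) break
    pk <- arrayInd(i, d)
    pos <- as.numeric(pk)
    if (subvoxel) {
      for (ax in 1:3) {
        q <- pk
        y2 <- sc0[q[1], q[2], q[3]]
        q[ax] <- pk[ax] - 1
        y1 <- if (q[ax] >= 1) sc0[q[1], q[2], q[3]] else NA_real_
        q[ax] <- pk[ax] + 1
        y3 <- if (q[ax] <= d[ax]) sc0[q[1], q[2], q[3]] else NA_real_
        if (!is.finite(y1) || !is.finite(y3)) next
        den <- y1 - 2 * y2 + y3
        if (abs(den) > 1e-12)
          pos[ax] <- pk[ax] + max(-0.5, min(0.5, 0.5 * (y1 - y3) / den))
      }
    }
    rec <- data.frame(x = pos[1], y = pos[2], z = pos[3], score = sc[i])
    if (!is.null(orient) && !is.null(grid)) {
      gi <- orient[i]
      rec$phi <- grid$phi[gi]; rec$theta <- grid$theta[gi]
      rec$psi <- grid$psi[gi]
    }
    out[[p]] <- rec
    rad <- ceiling(exclusion_radius_vox)
    xr <- max(1, pk[1] - rad):min(d[1], pk[1] + rad)
    yr <- max(1, pk[2] - rad):min(d[2], pk[2] + rad)
    zr <- max(1, pk[3] - rad):min(d[3], pk[3] + rad)
    sub <- expand.grid(x = xr, y = yr, z = zr)
    kill <- (sub$x - pk[1])^2 + (sub$y - pk[2])^2 + (sub$z - pk[3])^2 <= r2
    sc[cbind(sub$x, sub$y, sub$z)[kill, , drop = FALSE]] <- -Inf
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Erase very bright compact densities (gold fiducials) from a volume
#'
#' Gold beads are several-fold denser than any biological feature, so voxels
#' above a fraction of the volume maximum, dilated by a few voxels to catch
#' their missing-wedge tails, are blanked to zero.  Standard practice before
#' template matching, which bright beads would otherwise dominate.
#'
#' @param map \code{density_map} or 3D array.
#' @param threshold_frac fraction of the volume maximum above which a voxel is
#'   considered bead (default 0.5).
#' @param dilate_vox 6-neighbor dilation rounds applied to the bead mask
#'   (default 3).
#' @return object of the same class as \code{map} with bead voxels set to 0.
#' @export
erase_bright_blobs <- function(map, threshold_frac = 0.5, dilate_vox = 3) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  g <- as_grid(map)
  bead <- array((g > threshold_frac * max(g)) * 1, dim(g))
  if (any(bead > 0)) {
    for (k in seq_len(dilate_vox)) bead <- dilate_mask6(bead)
    g[bead > 0] <- 0
  }
  if (inherits(map, "density_map")) density_map(g, map$voxel_size) else g
}
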