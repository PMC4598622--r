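#' Tomographic reconstruction: frame alignment, CTF handling, tilt alignment,
#' weighted backprojection
#'
#' @name reconstruct
NULL

# circular cross-correlation peak of 2D a against b with subpixel parabola
# fit; returns the shift of a relative to b (a ~ b shifted by +s)
xcorr_peak2d <- function(a, b) {
  n <- dim(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- as.integer(arrayInd(which.max(cc), n))
  border <- any(pk == c(n[1] / 2 + 1, n[2] / 2 + 1))
  sub <- numeric(2)
  for (ax in 1:2) {
    i0 <- pk[ax]
    im <- ((i0 - 2) %% n[ax]) + 1
    ip <- (i0 %% n[ax]) + 1
    idx <- function(i) if (ax == 1) cc[i, pk[2]] else cc[pk[1], i]
    y1 <- idx(im); y2 <- idx(i0); y3 <- idx(ip)
    den <- y1 - 2 * y2 + y3
    sub[ax] <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
    sub[ax] <- max(-0.5, min(0.5, sub[ax]))
  }
  s <- pk - 1
  s[s > unlist(n) / 2] <- s[s > unlist(n) / 2] - unlist(n)[s > unlist(n) / 2]
  list(shift = s + sub, peak = max(cc), border = border)
}

#' Drift-correct and sum dose-fractionated movie frames
#'
#' Iterative quasi-expectation-maximization scheme: each frame is
#' cross-correlated against the running sum of the other frames to estimate
#' its drift (correlation peak with subpixel parabola fit), frames are then
#' re-summed at the updated shifts; iterated until the largest shift update
#' falls below \code{tol_px} or \code{max_iters} is reached.  A frame whose
#' correlation peak lands on the border (non-overlapping) gets a warning and
#' zero shift.
#'
#' @param frames list of >= 2 equal-shape 2D arrays.
#' @param max_iters maximum EM iterations (default 10).
#' @param tol_px convergence threshold on shift updates (default 0.02 px).
#' @return list(sum = drift-corrected sum image, shifts = k x 2 estimated
#'   per-frame shifts (px), n_iter).
#' @export
align_frames <- function(frames, max_iters = 10, tol_px = 0.02) {
  k <- length(frames)
  if (k < 2) stop("need at least 2 frames")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("frames differ in shape")
  shifts <- matrix(0, k, 2)
  aligned <- frames
  for (it in seq_len(max_iters)) {
    total <- Reduce(`+`, aligned)
    max_upd <- 0
    for (i in seq_len(k)) {
      ref <- total - aligned[[i]]
      pk <- xcorr_peak2d(frames[[i]], ref)
      if (pk$border) {
        warning("frame ", i, ": correlation peak at border, keeping zero shift")
        new_s <- c(0, 0)
      } else new_s <- pk$shift
      max_upd <- max(max_upd, sqrt(sum((new_s - shifts[i, ])^2)))
      shifts[i, ] <- new_s
      aligned[[i]] <- fourier_shift(frames[[i]], -shifts[i, ])
    }
    if (max_upd < tol_px) break
  }
  # report drift relative to the first frame
  shifts <- sweep(shifts, 2, shifts[1, ])
  list(sum = Reduce(`+`, lapply(seq_len(k), function(i)
    fourier_shift(frames[[i]], -shifts[i, ]))), shifts = shifts, n_iter = it)
}

#' Defocus estimation by strip-based periodogram averaging
#'
#' Splits the projection into overlapping strips parallel to the tilt axis
#' (y), Hann-windows each strip, averages their periodograms, radially
#' averages, removes the smooth background, and returns the defocus whose
#' simulated \code{|CTF|^2} best correlates with the ring pattern (grid search
#' plus local refinement).
#'
#' @param projection 2D array.
#' @param params \code{ctf_params} (defocus field ignored).
#' @param pixel_size A/px.
#' @param strip_width_px strip width (default 128); the projection must be at
#'   least twice as wide.
#' @param defocus_range_um length-2 search interval (default c(1, 6)).
#' @param n_grid grid points for the coarse search (default 101).
#' @return list(defocus_um, quality in [0,1] (0 flags a featureless
#'   spectrum), grid_spacing_um, profile = data.frame(s, power)).
#' @export
estimate_defocus <- function(projection, params, pixel_size,
                             strip_width_px = 128,
                             defocus_range_um = c(1, 6), n_grid = 101) {
  d <- dim(projection)
  if (d[1] < 2 * strip_width_px)
    stop("projection narrower than twice the strip width")
  w <- strip_width_px
  starts <- unique(pmin(seq(1, d[1] - w + 1, by = w %/% 2), d[1] - w + 1))
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))
  win <- outer(hann, 0.5 * (1 - cos(2 * pi * seq_len(d[2]) / (d[2] + 1))))
  pw <- 0
  for (s0 in starts) {
    strip <- projection[s0:(s0 + w - 1), ] * win
    pw <- pw + Mod(stats::fft(strip))^2
  }
  # radial average over the 2D frequency grid of the strip
  fx <- fft_freq(w) / pixel_size
  fy <- fft_freq_any(d[2]) / pixel_size
  s2d <- sqrt(outer(fx^2, fy^2, `+`))
  nyq <- 1 / (2 * pixel_size)
  nb <- w %/% 2
  bin <- pmin(nb, 1 + floor(s2d / nyq * nb))
  prof <- as.numeric(tapply(pw, bin, mean))
  s_centers <- (seq_len(nb) - 0.5) / nb * nyq
  prof <- prof[seq_len(nb)]
  keep <- s_centers > 0.02 * nyq               # drop the structure-heavy DC end
  sc <- s_centers[keep]; pr <- log(prof[keep] + 1e-30)
  bg <- stats::runmed(pr, k = min(31, 2 * (sum(keep) %/% 4) + 1))
  ring <- pr - bg
  score_fun <- function(dz) {
    model <- ctf_eval(sc, dz, params)^2
    m <- model - mean(model)
    r <- ring - mean(ring)
    sum(m * r) / sqrt(sum(m^2) * sum(r^2))
  }
  grid <- seq(defocus_range_um[1], defocus_range_um[2], length.out = n_grid)
  sc_grid <- vapply(grid, score_fun, 0)
  best <- which.max(sc_grid)
  spacing <- diff(grid[1:2])
  lo <- max(defocus_range_um[1], grid[best] - spacing)
  hi <- min(defocus_range_um[2], grid[best] + spacing)
  opt <- stats::optimize(score_fun, c(lo, hi), maximum = TRUE)
  quality <- max(0, opt$objective)
  if (!is.finite(quality) || quality < 0.15) quality <- 0
  list(defocus_um = opt$maximum, quality = quality,
       grid_spacing_um = spacing,
       profile = data.frame(s = sc, power = ring))
}

#' Correct CTF phase reversals on a single projection
#'
#' Multiplies the Fourier transform by the sign of the CTF, referenced so the
#' low-frequency band (before the first zero crossing) is left unchanged;
#' amplitudes are preserved exactly.  Applying the operation twice is the
#' identity.
#'
#' @param projection 2D array.
#' @param params \code{ctf_params}.
#' @param defocus_um underfocus for this projection, micrometer.
#' @param pixel_size A/px.
#' @return phase-flipped projection.
#' @export
phase_flip <- function(projection, params, defocus_um, pixel_size) {
  if (defocus_um <= 0) stop("defocus must be positive")
  n <- dim(projection)
  f1 <- fft_freq_any(n[1]) / pixel_size
  f2 <- fft_freq_any(n[2]) / pixel_size
  s <- sqrt(outer(f1^2, f2^2, `+`))
  ctf <- ctf_eval(s, defocus_um, params)
  sgn <- -sign(ctf)                 # low-s band has negative CTF: keep it as-is
  sgn[sgn == 0] <- 1
  Re(stats::fft(stats::fft(projection) * sgn, inverse = TRUE)) / prod(n)
}

#' Marker-based tilt-series alignment (shift-only projection model)
#'
#' Least-squares fit of the projection model
#' \code{u_ij = cos(t_i) x_j + sin(t_i) z_j + sx_i},
#' \code{v_ij = y_j + sy_i} for unknown marker positions (x, y, z)_j and
#' per-image shifts (sx, sy)_i at known tilt angles.  The unobservable global
#' translation of the marker set is fixed by constraining the marker centroid
#' to the origin, so recovered shifts are relative to centroid-zero markers.
#'
#' @param marker_xy array [n_markers, n_images, 2] of marker image coordinates
#'   (px, relative to the image center); NA entries are allowed for untracked
#'   markers.
#' @param tilt_deg tilt angle per image.
#' @return list(shifts = n_images x 2 (px), markers = n_markers x 3 (px),
#'   residual_rms_px).
#' @export
align_tilt_series <- function(marker_xy, tilt_deg) {
  dm <- dim(marker_xy)
  M <- dm[1]; K <- dm[2]
  if (M < 3) stop("rank-deficient system: need >= 3 markers, got ", M)
  if (K < 3) stop("rank-deficient system: need >= 3 images, got ", K)
  th <- tilt_deg * pi / 180
  # u-system unknowns: x_1..x_M, z_1..z_M, sx_1..sx_K
  rows_u <- list(); rhs_u <- numeric(0)
  rows_v <- list(); rhs_v <- numeric(0)
  for (j in seq_len(M)) for (i in seq_len(K)) {
    if (is.na(marker_xy[j, i, 1])) next
    ru <- numeric(2 * M + K)
    ru[j] <- cos(th[i]); ru[M + j] <- sin(th[i]); ru[2 * M + i] <- 1
    rows_u[[length(rows_u) + 1]] <- ru
    rhs_u <- c(rhs_u, marker_xy[j, i, 1])
    rv <- numeric(M + K)
    rv[j] <- 1; rv[M + i] <- 1
    rows_v[[length(rows_v) + 1]] <- rv
    rhs_v <- c(rhs_v, marker_xy[j, i, 2])
  }
  wt <- 1e4
  Au <- do.call(rbind, rows_u)
  Au <- rbind(Au, wt * c(rep(1, M), rep(0, M + K)),
              wt * c(rep(0, M), rep(1, M), rep(0, K)))
  bu <- c(rhs_u, 0, 0)
  Av <- do.call(rbind, rows_v)
  Av <- rbind(Av, wt * c(rep(1, M), rep(0, K)))
  bv <- c(rhs_v, 0)
  cu <- stats::lm.fit(Au, bu)$coefficients
  cv <- stats::lm.fit(Av, bv)$coefficients
  cu[is.na(cu)] <- 0; cv[is.na(cv)] <- 0
  shifts <- cbind(cu[2 * M + seq_len(K)], cv[M + seq_len(K)])
  markers <- cbind(cu[seq_len(M)], cv[seq_len(M)], cu[M + seq_len(M)])
  res <- c(Au[seq_along(rhs_u), , drop = FALSE] %*% cu - rhs_u,
           Av[seq_along(rhs_v), , drop = FALSE] %*% cv - rhs_v)
  dimnames(shifts) <- NULL; dimnames(markers) <- NULL
  list(shifts = shifts, markers = markers,
       residual_rms_px = sqrt(mean(res^2)))
}

#' Pre-apply the ramp filter to a whole tilt series
#'
#' Returns a copy of the series whose images carry the 1D |k| weighting used
#' by weighted backprojection, marked so the reconstruction functions skip
#' re-filtering.  Useful when many subtomograms are cut from one series.
#'
#' @param series \code{tilt_series}.
#' @return filtered \code{tilt_series}.
#' @export
ramp_filter_series <- function(series) {
  series$images <- ramp_filter_images(series$images)
  attr(series, "ramp_filtered") <- TRUE
  series
}

ramp_filter_images <- function(images, pixel_weights = NULL) {
  n1 <- dim(images)[1]
  w <- abs(fft_freq(n1))
  k <- dim(images)[3]
  out <- images
  for (i in seq_len(k)) {
    F <- stats::mvfft(images[, , i])
    out[, , i] <- Re(stats::mvfft(F * w, inverse = TRUE)) / n1
  }
  out
}

# shared backprojection core: evaluates the WBP sum on arbitrary centered
# world coordinates (A); gx/gy/gz are equal-length vectors
backproject_points <- function(images, tilt_deg, pixel_size, gx, gy, gz,
                               shifts = NULL) {
  k <- length(tilt_deg)
  n_img <- dim(images)[1:2]
  ci <- vol_center(n_img[1]); cj <- vol_center(n_img[2])
  acc <- numeric(length(gx))
  for (i in seq_len(k)) {
    th <- tilt_deg[i] * pi / 180
    u <- (cos(th) * gx + sin(th) * gz) / pixel_size + ci
    v <- gy / pixel_size + cj
    if (!is.null(shifts)) { u <- u + shifts[i, 1]; v <- v + shifts[i, 2] }
    # bilinear sample of image i
    u0 <- floor(u); v0 <- floor(v)
    fu <- u - u0; fv <- v - v0
    ok <- u0 >= 1 & u0 < n_img[1] & v0 >= 1 & v0 < n_img[2]
    img <- images[, , i]
    iu <- u0[ok]; iv <- v0[ok]
    i00 <- iu + (iv - 1) * n_img[1]
    vals <- (img[i00] * (1 - fu[ok]) + img[i00 + 1] * fu[ok]) * (1 - fv[ok]) +
            (img[i00 + n_img[1]] * (1 - fu[ok]) + img[i00 + n_img[1] + 1] * fu[ok]) * fv[ok]
    acc[ok] <- acc[ok] + vals
  }
  acc * pi / (2 * k)
}

#' Weighted backprojection of a tilt series into a tomogram
#'
#' Each selected projection is ramp-filtered (analytic |k| weighting along the
#' direction perpendicular to the tilt axis) and smeared back along its
#' viewing direction; the output voxel size is the pixel size times the
#' binning factor.
#'
#' @param series \code{tilt_series}.
#' @param tilt_subset length-2 inclusive tilt range in degrees (default the
#'   full range).
#' @param out_n output cube edge in (binned) voxels; default the image width
#'   divided by the binning.
#' @param binning integer image-binning factor before reconstruction.
#' @param shifts optional per-image 2D shifts (px, at the unbinned pixel) to
#'   undo during backprojection, e.g. from \code{\link{align_tilt_series}}.
#' @return list(map = \code{density_map}, wedge = \code{wedge_spec}, dose_e_A2
#'   = accumulated dose of the images used).
#' @export
weighted_backprojection <- function(series, tilt_subset = NULL, out_n = NULL,
                                    binning = 1, shifts = NULL) {
  if (is.null(tilt_subset))
    tilt_subset <- range(series$tilt_deg)
  sel <- which(series$tilt_deg >= tilt_subset[1] &
               series$tilt_deg <= tilt_subset[2])
  if (length(sel) == 0)
    stop("tilt subset [", tilt_subset[1], ", ", tilt_subset[2],
         "] selects no images")
  imgs <- series$images[, , sel, drop = FALSE]
  px <- series$pixel_size_A
  shf <- if (!is.null(shifts)) shifts[sel, , drop = FALSE] else NULL
  if (binning > 1) {
    d <- dim(imgs)
    bb <- array(0, c(d[1] / binning, d[2] / binning, d[3]))
    for (i in seq_len(d[3])) bb[, , i] <- bin_array(imgs[, , i], binning)
    imgs <- bb
    px <- px * binning
    if (!is.null(shf)) shf <- shf / binning
  }
  if (is.null(out_n)) out_n <- dim(imgs)[1]
  filt <- if (isTRUE(attr(series, "ramp_filtered"))) imgs
          else ramp_filter_images(imgs)
  c0 <- vol_center(out_n)
  idx <- voxel_index_grids(out_n)
  gx <- (idx$x - c0) * px; gy <- (idx$y - c0) * px; gz <- (idx$z - c0) * px
  vals <- backproject_points(filt, series$tilt_deg[sel], px, gx, gy, gz, shf)
  list(map = density_map(array(vals, rep(out_n, 3)), px),
       wedge = wedge_spec(min(series$tilt_deg[sel]) - 1e-9,
                          max(series$tilt_deg[sel]) + 1e-9),
       dose_e_A2 = sum(series$dose_e_A2[sel]))
}

#' Reconstruct a subtomogram centered on a particle position
#'
#' Per-particle weighted backprojection on a box whose center voxel tracks the
#' given position, using only the selected tilt range; attaches the
#' missing-wedge specification and the accumulated dose of the projections
#' used.  With an integer-voxel position and the full tilt range this equals
#' the corresponding crop of the full tomogram.
#'
#' @param series \code{tilt_series}.
#' @param position_A length-3 position in centered world coordinates (A).
#' @param box_px subtomogram cube edge (voxels at the unbinned pixel size).
#' @param tilt_subset length-2 inclusive tilt range (default full range).
#' @param shifts optional per-image alignment shifts (px) to undo.
#' @return list(map, wedge, dose_e_A2) as for
#'   \code{\link{weighted_backprojection}}.
#' @export
reconstruct_subtomogram <- function(series, position_A, box_px,
                                    tilt_subset = NULL, shifts = NULL) {
  if (is.null(tilt_subset)) tilt_subset <- range(series$tilt_deg)
  sel <- which(series$tilt_deg >= tilt_subset[1] &
               series$tilt_deg <= tilt_subset[2])
  if (length(sel) == 0)
    stop("tilt subset [", tilt_subset[1], ", ", tilt_subset[2],
         "] selects no images")
  px <- series$pixel_size_A
  n_img <- dim(series$images)[1]
  # the center must be inside the field; a box that overhangs the edge is
  # still reconstructable (projections are shifted before cropping), but its
  # overhanging rim picks up circularly wrapped content, so callers should
  # mask the box periphery
  margin <- (n_img / 2 - 1) * px
  if (any(abs(position_A) > margin))
    stop("position too close to the field edge: |position| must be <= ",
         margin, " A")
  filt <- if (isTRUE(attr(series, "ramp_filtered")))
            series$images[, , sel, drop = FALSE]
          else ramp_filter_images(series$images[, , sel, drop = FALSE])
  shf <- if (!is.null(shifts)) shifts[sel, , drop = FALSE] else NULL
  c0 <- vol_center(box_px)
  idx <- voxel_index_grids(box_px)
  gx <- (idx$x - c0) * px + position_A[1]
  gy <- (idx$y - c0) * px + position_A[2]
  gz <- (idx$z - c0) * px + position_A[3]
  vals <- backproject_points(filt, series$tilt_deg[sel], px, gx, gy, gz, shf)
  list(map = density_map(array(vals, rep(box_px, 3)), px),
       wedge = wedge_spec(min(series$tilt_deg[sel]) - 1e-9,
                          max(series$tilt_deg[sel]) + 1e-9),
       dose_e_A2 = sum(series$dose_e_A2[sel]))
}
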