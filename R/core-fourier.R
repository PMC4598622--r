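#' Fourier-domain utilities: frequency grids, wedge masks, bandpass filters
#'
#' All Fourier-domain masks and filters in the package are stored in the
#' unshifted FFT layout (DC at array index \code{[1,1,1]}) so they multiply
#' the output of \code{\link[stats]{fft}} directly.  Frequencies are in cycles
#' per voxel; divide by the voxel size for 1/Angstrom.
#' @name fourier-utils
NULL

#' FFT sample frequencies (cycles per voxel) of an even-length axis
#' @param n even axis length.
#' @return numeric vector of length n in FFT order.
#' @export
fft_freq <- function(n) {
  stopifnot(n %% 2 == 0)
  c(0:(n / 2 - 1), -(n / 2):-1) / n
}

# cached FFT-order frequency component grids and radius for an n^3 cube
freq_grids <- function(n) {
  key <- paste0("frq", n)
  if (!is.null(.tomo_cache[[key]])) return(.tomo_cache[[key]])
  f <- fft_freq(n)
  kx <- rep.int(f, n * n)
  ky <- rep.int(rep(f, each = n), n)
  kz <- rep(f, each = n * n)
  g <- list(kx = kx, ky = ky, kz = kz,
            kr = sqrt(kx^2 + ky^2 + kz^2))
  .tomo_cache[[key]] <- g
  g
}

#' Tilt-range specification of single-axis tomography
#'
#' The tilt axis is fixed to the y axis of the volume frame; the untilted beam
#' runs along z.
#'
#' @param tilt_min,tilt_max tilt bounds in degrees, \code{-90 < min < max < 90}.
#' @return object of class \code{wedge_spec}.
#' @export
wedge_spec <- function(tilt_min, tilt_max) {
  if (!(tilt_min > -90 && tilt_max < 90 && tilt_min < tilt_max))
    stop("invalid wedge bounds: need -90 < tilt_min < tilt_max < 90, got [",
         tilt_min, ", ", tilt_max, "]")
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max, tilt_axis = "y"),
            class = "wedge_spec")
}

#' Binary missing-wedge mask in Fourier space
#'
#' For tilting about y with the beam along z, the central slice at tilt theta
#' is the plane spanned by ky and the direction at angle -theta from the kx
#' axis in the kx-kz plane; a Fourier voxel is sampled when its (kx, kz) line
#' angle falls inside the swept range, leaving the familiar missing wedge
#' around the kz (beam) axis.  The full ky axis is always sampled and the DC
#' voxel is forced to 1.  The mask is centrosymmetric (Friedel symmetry) and
#' returned in unshifted FFT order.  Masks are cached per (n, tilt range).
#'
#' @param n cube edge length (even).
#' @param wedge \code{wedge_spec}.
#' @return 3D 0/1 array of dim \code{c(n, n, n)}.
#' @export
make_wedge_mask <- function(n, wedge) {
  stopifnot(inherits(wedge, "wedge_spec"))
  if (n %% 2 != 0) stop("wedge mask shape must be even and cubic, got ", n)
  key <- sprintf("wdg%d_%.6f_%.6f", n, wedge$tilt_min, wedge$tilt_max)
  if (!is.null(.tomo_cache[[key]])) return(.tomo_cache[[key]])
  m <- wedge_condition(freq_grids(n)$kx, freq_grids(n)$ky, freq_grids(n)$kz,
                       wedge)
  m[1] <- 1                                    # DC
  m <- array(m, dim = c(n, n, n))
  # Friedel symmetry: a voxel on a Nyquist plane aliases both +0.5 and -0.5,
  # i.e. it represents two (kx, kz) lines; for an asymmetric tilt range the
  # membership test can pick different sides for a conjugate pair.  The DFT
  # coefficient carries data when either aliased line was swept, so the mask
  # is symmetrized with the centrosymmetric image.
  cs <- c(1L, n:2L)
  m <- pmax(m, m[cs, cs, cs])
  .tomo_cache[[key]] <- m
  m
}

# sampled-region membership for frequency components under a tilt range:
# line angle of (kx, kz) from the kx axis, folded to (-90, 90], must lie in
# [-tilt_max, -tilt_min] (the slice at tilt theta has line angle -theta)
wedge_condition <- function(kx, ky, kz, wedge) {
  ang <- atan2(kz, kx) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  as.numeric(ang >= -wedge$tilt_max & ang <= -wedge$tilt_min)
}

#' Fraction of a map's Fourier energy outside a missing-wedge mask
#'
#' The wedge mask is dilated by \code{dilate_vox} Fourier voxels before
#' measuring, since at radii of a few voxels wedge membership is only defined
#' to one-voxel precision; energy is summed over the full cube, DC excluded.
#'
#' @param map \code{density_map} or 3D array.
#' @param wedge \code{wedge_spec}.
#' @param dilate_vox dilation of the wedge support (default 1).
#' @return fraction in [0, 1].
#' @export
fourier_energy_outside_wedge <- function(map, wedge, dilate_vox = 1) {
  g <- as_grid(map)
  n <- check_cubic(g)
  g <- g - mean(g)
  F <- Mod(stats::fft(g))^2
  w <- make_wedge_mask(n, wedge)
  for (i in seq_len(dilate_vox)) w <- dilate_mask6(w)
  sum(F * (1 - w)) / sum(F)
}

# one-step 6-neighborhood dilation with circular wrap (FFT-order masks)
dilate_mask6 <- function(m) {
  d <- m
  for (ax in 1:3) for (s in c(-1, 1)) {
    idx <- seq_len(dim(m)[ax])
    src <- ((idx - 1 - s) %% dim(m)[ax]) + 1
    shifted <- switch(ax, m[src, , , drop = FALSE],
                      m[, src, , drop = FALSE], m[, , src, drop = FALSE])
    d <- pmax(d, shifted)
  }
  d
}

#' Gaussian-edged soft band mask in Fourier space (unshifted layout)
#'
#' Weight 1 for frequencies inside [1/low_res, 1/high_res] (1/A), Gaussian
#' rolloff of width \code{edge_shells} Fourier voxels outside.  \code{low_res
#' = Inf} disables the low cut, \code{high_res = NULL/NA} the high cut; a
#' finite low cut removes the DC term.
#'
#' @param n cube edge; \code{voxel_size} A/voxel.
#' @param low_res_A,high_res_A resolution cutoffs in Angstrom.
#' @param edge_shells Gaussian edge width in Fourier voxels (default 2).
#' @return 3D numeric array in [0, 1].
#' @export
band_mask <- function(n, voxel_size, low_res_A = Inf, high_res_A = NULL,
                      edge_shells = 2) {
  if (!is.null(high_res_A) && !is.na(high_res_A)) {
    if (high_res_A < 2 * voxel_size)
      stop("high-resolution cutoff ", high_res_A,
           " A is beyond Nyquist (", 2 * voxel_size, " A)")
    if (is.finite(low_res_A) && high_res_A >= low_res_A)
      stop("need high_res_A < low_res_A")
  }
  g <- freq_grids(n)
  s <- g$kr / voxel_size                       # 1/A
  w <- rep(1, length(s))
  sig <- edge_shells / (n * voxel_size)        # edge width in 1/A
  if (is.finite(low_res_A)) {
    lo <- 1 / low_res_A
    below <- s < lo
    w[below] <- exp(-((s[below] - lo)^2) / (2 * sig^2))
    w[1] <- 0
  }
  if (!is.null(high_res_A) && !is.na(high_res_A)) {
    hi <- 1 / high_res_A
    above <- s > hi
    w[above] <- w[above] * exp(-((s[above] - hi)^2) / (2 * sig^2))
  }
  array(w, dim = c(n, n, n))
}

#' Bandpass filter a density map
#'
#' Multiplies the Fourier transform by \code{\link{band_mask}} weights; with a
#' finite low-resolution cutoff the mean (DC) is removed.
#'
#' @param map \code{density_map}.
#' @param low_res_A low-resolution (coarse) cutoff, Angstrom; \code{Inf} keeps
#'   all low frequencies.
#' @param high_res_A high-resolution (fine) cutoff, Angstrom; \code{NULL}
#'   keeps everything up to Nyquist.
#' @param edge_shells Gaussian edge width in Fourier voxels.
#' @return filtered \code{density_map}.
#' @export
bandpass <- function(map, low_res_A = Inf, high_res_A = NULL, edge_shells = 2) {
  grid <- as_grid(map)
  n <- check_cubic(grid, "bandpass input")
  vs <- if (inherits(map, "density_map")) map$voxel_size else 1
  w <- band_mask(n, vs, low_res_A, high_res_A, edge_shells)
  out <- Re(stats::fft(stats::fft(grid) * w, inverse = TRUE)) / length(grid)
  if (inherits(map, "density_map")) density_map(out, vs, map$origin) else out
}

#' Low-pass filter (convenience wrapper around \code{bandpass})
#' @inheritParams bandpass
#' @param res_A resolution cutoff in Angstrom.
#' @return filtered \code{density_map}.
#' @export
lowpass <- function(map, res_A, edge_shells = 2) {
  bandpass(map, low_res_A = Inf, high_res_A = res_A, edge_shells = edge_shells)
}

#' Apply a Fourier-domain multiplicative filter to a real volume
#' @keywords internal
apply_fourier_filter <- function(grid, filt) {
  Re(stats::fft(stats::fft(grid) * filt, inverse = TRUE)) / length(grid)
}

#' Subpixel shift of a real 2D or 3D array by Fourier phase ramps
#' @param x array.
#' @param shift shift in pixels/voxels (length = number of dims); positive
#'   moves content toward higher indices.
#' @return shifted array (real part).
#' @export
fourier_shift <- function(x, shift) {
  d <- dim(x)
  ph <- array(0, d)
  for (a in seq_along(d)) {
    if (shift[a] == 0) next
    f <- fft_freq_any(d[a])
    fa <- array(rep(f, times = prod(d) / d[a]), dim = c(d[a], d[-a]))
    fa <- aperm(fa, order(c(a, seq_along(d)[-a])))
    ph <- ph + fa * shift[a]
  }
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * ph), inverse = TRUE)) / prod(d)
}

fft_freq_any <- function(n) {
  k <- seq_len(n) - 1
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

#' Fourier (sinc) upsampling of a cubic volume by an integer factor
#'
#' Zero-pads the spectrum, giving the band-limited interpolation of the
#' volume on a finer grid; used to make subsequent trilinear resampling
#' nearly sinc-quality.
#'
#' @param grid 3D cubic array (even edge).
#' @param factor integer upsampling factor (default 2).
#' @return array of dim \code{dim(grid) * factor}.
#' @export
fourier_upsample <- function(grid, factor = 2) {
  n <- check_cubic(grid)
  m <- n * factor
  F <- stats::fft(grid)
  Fs <- array(0 + 0i, rep(m, 3))
  lo <- 1:(n / 2); hi_src <- (n / 2 + 1):n; hi_dst <- (m - n / 2 + 1):m
  ix <- c(lo, hi_src); ox <- c(lo, hi_dst)
  Fs[ox, ox, ox] <- F[ix, ix, ix]
  Re(stats::fft(Fs, inverse = TRUE)) / n^3
}

#' Raised-cosine (Tukey) apodization window for a cube
#'
#' 1 in the interior, cosine falloff over the outer \code{fraction} of the
#' half-width; used to window boxes for local FSC.
#'
#' @param n cube edge.
#' @param fraction outer fraction tapered (default 0.2).
#' @return 3D array in [0, 1].
#' @export
tukey_window3 <- function(n, fraction = 0.2) {
  w1 <- function(n) {
    x <- abs(seq_len(n) - vol_center(n)) / (n / 2)
    w <- rep(1, n)
    t <- x > (1 - fraction)
    w[t] <- 0.5 * (1 + cos(pi * (x[t] - (1 - fraction)) / fraction))
    w
  }
  w <- w1(n)
  outer(outer(w, w), w)
}
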