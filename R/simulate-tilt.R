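#' Contrast transfer function parameters
#'
#' @param voltage_kV acceleration voltage (default 300).
#' @param cs_mm spherical aberration (default 2.7 mm).
#' @param amplitude_contrast amplitude-contrast fraction in [0, 1).
#' @param defocus_um underfocus in micrometer (positive), scalar or per image.
#' @return object of class \code{ctf_params}.
#' @export
ctf_params <- function(voltage_kV = 300, cs_mm = 2.7,
                       amplitude_contrast = 0.07, defocus_um = 3.5) {
  if (any(defocus_um <= 0)) stop("defocus must be positive (underfocus)")
  if (amplitude_contrast < 0 || amplitude_contrast >= 1)
    stop("amplitude contrast must be in [0, 1)")
  structure(list(voltage_kV = voltage_kV, cs_mm = cs_mm,
                 amplitude_contrast = amplitude_contrast,
                 defocus_um = defocus_um),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#' @param voltage_kV acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kV) {
  v <- voltage_kV * 1e3
  12.2639 / sqrt(v * (1 + v * 0.97845e-6))
}

#' Evaluate the signed CTF at spatial frequencies
#'
#' \code{-(sqrt(1 - A^2) sin(chi) + A cos(chi))} with aberration phase
#' \code{chi = pi lambda s^2 dz - pi/2 Cs lambda^3 s^4} (underfocus positive),
#' the standard weak-phase/weak-amplitude form.
#'
#' @param s spatial frequency, 1/Angstrom.
#' @param defocus_um underfocus in micrometer.
#' @param params \code{ctf_params}.
#' @return numeric CTF values in [-1, 1].
#' @export
ctf_eval <- function(s, defocus_um, params) {
  lambda <- electron_wavelength(params$voltage_kV)
  dz <- defocus_um * 1e4                   # A
  cs <- params$cs_mm * 1e7                 # A
  chi <- pi * lambda * s^2 * dz - pi / 2 * cs * lambda^3 * s^4
  A <- params$amplitude_contrast
  -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
}

# 2D radial frequency grid (1/A) in FFT order for an n x n image
freq_grid2d <- function(n, pixel_size) {
  f <- fft_freq(n) / pixel_size
  sqrt(outer(f^2, f^2, `+`))
}

#' Project a scene volume into a tilt series
#'
#' Each projection is the parallel-beam line integral along z after rotating
#' the scene by the tilt angle about the y axis (the tilt axis), optionally
#' multiplied in Fourier space by the signed CTF for its defocus, shifted by a
#' small random in-plane displacement (recorded as ground truth), and
#' corrupted with additive white Gaussian noise whose variance scales
#' inversely with the per-image dose.  Deterministic given \code{seed}.
#'
#' @param volume \code{density_map} scene (cubic).
#' @param tilt_deg sorted unique tilt angles in (-90, 90); default the
#'   acquisition scheme -60..60 in 2-degree steps.
#' @param ctf \code{ctf_params} with scalar or per-image defocus, or
#'   \code{NULL} to disable CTF modulation.
#' @param dose_per_image electrons/A^2 per projection (default 1.5, i.e. a
#'   ~90 e/A^2 cumulative series over 61 images).
#' @param noise_sd0 noise standard deviation at unit dose; per-image sd is
#'   \code{noise_sd0 / sqrt(dose_per_image)}.  0 disables noise.
#' @param shift_jitter_px uniform half-range of random in-plane shifts (px).
#' @param seed integer seed.
#' @return object of class \code{tilt_series}: list(images [n x n x k],
#'   tilt_deg, defocus_um, dose_e_A2, pixel_size_A, shifts [k x 2, true
#'   applied shifts in px]).
#' @export
project_tilt_series <- function(volume, tilt_deg = seq(-60, 60, by = 2),
                                ctf = NULL, dose_per_image = 1.5,
                                noise_sd0 = 0, shift_jitter_px = 0, seed = 1) {
  if (length(tilt_deg) == 0) stop("empty tilt-angle list")
  if (any(duplicated(tilt_deg)) || is.unsorted(tilt_deg) ||
      any(abs(tilt_deg) >= 90))
    stop("tilt angles must be sorted, unique and inside (-90, 90)")
  grid <- as_grid(volume)
  n <- check_cubic(grid, "scene volume")
  vs <- volume$voxel_size
  k <- length(tilt_deg)
  defocus <- if (is.null(ctf)) rep(NA_real_, k) else rep(ctf$defocus_um, length.out = k)
  set.seed(seed)
  shifts <- if (shift_jitter_px > 0)
    matrix(stats::runif(2 * k, -shift_jitter_px, shift_jitter_px), k, 2)
  else matrix(0, k, 2)
  noise_sd <- if (noise_sd0 > 0) noise_sd0 / sqrt(dose_per_image) else 0
  images <- array(0, c(n, n, k))
  for (i in seq_len(k)) {
    rot <- rigid_transform(rot_y(tilt_deg[i]))
    proj <- rowSums(rotate_volume(volume, rot)$grid, dims = 2)
    if (!is.null(ctf)) {
      s <- freq_grid2d(n, vs)
      proj <- Re(stats::fft(stats::fft(proj) * ctf_eval(s, defocus[i], ctf),
                            inverse = TRUE)) / (n * n)
    }
    if (any(shifts[i, ] != 0)) proj <- fourier_shift(proj, shifts[i, ])
    if (noise_sd > 0) proj <- proj + stats::rnorm(n * n, 0, noise_sd)
    images[, , i] <- proj
  }
  structure(list(images = images, tilt_deg = tilt_deg, defocus_um = defocus,
                 dose_e_A2 = rep(dose_per_image, k), pixel_size_A = vs,
                 shifts = shifts),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf("tilt_series: %d images %d x %d px, %.3g A/px, tilt %g..%g deg, dose %.3g e/A^2 total\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              x$pixel_size_A, min(x$tilt_deg), max(x$tilt_deg),
              sum(x$dose_e_A2)))
  invisible(x)
}

#' Split a projection into simulated dose-fractionated movie frames
#'
#' Emulates a direct-detector movie: \code{k} copies sharing the projection
#' signal (scaled by 1/k) with independent noise and cumulative per-frame
#' drift; used to exercise frame alignment.
#'
#' @param projection 2D array (one clean projection).
#' @param k number of frames (detectors of the period used 4-7).
#' @param drift_px k x 2 matrix of per-frame shifts, or a scalar per-frame
#'   drift step applied cumulatively along a random direction.
#' @param noise_sd per-frame additive noise sd.
#' @param seed integer seed.
#' @return list(frames = list of 2D arrays, shifts = k x 2 true shifts).
#' @export
simulate_frame_stack <- function(projection, k = 5, drift_px = 1,
                                 noise_sd = 0, seed = 1) {
  set.seed(seed)
  if (is.matrix(drift_px)) {
    shifts <- drift_px
  } else {
    dir <- stats::rnorm(2); dir <- dir / sqrt(sum(dir^2))
    shifts <- outer(0:(k - 1), dir * drift_px)
  }
  frames <- vector("list", k)
  for (i in seq_len(k)) {
    f <- fourier_shift(projection / k, shifts[i, ])
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    frames[[i]] <- matrix(f, nrow(projection))
  }
  list(frames = frames, shifts = shifts)
}

#' Persist / load a tilt series as an MRC stack plus TSV sidecar
#'
#' The sidecar records image_index, tilt_deg, defocus_um, dose_e_per_A2 and
#' the true applied shifts.
#'
#' @param series \code{tilt_series}.
#' @param path base path; writes \code{<path>.mrc} and \code{<path>.tsv}.
#' @return \code{write_tilt_series} returns \code{path} invisibly;
#'   \code{read_tilt_series} the reconstructed \code{tilt_series}.
#' @export
write_tilt_series <- function(series, path) {
  d <- dim(series$images)
  write_mrc(density_map(series$images, series$pixel_size_A,
                        origin = c(0, 0, 0)),
            paste0(path, ".mrc"))
  tab <- data.frame(image_index = seq_len(d[3]),
                    tilt_deg = series$tilt_deg,
                    defocus_um = series$defocus_um,
                    dose_e_per_A2 = series$dose_e_A2,
                    true_shift_x = series$shifts[, 1],
                    true_shift_y = series$shifts[, 2])
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_tilt_series
#' @export
read_tilt_series <- function(path) {
  vol <- read_mrc(paste0(path, ".mrc"))
  tab <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  structure(list(images = vol$grid, tilt_deg = tab$tilt_deg,
                 defocus_um = tab$defocus_um, dose_e_A2 = tab$dose_e_per_A2,
                 pixel_size_A = vol$voxel_size,
                 shifts = cbind(tab$true_shift_x, tab$true_shift_y)),
            class = "tilt_series")
}
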