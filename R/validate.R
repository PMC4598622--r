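#' Resolution estimation and map sharpening
#'
#' All resolution claims flow through the Fourier shell correlation: global
#' FSC between half-maps (threshold 0.5 for conventional random halves, 0.143
#' for independent gold-standard halves), cross-resolution against an
#' external reference (threshold 0.33), windowed local FSC, and
#' Rosenthal-Henderson B-factor sharpening of the resolution-limited map.
#'
#' @name validate
NULL

#' Fourier shell correlation between two maps
#'
#' Per concentric shell of one Fourier-voxel width:
#' \code{Re(sum(Fa conj(Fb))) / sqrt(sum|Fa|^2 sum|Fb|^2)} after optional
#' real-space masking.
#'
#' @param map_a,map_b \code{density_map}s of identical shape and voxel size.
#' @param mask optional \code{soft_mask}/array applied to both.
#' @return object of class \code{fsc_curve}: data.frame(freq_invA, fsc,
#'   n_vox) with attribute \code{voxel_size}.
#' @export
fsc_curve <- function(map_a, map_b, mask = NULL) {
  ga <- as_grid(map_a); gb <- as_grid(map_b)
  if (!identical(dim(ga), dim(gb)))
    stop("shape mismatch: ", paste(dim(ga), collapse = "x"), " vs ",
         paste(dim(gb), collapse = "x"))
  n <- check_cubic(ga, "fsc input")
  vs <- if (inherits(map_a, "density_map")) map_a$voxel_size else 1
  if (!is.null(mask)) {
    m <- as_mask_grid(mask)
    ga <- ga * m; gb <- gb * m
  }
  Fa <- stats::fft(ga); Fb <- stats::fft(gb)
  shell <- shell_index(n)
  nsh <- n / 2
  num <- tapply_sum(Re(Fa * Conj(Fb)), shell, nsh)
  pa <- tapply_sum(Mod(Fa)^2, shell, nsh)
  pb <- tapply_sum(Mod(Fb)^2, shell, nsh)
  cnt <- tapply_sum(rep(1, length(shell)), shell, nsh)
  fsc <- num / sqrt(pmax(pa * pb, 1e-300))
  out <- data.frame(freq_invA = (seq_len(nsh) - 0.5) / (n * vs),
                    fsc = pmax(-1, pmin(1, fsc)), n_vox = cnt)
  attr(out, "voxel_size") <- vs
  class(out) <- c("fsc_curve", "data.frame")
  out
}

# shell index (1..n/2, 0 = discard) per Fourier voxel, cached
shell_index <- function(n) {
  key <- paste0("shl", n)
  if (!is.null(.tomo_cache[[key]])) return(.tomo_cache[[key]])
  g <- freq_grids(n)
  idx <- 1 + floor(g$kr * n)                # shell of width 1 Fourier voxel
  idx[idx > n / 2] <- 0L
  .tomo_cache[[key]] <- idx
  idx
}

tapply_sum <- function(x, idx, nsh) {
  out <- numeric(nsh)
  s <- rowsum(as.vector(x), as.vector(idx))
  lab <- as.integer(rownames(s))
  keep <- lab >= 1 & lab <= nsh
  out[lab[keep]] <- s[keep]
  out
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.143, ...) {
  graphics::plot(x$freq_invA, x$fsc, type = "l", xlab = "frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Finds the first crossing below the threshold by linear interpolation
#' between shells; if the curve never crosses, the Nyquist-limit resolution is
#' returned flagged as a bound.
#'
#' @param curve \code{fsc_curve} (or data.frame with freq_invA and fsc).
#' @param threshold FSC threshold in (0, 1): 0.5 conventional halves, 0.143
#'   gold standard, 0.33 cross-resolution.
#' @param voxel_size A/voxel (for the Nyquist bound).
#' @return list(resolution_A, freq_invA, is_bound).
#' @export
resolution_at_threshold <- function(curve, threshold, voxel_size) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (nrow(curve) == 0) stop("empty FSC curve")
  f <- curve$freq_invA; y <- curve$fsc
  below <- which(y < threshold)
  below <- below[below > 1]                 # first shell is same-object ~ 1
  if (length(below) == 0)
    return(list(resolution_A = 2 * voxel_size, freq_invA = 1 / (2 * voxel_size),
                is_bound = TRUE))
  i <- below[1]
  f_cross <- if (i == 1) f[1] else {
    f[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) * (f[i] - f[i - 1])
  }
  list(resolution_A = 1 / f_cross, freq_invA = f_cross, is_bound = FALSE)
}

#' Windowed local resolution map
#'
#' For each window position on a stride grid, the two half-maps are windowed
#' (raised-cosine apodization over the outer 20 percent of the box),
#' correlated per shell, and the FSC = 0.5 resolution assigned to the window
#' center; intermediate voxels take the nearest node's value.
#'
#' @param map_a,map_b half-maps.
#' @param box_vox window edge (default 20, >= 8).
#' @param stride node spacing in voxels (default box_vox / 2).
#' @return list(map = \code{density_map} of local resolution (A), box_vox,
#'   stride).
#' @export
local_resolution <- function(map_a, map_b, box_vox = 20, stride = NULL) {
  if (box_vox < 8) stop("box size below 8 voxels gives unreliable shells")
  if (box_vox %% 2 != 0) stop("box size must be even")
  ga <- as_grid(map_a); gb <- as_grid(map_b)
  n <- check_cubic(ga)
  vs <- if (inherits(map_a, "density_map")) map_a$voxel_size else 1
  if (is.null(stride)) stride <- box_vox / 2
  win <- tukey_window3(box_vox, 0.2)
  starts <- unique(pmin(seq(1, n - box_vox + 1, by = stride), n - box_vox + 1))
  nodes <- expand.grid(x = starts, y = starts, z = starts)
  vals <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    xs <- nodes$x[i]:(nodes$x[i] + box_vox - 1)
    ys <- nodes$y[i]:(nodes$y[i] + box_vox - 1)
    zs <- nodes$z[i]:(nodes$z[i] + box_vox - 1)
    a <- density_map(ga[xs, ys, zs] * win, vs)
    b <- density_map(gb[xs, ys, zs] * win, vs)
    vals[i] <- resolution_at_threshold(fsc_curve(a, b), 0.5, vs)$resolution_A
  }
  # nearest-node fill: snap each voxel to its nearest node center per axis
  nodes_arr <- array(vals, rep(length(starts), 3))
  centers1d <- starts + box_vox / 2 - 0.5
  cuts <- c(-Inf, (centers1d[-1] + centers1d[-length(centers1d)]) / 2)
  snap <- findInterval(seq_len(n), cuts)
  out <- nodes_arr[snap, snap, snap, drop = FALSE]
  list(map = density_map(array(out, rep(n, 3)), vs), box_vox = box_vox,
       stride = stride)
}

#' B-factor sharpening with resolution-limited low-pass
#'
#' Fourier amplitudes are scaled by \code{exp(-B s^2 / 4)} with s in 1/A
#' (negative B amplifies high frequencies, the Rosenthal-Henderson
#' convention), then low-pass filtered at the cutoff with a soft Gaussian
#' edge.
#'
#' @param map \code{density_map}.
#' @param b_factor_A2 B-factor in A^2 (the deposited maps used -500).
#' @param resolution_cutoff_A low-pass cutoff (>= 2 voxels).
#' @return sharpened \code{density_map}.
#' @export
sharpen <- function(map, b_factor_A2, resolution_cutoff_A) {
  grid <- as_grid(map)
  n <- check_cubic(grid)
  vs <- map$voxel_size
  if (resolution_cutoff_A < 2 * vs)
    stop("cutoff beyond Nyquist (", 2 * vs, " A)")
  g <- freq_grids(n)
  s <- g$kr / vs
  filt <- exp(-b_factor_A2 * s^2 / 4) *
    as.vector(band_mask(n, vs, Inf, resolution_cutoff_A))
  out <- apply_fourier_filter(grid, array(filt, rep(n, 3)))
  density_map(out, vs, map$origin)
}
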