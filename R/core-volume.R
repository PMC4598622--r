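#' 3D density maps
#'
#' The universal volume currency of the package: a 3D scalar grid with an
#' isotropic physical voxel size in Angstrom.  All volumes handled by the
#' rotation/Fourier machinery are cubic with an even edge length so that the
#' Fourier center is unambiguous; the rotation center is the voxel
#' \code{floor(n/2)} (0-based), i.e. index \code{floor(n/2) + 1} in R.
#' Physical position of voxel index i (0-based) is \code{origin + i * voxel_size};
#' the default origin places the rotation-center voxel at the physical origin.
#'
#' @param grid 3D numeric array (nx x ny x nz), finite values.
#' @param voxel_size positive voxel edge, Angstrom.
#' @param origin physical coordinate of voxel (0,0,0), Angstrom; default
#'   \code{-floor(dim/2) * voxel_size}.
#' @return object of class \code{density_map}.
#' @export
density_map <- function(grid, voxel_size, origin = NULL) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number (Angstrom)")
  if (!all(is.finite(grid))) stop("density grid contains non-finite values")
  if (is.null(origin)) origin <- -floor(dim(grid) / 2) * voxel_size
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_map: %d x %d x %d voxels, %.4g A/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

as_grid <- function(x) if (inherits(x, "density_map")) x$grid else x

check_cubic <- function(grid, what = "volume") {
  d <- dim(grid)
  if (length(unique(d)) != 1)
    stop(what, " must be cubic, got shape ", paste(d, collapse = " x "))
  if (d[1] %% 2 != 0)
    stop(what, " edge length must be even, got ", d[1])
  invisible(d[1])
}

#' 1-based index of the rotation-center voxel of an n-length axis
#' @param n axis length.
#' @return integer index.
#' @export
vol_center <- function(n) floor(n / 2) + 1

#' Trilinear sampling of a 3D grid at fractional voxel coordinates
#'
#' Coordinates are 1-based voxel indices; points outside the grid return
#' \code{fill}.
#'
#' @param grid 3D array.
#' @param xi,yi,zi equal-length numeric vectors of coordinates.
#' @param fill value for out-of-bounds points.
#' @return numeric vector of sampled values.
#' @export
trilinear_sample <- function(grid, xi, yi, zi, fill = 0) {
  d <- dim(grid)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  # points exactly on the top face belong to the last cell
  x0[x0 == d[1] & xi <= d[1]] <- d[1] - 1
  y0[y0 == d[2] & yi <= d[2]] <- d[2] - 1
  z0[z0 == d[3] & zi <= d[3]] <- d[3] - 1
  fx <- xi - x0;   fy <- yi - y0;   fz <- zi - z0
  ok <- x0 >= 1 & x0 < d[1] & y0 >= 1 & y0 < d[2] & z0 >= 1 & z0 < d[3]
  out <- rep(fill, length(xi))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  nx <- d[1]; nxy <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * nx + (z0 - 1) * nxy
  v <- (grid[i000]            * (1 - fx) + grid[i000 + 1]            * fx) * (1 - fy) * (1 - fz) +
       (grid[i000 + nx]       * (1 - fx) + grid[i000 + nx + 1]       * fx) * fy       * (1 - fz) +
       (grid[i000 + nxy]      * (1 - fx) + grid[i000 + nxy + 1]      * fx) * (1 - fy) * fz +
       (grid[i000 + nx + nxy] * (1 - fx) + grid[i000 + nx + nxy + 1] * fx) * fy       * fz
  out[ok] <- v
  out
}

# cached 1-based index grids (as vectors) for an n^3 volume
.tomo_cache <- new.env(parent = emptyenv())

voxel_index_grids <- function(n) {
  key <- paste0("idx", n)
  if (!is.null(.tomo_cache[[key]])) return(.tomo_cache[[key]])
  ix <- rep.int(seq_len(n), n * n)
  iy <- rep.int(rep(seq_len(n), each = n), n)
  iz <- rep(seq_len(n), each = n * n)
  g <- list(x = ix, y = iy, z = iz)
  .tomo_cache[[key]] <- g
  g
}

#' Rigid transform of a density map
#'
#' Resamples the map under a rigid transform by inverse mapping with trilinear
#' interpolation about the rotation-center voxel.  The transform is applied in
#' the "forward" sense: a feature at physical position x moves to
#' \code{R x + t}.  Out-of-bounds voxels are filled with the map mean.
#'
#' @param map \code{density_map} (cubic, even edge).
#' @param rot \code{rigid_transform}; translation in Angstrom.
#' @return transformed \code{density_map} on the same grid.
#' @export
rotate_volume <- function(map, rot) {
  grid <- as_grid(map)
  vs <- if (inherits(map, "density_map")) map$voxel_size else 1
  n <- check_cubic(grid, "rotate_volume input")
  c0 <- vol_center(n)
  idx <- voxel_index_grids(n)
  t_vox <- rot$translation / vs
  Rinv <- t(rot$rotation)
  # source coordinate = Rinv %*% (x - c - t) + c
  xs <- idx$x - c0 - t_vox[1]
  ys <- idx$y - c0 - t_vox[2]
  zs <- idx$z - c0 - t_vox[3]
  sx <- Rinv[1, 1] * xs + Rinv[1, 2] * ys + Rinv[1, 3] * zs + c0
  sy <- Rinv[2, 1] * xs + Rinv[2, 2] * ys + Rinv[2, 3] * zs + c0
  sz <- Rinv[3, 1] * xs + Rinv[3, 2] * ys + Rinv[3, 3] * zs + c0
  vals <- trilinear_sample(grid, sx, sy, sz, fill = mean(grid))
  out <- array(vals, dim = c(n, n, n))
  if (inherits(map, "density_map")) density_map(out, vs, map$origin) else out
}

#' Integer-voxel translation helper (wraps nothing, fills with value)
#' @keywords internal
shift_volume_real <- function(grid, shift_vox, fill = 0) {
  n <- dim(grid)
  out <- array(fill, n)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift_vox[a]
    dst[[a]] <- seq(max(1, 1 + s), min(n[a], n[a] + s))
    src[[a]] <- dst[[a]] - s
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- grid[src[[1]], src[[2]], src[[3]]]
  out
}

#' Soft-edged spherical mask
#'
#' Value 1 inside \code{radius_vox}, raised-cosine falloff over
#' \code{edge_width} voxels, 0 beyond.
#'
#' @param n cube edge (voxels).
#' @param radius_vox inner radius in voxels.
#' @param edge_width cosine-edge width in voxels (default 3).
#' @param center length-3 center (1-based voxel index); default rotation center.
#' @return 3D array in [0, 1].
#' @export
soft_sphere_mask <- function(n, radius_vox, edge_width = 3, center = NULL) {
  if (is.null(center)) center <- rep(vol_center(n), 3)
  idx <- voxel_index_grids(n)
  r <- sqrt((idx$x - center[1])^2 + (idx$y - center[2])^2 + (idx$z - center[3])^2)
  m <- numeric(length(r))
  m[r <= radius_vox] <- 1
  edge <- r > radius_vox & r < radius_vox + edge_width
  m[edge] <- 0.5 * (1 + cos(pi * (r[edge] - radius_vox) / edge_width))
  array(m, dim = c(n, n, n))
}

#' Soft mask constructor with validity checks
#'
#' @param grid 3D array with values in [0, 1].
#' @param edge_width cosine-edge width used to build it (bookkeeping).
#' @return object of class \code{soft_mask}.
#' @export
soft_mask <- function(grid, edge_width = 3) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (min(grid) < -1e-9 || max(grid) > 1 + 1e-9)
    stop("soft mask values must lie in [0, 1]")
  structure(list(grid = grid, edge_width = edge_width), class = "soft_mask")
}

as_mask_grid <- function(m) {
  if (inherits(m, "soft_mask")) m$grid else if (inherits(m, "density_map")) m$grid else m
}

#' Pearson correlation of two volumes
#' @param a,b arrays or \code{density_map}s of identical shape.
#' @return correlation coefficient.
#' @export
map_correlation <- function(a, b) {
  stats::cor(as.vector(as_grid(a)), as.vector(as_grid(b)))
}

#' Block-average binning of a 2D or 3D array by an integer factor
#' @param x array; each dimension must be divisible by \code{factor}.
#' @param factor integer binning factor.
#' @return binned array.
#' @export
bin_array <- function(x, factor) {
  if (factor == 1) return(x)
  d <- dim(x)
  if (any(d %% factor != 0)) stop("dimensions not divisible by binning factor")
  if (length(d) == 2) {
    x <- array(x, c(factor, d[1] / factor, factor, d[2] / factor))
    return(apply(x, c(2, 4), mean))
  }
  nd <- d / factor
  out <- array(0, nd)
  for (i in 0:(factor - 1)) for (j in 0:(factor - 1)) for (k in 0:(factor - 1)) {
    out <- out + x[seq(1 + i, d[1], factor), seq(1 + j, d[2], factor),
                   seq(1 + k, d[3], factor)]
  }
  out / factor^3
}
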