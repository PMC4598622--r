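#' Phantom specification for the ribosome-translocon particle
#'
#' Describes the two-part synthetic particle used throughout the package: a
#' large "body" (ribosome-like cluster of Gaussian lobes) riding on a smaller
#' membrane-embedded "foot" (translocon-like cluster), with optional
#' sub-densities present in a fraction of particles (an OST-like lumenal lobe
#' and a tRNA-like lobe in the intersubunit space) and named conformer
#' variants defined by per-domain rigid motions (e.g. a lateral-gate-open
#' translocon half).
#'
#' In the particle reference frame the membrane normal is +z: the body sits
#' at positive z, the foot at negative z with its center a fixed offset below
#' the particle origin, so a membrane-bound particle has its foot in the
#' membrane shell when the frame -z axis points at the vesicle center.
#'
#' @param particle_diameter_A overall particle diameter (default 280 A,
#'   matching the ~25-30 nm ribosome-translocon footprint).
#' @param body_blob_count,foot_blob_count Gaussian lobes in body and foot
#'   (defaults 12 and 3); body lobes span coarse to fine widths so the
#'   phantom's power spectrum, like a ribosome's, extends to the working
#'   Nyquist frequency.
#' @param subdensities list of lists with elements \code{name},
#'   \code{offset} (length-3, particle frame, as a fraction of the particle
#'   diameter), \code{radius} (fraction of the diameter), \code{occupancy} in
#'   [0,1].  Defaults: an OST-like lumenal lobe at occupancy 0.55 and a
#'   tRNA-like lobe in the intersubunit space at occupancy 0.29, the
#'   abundances observed for the native translocon data set.
#' @param conformers named list of per-domain \code{rigid_transform}s; each
#'   entry defines a variant in which the "foot_mobile" sub-cluster is moved
#'   by the given transform (e.g. \code{gate_open}).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(particle_diameter_A = 280,
                         body_blob_count = 12,
                         foot_blob_count = 3,
                         subdensities = list(
                           list(name = "OST", offset = c(0.20, 0, -0.35),
                                radius = 0.085, occupancy = 0.55),
                           list(name = "tRNA", offset = c(0, 0.11, 0.125),
                                radius = 0.10, occupancy = 0.29)),
                         conformers = list()) {
  stopifnot(particle_diameter_A > 0, body_blob_count >= 1, foot_blob_count >= 1)
  for (sd in subdensities) {
    if (sd$occupancy < 0 || sd$occupancy > 1)
      stop("occupancy for ", sd$name, " outside [0, 1]")
    if (sd$radius <= 0) stop("subdensity radius must be positive")
  }
  structure(list(particle_diameter_A = particle_diameter_A,
                 body_blob_count = body_blob_count,
                 foot_blob_count = foot_blob_count,
                 subdensities = subdensities,
                 conformers = conformers),
            class = "phantom_spec")
}

# Deterministic blob layout for a phantom spec: positions (A, particle frame),
# sigma (A), amplitude, domain tag.  The layout guarantees, per axis,
# |pos| + 3*sigma <= 0.55 * diameter, so any box with edge >= 1.1 * diameter
# holds the phantom.
phantom_blobs <- function(spec, seed) {
  set.seed(seed)
  d <- spec$particle_diameter_A
  bound <- 0.55 * d
  body_r <- 0.30 * d                      # body cluster radius
  body_c <- c(0, 0, 0.12 * d)             # body center above origin
  foot_c <- c(0, 0, -0.35 * d)            # foot center below origin (membrane)
  blobs <- list()
  # body: one anchoring central lobe plus satellites spanning coarse-to-fine
  # sizes (a real ribosome has structure at every scale down to the pixel),
  # laid out asymmetrically by seed
  blobs[[1]] <- list(pos = body_c, sigma = 0.13 * d, amp = 1.0, domain = "body")
  for (i in seq_len(spec$body_blob_count - 1)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    sg <- stats::runif(1, 0.035, 0.095) * d
    r_max <- min(body_r, bound - 3 * sg - max(abs(body_c)))
    r <- stats::runif(1, 0.3, 0.95) * max(r_max, 0)
    blobs[[length(blobs) + 1]] <-
      list(pos = body_c + u * r, sigma = sg,
           amp = stats::runif(1, 0.6, 0.9), domain = "body")
  }
  # foot: compact cluster in the membrane plane; tagged mobile/static so
  # conformers can move part of it (lateral-gate analog)
  for (i in seq_len(spec$foot_blob_count)) {
    ang <- 2 * pi * (i - 1) / spec$foot_blob_count
    pos <- foot_c + c(cos(ang), sin(ang), 0) * 0.10 * d
    blobs[[length(blobs) + 1]] <-
      list(pos = pos, sigma = 0.06 * d, amp = 0.8,
           domain = if (i == 1) "foot_mobile" else "foot_static")
  }
  for (sd in spec$subdensities) {
    blobs[[length(blobs) + 1]] <-
      list(pos = sd$offset * d, sigma = sd$radius * d / 1.5, amp = 0.7,
           domain = sd$name)
  }
  blobs
}

# render a list of blobs (positions in A relative to box center) into a grid
render_blobs <- function(blobs, n, voxel_size, center_vox = NULL) {
  if (is.null(center_vox)) center_vox <- rep(vol_center(n), 3)
  grid <- array(0, c(n, n, n))
  for (b in blobs) {
    c_vox <- center_vox + b$pos / voxel_size
    s_vox <- b$sigma / voxel_size
    lo <- pmax(1, floor(c_vox - 3.5 * s_vox))
    hi <- pmin(n, ceiling(c_vox + 3.5 * s_vox))
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    gx <- exp(-((xs - c_vox[1])^2) / (2 * s_vox^2))
    gy <- exp(-((ys - c_vox[2])^2) / (2 * s_vox^2))
    gz <- exp(-((zs - c_vox[3])^2) / (2 * s_vox^2))
    add <- b$amp * outer(outer(gx, gy), gz)
    grid[xs, ys, zs] <- grid[xs, ys, zs] + add
  }
  grid
}

#' Build phantom density maps for every conformer/occupancy variant
#'
#' Each variant map is a sum of Gaussian blobs on a cubic grid; variants
#' differ only by the presence of a sub-density or by the rigid motion of a
#' tagged domain.  Deterministic given \code{seed}.
#'
#' @param spec \code{phantom_spec}.
#' @param n cube edge in voxels (even); blobs must fit inside the box.
#' @param voxel_size A per voxel.
#' @param seed integer; fixes the blob layout.
#' @return list with elements \code{variants} (named list of
#'   \code{density_map}: \code{base}, one per sub-density, one per conformer),
#'   \code{blobs} (annotated layout), and \code{spec}.
#' @export
build_phantom <- function(spec, n = 32, voxel_size = 10, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), n %% 2 == 0)
  blobs <- phantom_blobs(spec, seed)
  half <- n / 2 * voxel_size
  for (b in blobs) {
    if (any(abs(b$pos) + 3 * b$sigma > half))
      stop("blob of domain '", b$domain, "' exceeds the box: |pos| + 3 sigma = ",
           max(abs(b$pos) + 3 * b$sigma), " A > half-box ", half, " A")
  }
  subnames <- vapply(spec$subdensities, `[[`, "", "name")
  core <- Filter(function(b) !(b$domain %in% subnames), blobs)
  variants <- list(base = density_map(render_blobs(core, n, voxel_size),
                                      voxel_size))
  for (nm in subnames) {
    withsub <- Filter(function(b) !(b$domain %in% setdiff(subnames, nm)), blobs)
    variants[[paste0("with_", nm)]] <-
      density_map(render_blobs(withsub, n, voxel_size), voxel_size)
  }
  for (cn in names(spec$conformers)) {
    tr <- spec$conformers[[cn]]
    moved <- lapply(core, function(b) {
      if (b$domain == "foot_mobile") b$pos <- apply_transform(tr, b$pos)
      b
    })
    variants[[cn]] <- density_map(render_blobs(moved, n, voxel_size), voxel_size)
  }
  list(variants = variants, blobs = blobs, spec = spec)
}
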