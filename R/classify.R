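#' Constrained-PCA classification of subtomograms
#'
#' Focused, missing-wedge-compensated principal component analysis: each
#' aligned subtomogram is rotated to the reference frame, its unmeasured
#' Fourier region filled with the current average's values (wedge
#' compensation), band-limited, and the voxels under a focus mask extracted
#' as a feature vector; PCA of the centered vectors gives per-particle
#' component scores that are clustered with seeded k-means.  Used with a
#' membrane-proximal mask (round 1: bound vs unbound/junk), a translocon
#' focus (round 2) and a tRNA-site focus.
#'
#' @name classify
NULL

#' @rdname classify
#' @param subtomos list of \code{density_map}s.
#' @param records aligned particle table (poses applied before extraction).
#' @param average current \code{density_map} average used for wedge filling.
#' @param focus_mask \code{soft_mask}/array over the region of interest.
#' @param band optional c(low_res_A, high_res_A) bandpass.
#' @param n_components number of principal components to keep (default 10).
#' @return list(features = n x n_components score matrix, variance =
#'   explained-variance spectrum, mask_voxels = count).
#' @export
cpca_features <- function(subtomos, records, average, focus_mask, band = NULL,
                          n_components = 10) {
  N <- nrow(records)
  if (n_components >= N)
    stop("n_components must be smaller than the particle count")
  m <- as_mask_grid(focus_mask)
  keep <- which(as.vector(m) > 0.1)
  if (length(keep) == 0) stop("empty focus mask")
  avg <- as_grid(average)
  n <- dim(avg)[1]
  vs <- if (inherits(average, "density_map")) average$voxel_size else 1
  Favg <- stats::fft(avg)
  bnd <- if (!is.null(band)) band_mask(n, vs, band[1], band[2]) else NULL
  X <- matrix(0, N, length(keep))
  mv <- as.vector(m)[keep]
  for (r in seq_len(N)) {
    i <- records$particle[r]
    pose <- record_pose(records, r)
    al <- rotate_volume(density_map(as_grid(subtomos[[i]]), vs),
                        invert_transform(pose))$grid
    W <- rotated_wedge_mask(n, wedge_spec(records$wedge_min[r],
                                          records$wedge_max[r]),
                            pose$rotation)
    F <- stats::fft(al) * W + Favg * (1 - W)     # fill missing wedge
    if (!is.null(bnd)) F <- F * bnd
    v <- Re(stats::fft(F, inverse = TRUE)) / n^3
    X[r, ] <- v[keep] * mv
  }
  # scale-invariance across the data set: normalize each vector set globally
  X <- sweep(X, 2, colMeans(X))
  sdev_all <- sqrt(sum(X^2) / (N * length(keep)))
  if (sdev_all > 0) X <- X / sdev_all
  pc <- stats::prcomp(X, center = FALSE, rank. = n_components)
  list(features = pc$x[, seq_len(n_components), drop = FALSE],
       variance = pc$sdev^2, mask_voxels = length(keep))
}

#' Seeded k-means clustering of CPCA features
#'
#' Best of \code{n_restarts} seeded k-means runs by within-cluster sum of
#' squares; cluster labels are renumbered by decreasing class size so label 1
#' is always the majority class.
#'
#' @param features n x p feature matrix.
#' @param k number of classes (>= 2, <= particles).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @return integer labels of length n.
#' @export
kmeans_classify <- function(features, k, n_restarts = 10, seed = 1) {
  features <- as.matrix(features)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(features)) stop("k exceeds the number of particles")
  if (max(apply(features, 2, stats::sd)) < 1e-12) {
    warning("degenerate features: all particles identical, single cluster")
    return(rep(1L, nrow(features)))
  }
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = n_restarts,
                      iter.max = 100)
  sizes <- table(km$cluster)
  remap <- integer(k)
  remap[order(sizes, decreasing = TRUE)] <- seq_len(k)
  remap[km$cluster]
}

#' Class averages, sizes and fractions
#'
#' Wedge-compensated average per class (via
#' \code{\link{average_subtomograms}}), class sizes/fractions, and a
#' per-class resolution estimate (FSC = 0.5 between random class halves).
#'
#' @param subtomos list of \code{density_map}s.
#' @param records aligned particle table.
#' @param labels integer class label per particle.
#' @param seed seed for the per-class half splits.
#' @return object of class \code{class_result}: list(labels, sizes,
#'   fractions, maps = list of \code{density_map} or NULL for empty classes,
#'   resolution_A per class).
#' @export
class_averages <- function(subtomos, records, labels, seed = 1) {
  N <- nrow(records)
  stopifnot(length(labels) == N)
  records$class_label <- labels
  ks <- sort(unique(labels))
  sizes <- vapply(ks, function(k) sum(labels == k), 0L)
  fractions <- sizes / N
  maps <- vector("list", length(ks))
  res <- rep(NA_real_, length(ks))
  set.seed(seed)
  for (j in seq_along(ks)) {
    rows <- which(labels == ks[j])
    if (length(rows) == 0) next
    maps[[j]] <- average_subtomograms(subtomos, records[rows, ])
    if (length(rows) >= 4) {
      split <- sample(rep(0:1, length.out = length(rows)))
      a <- average_subtomograms(subtomos, records[rows[split == 0], ])
      b <- average_subtomograms(subtomos, records[rows[split == 1], ])
      res[j] <- resolution_at_threshold(fsc_curve(a, b), 0.5,
                                        a$voxel_size)$resolution_A
    }
  }
  structure(list(labels = labels, classes = ks, sizes = sizes,
                 fractions = fractions, maps = maps, resolution_A = res),
            class = "class_result")
}

#' @export
print.class_result <- function(x, ...) {
  for (j in seq_along(x$classes))
    cat(sprintf("class %d: n = %d (%.1f%%), resolution %.1f A\n",
                x$classes[j], x$sizes[j], 100 * x$fractions[j],
                x$resolution_A[j]))
  invisible(x)
}
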