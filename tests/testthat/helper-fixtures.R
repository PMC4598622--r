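# Shared fixture builders.  Everything is generated in code at test time;
# seeds are fixed so quoted statistics are reproducible.

# smooth random volume (band-limited white noise)
smooth_map <- function(n = 32, voxel_size = 10, res_A = 80, seed = 1) {
  set.seed(seed)
  m <- density_map(array(rnorm(n^3), rep(n, 3)), voxel_size)
  lowpass(m, res_A)
}

# standard small phantom used across alignment/classification tests
fixture_phantom <- function(n = 32, voxel_size = 12, diameter = 250, seed = 7) {
  spec <- phantom_spec(particle_diameter_A = diameter)
  build_phantom(spec, n = n, voxel_size = voxel_size, seed = seed)
}

# particle-frame blob layout without sub-densities
fixture_blobs <- function(diameter = 250, seed = 7, with = character()) {
  spec <- phantom_spec(particle_diameter_A = diameter)
  keep <- c("body", "foot_mobile", "foot_static", with)
  Filter(function(b) b$domain %in% keep, tomopipe:::phantom_blobs(spec, seed))
}

# render one particle at a given pose into an n^3 box (analytic: no
# interpolation), optionally wedge-filtered and noisy
render_particle <- function(blobs, R = diag(3), shift_A = c(0, 0, 0), n = 32,
                            voxel_size = 12, wedge = NULL, noise_sd = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bl <- lapply(blobs, function(b) {
    b$pos <- as.numeric(R %*% b$pos) + shift_A
    b
  })
  g <- tomopipe:::render_blobs(bl, n, voxel_size)
  if (!is.null(wedge))
    g <- tomopipe:::apply_fourier_filter(g, make_wedge_mask(n, wedge))
  if (noise_sd > 0) g <- g + rnorm(n^3, 0, noise_sd)
  density_map(array(g, rep(n, 3)), voxel_size)
}

random_rotation <- function() {
  euler_to_matrix(runif(1, 0, 360), acos(runif(1, -1, 1)) * 180 / pi,
                  runif(1, 0, 360))
}

# set of subtomograms with known poses for averaging/classification tests
fixture_particle_set <- function(N, blobs, n = 24, voxel_size = 12,
                                 wedge = wedge_spec(-20, 20), noise_sd = 0,
                                 seed = 1) {
  set.seed(seed)
  subs <- vector("list", N)
  rots <- vector("list", N)
  for (i in seq_len(N)) {
    rots[[i]] <- random_rotation()
    subs[[i]] <- render_particle(blobs, rots[[i]], n = n,
                                 voxel_size = voxel_size, wedge = wedge,
                                 noise_sd = noise_sd)
  }
  recs <- particle_records(N, wedge)
  for (i in seq_len(N))
    recs <- tomopipe:::set_record_pose(recs, i, rigid_transform(rots[[i]]))
  list(subtomos = subs, records = recs, rotations = rots)
}
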