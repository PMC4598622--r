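test_that("the SO(3) grid covers orientation space at the requested spacing", {
  g <- so3_grid(12.85)
  # node count: ~4 pi / inc^2 sphere directions x ceil(360 / inc) in-plane
  inc <- 12.85 * pi / 180
  expect_equal(nrow(g), ceiling(4 * pi / inc^2) * ceiling(360 / 12.85))
  expect_true(all(g$theta >= 0 & g$theta <= 180))
  # coverage: every random direction has a grid direction within ~1 spacing
  dirs <- t(vapply(seq_len(nrow(g) / ceiling(360 / 12.85)), function(i) {
    R <- euler_to_matrix(g$phi[(i - 1) * ceiling(360 / 12.85) + 1],
                         g$theta[(i - 1) * ceiling(360 / 12.85) + 1], 0)
    as.numeric(R %*% c(0, 0, 1))
  }, numeric(3)))
  set.seed(1)
  for (t in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    ang <- acos(pmax(-1, pmin(1, dirs %*% u))) * 180 / pi
    expect_lt(min(ang), 1.5 * 12.85)
  }
  # spacing scales: a 2x finer grid has ~4x the sphere nodes
  g2 <- so3_grid(12.85 / 2)
  expect_gt(nrow(g2) / nrow(g), 6)
  expect_error(so3_grid(0), "positive")
  expect_error(so3_grid(-5), "positive")
})

test_that("peak extraction is greedy with spherical suppression", {
  # -Inf background: only the planted maxima are eligible picks
  sc <- array(-Inf, c(20, 20, 20))
  sc[5, 5, 5] <- 1.0
  sc[6, 5, 5] <- 0.9      # inside the exclusion sphere of the first peak
  sc[15, 15, 15] <- 0.8
  pks <- extract_peaks(sc, 5, exclusion_radius_vox = 3)
  expect_equal(nrow(pks), 2)
  expect_equal(unlist(pks[1, c("x", "y", "z")], use.names = FALSE), c(5, 5, 5))
  expect_equal(unlist(pks[2, c("x", "y", "z")], use.names = FALSE),
               c(15, 15, 15))
  expect_equal(pks$score, c(1.0, 0.8))
  # a smaller radius lets the shoulder voxel through as its own peak
  pks2 <- extract_peaks(sc, 5, exclusion_radius_vox = 0.5)
  expect_equal(nrow(pks2), 3)
  # orientation attachment
  orient <- array(1L, dim(sc)); orient[15, 15, 15] <- 3L
  grid <- data.frame(phi = c(0, 10, 20), theta = c(0, 5, 10),
                     psi = c(0, 0, 0))
  pk3 <- extract_peaks(sc, 2, 3, orient = orient, grid = grid)
  expect_equal(pk3$phi, c(0, 20))
  expect_error(extract_peaks(sc, 0, 3), "n_peaks")
})

test_that("template matching localizes planted particles and their poses", {
  set.seed(4)
  n <- 36; vs <- 12
  blobs <- fixture_blobs(diameter = 200, seed = 7)
  wedge <- wedge_spec(-60, 60)
  inc <- 40
  grid <- so3_grid(inc)
  # plant two copies at grid orientations so the arg-max pose is testable
  truth <- data.frame(x = c(12, 26), y = c(13, 25), z = c(19, 16),
                      gi = c(5, 47))
  tomo <- array(0, rep(n, 3))
  for (i in 1:2) {
    R <- euler_to_matrix(grid$phi[truth$gi[i]], grid$theta[truth$gi[i]],
                         grid$psi[truth$gi[i]])
    shift_A <- (unlist(truth[i, c("x", "y", "z")]) - vol_center(n)) * vs
    tomo <- tomo + render_particle(blobs, R, shift_A, n = n,
                                   voxel_size = vs)$grid
  }
  tomo <- tomopipe:::apply_fourier_filter(tomo, make_wedge_mask(n, wedge))
  tomo <- tomo + rnorm(n^3, 0, 0.02 * sd(tomo))
  tmpl <- render_particle(blobs, n = 18, voxel_size = vs)
  msk <- soft_sphere_mask(18, 8, 2)
  mt <- match_template(density_map(array(tomo, rep(n, 3)), vs), tmpl, msk,
                       angular_increment_deg = inc, wedge = wedge)
  expect_s3_class(mt$scores, "density_map")
  expect_true(all(mt$scores$grid >= -1 & mt$scores$grid <= 1))
  pks <- extract_peaks(mt$scores, 2, exclusion_radius_vox = 8,
                       orient = mt$orient, grid = mt$grid)
  # both particles found within 2 voxels
  for (i in 1:2) {
    d <- sqrt(rowSums(sweep(as.matrix(pks[, c("x", "y", "z")]), 2,
                            unlist(truth[i, c("x", "y", "z")]))^2))
    expect_lt(min(d), 2)
    j <- which.min(d)
    Rt <- euler_to_matrix(grid$phi[truth$gi[i]], grid$theta[truth$gi[i]],
                          grid$psi[truth$gi[i]])
    Re_ <- euler_to_matrix(pks$phi[j], pks$theta[j], pks$psi[j])
    expect_lt(rotation_distance(Rt, Re_), 1.5 * inc)
  }
  # affine intensity invariance: scaling and offsetting the tomogram does not
  # change the normalized scores
  mt2 <- match_template(density_map(array(3 * tomo + 7, rep(n, 3)), vs), tmpl,
                        msk, angular_increment_deg = inc, wedge = wedge)
  expect_lt(max(abs(mt2$scores$grid - mt$scores$grid)), 1e-6)
  # contract errors
  expect_error(match_template(tmpl, tmpl, msk, inc, wedge), "smaller")
  expect_error(match_template(density_map(array(tomo, rep(n, 3)), vs), tmpl,
                              array(0, rep(18, 3)), inc, wedge), "empty")
})

test_that("extract_peaks subvoxel interpolation recovers fractional maxima", {
  n <- 16
  x0 <- c(7.3, 9.6, 8.25)
  idx <- tomopipe:::voxel_index_grids(n)
  sc <- 5 - 0.05 * ((idx$x - x0[1])^2 + (idx$y - x0[2])^2 + (idx$z - x0[3])^2)
  pk <- extract_peaks(array(sc, rep(n, 3)), 1, exclusion_radius_vox = 3,
                      subvoxel = TRUE)
  # a separable quadratic is interpolated exactly
  expect_equal(as.numeric(pk[1, c("x", "y", "z")]), x0, tolerance = 1e-9)
  # without subvoxel the same peak sits on the integer grid
  pk0 <- extract_peaks(array(sc, rep(n, 3)), 1, exclusion_radius_vox = 3)
  expect_equal(as.numeric(pk0[1, c("x", "y", "z")]), round(x0))
})

test_that("erase_bright_blobs removes beads and keeps protein-scale density", {
  n <- 32
  idx <- tomopipe:::voxel_index_grids(n)
  blob <- exp(-((idx$x - 10)^2 + (idx$y - 16)^2 + (idx$z - 16)^2) / (2 * 9))
  bead <- 10 * exp(-((idx$x - 24)^2 + (idx$y - 16)^2 + (idx$z - 16)^2) / 2)
  m <- density_map(array(blob + bead, rep(n, 3)), 10)
  out <- erase_bright_blobs(m)
  expect_s3_class(out, "density_map")
  expect_lt(out$grid[24, 16, 16], 1e-9)          # bead blanked
  expect_gt(out$grid[10, 16, 16], 0.9)           # blob untouched
  expect_error(erase_bright_blobs(m, threshold_frac = 1.5), "threshold_frac")
})

test_that("render_membrane_shell peaks on the sphere at the requested offset", {
  n <- 32; vs <- 10
  sh <- render_membrane_shell(n, vs, radius_A = 100,
                              center_A = c(0, 0, -60), thickness_A = 40,
                              amp = 0.4)
  c0 <- vol_center(n)
  # along +z from the shifted center, density peaks 100 A from it
  prof <- sh$grid[c0, c0, ]
  zA <- (seq_len(n) - c0) * vs - (-60)
  expect_equal(zA[which.max(prof)], 100, tolerance = vs)
  expect_equal(max(sh$grid), 0.4, tolerance = 0.01)
  expect_error(render_membrane_shell(n, vs, radius_A = -5), "radius_A")
})
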