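test_that("rotated wedge masks are exact supports of rotated volumes", {
  n <- 32
  w <- wedge_spec(-30, 30)
  # identity rotation reproduces the axis-aligned mask
  expect_identical(rotated_wedge_mask(n, w, diag(3)), make_wedge_mask(n, w))
  # support tracking: rotate a wedge-limited volume and measure the Fourier
  # energy captured by the analytically rotated mask (vs the un-rotated one)
  v <- smooth_map(n, 10, 30, seed = 5)
  v$grid <- tomopipe:::apply_fourier_filter(v$grid * soft_sphere_mask(n, 10, 3),
                                            make_wedge_mask(n, w))
  R <- euler_to_matrix(25, 40, 10)
  y <- rotate_volume(v, rigid_transform(R))
  P <- Mod(stats::fft(y$grid))^2; P[1] <- 0
  cap <- function(m) sum(P * m) / sum(P)
  cap_rot <- cap(rotated_wedge_mask(n, w, t(R)))
  expect_gt(cap_rot, 0.9)                  # interpolation leaks a little
  expect_gt(cap_rot, cap(make_wedge_mask(n, w)) + 0.2)
  # rotation preserves the sampled solid-angle fraction within the Nyquist
  # ball (outside the ball the cube corners make the fraction anisotropic)
  ball <- tomopipe:::freq_grids(n)$kr <= 0.5
  f0 <- mean(make_wedge_mask(n, w)[ball])
  f1 <- mean(rotated_wedge_mask(n, w, t(R))[ball])
  expect_lt(abs(f1 - f0) / f0, 0.05)
  # masks are binary with DC always sampled
  m <- rotated_wedge_mask(n, w, t(R))
  expect_true(all(m %in% c(0, 1)))
  expect_equal(m[1, 1, 1], 1)
})

test_that("constrained cross-correlation is a normalized symmetric score", {
  a <- smooth_map(24, 10, 40, seed = 1)
  b <- smooth_map(24, 10, 40, seed = 2)
  w <- wedge_spec(-40, 40)
  expect_equal(constrained_cc(a, a, w, w), 1, tolerance = 1e-9)
  # affine scaling of either argument changes nothing (DC is excluded)
  a5 <- density_map(5 * a$grid + 2, 10)
  expect_equal(constrained_cc(a5, b, w, w), constrained_cc(a, b, w, w),
               tolerance = 1e-9)
  # symmetry
  expect_equal(constrained_cc(a, b, w, w), constrained_cc(b, a, w, w),
               tolerance = 1e-12)
  # negation flips the sign
  expect_equal(constrained_cc(density_map(-a$grid, 10), a, w, w), -1,
               tolerance = 1e-9)
  # independent band-limited noise scores near zero
  expect_lt(abs(constrained_cc(a, b, w, w)), 0.2)
  # band selection: maps identical below 60 A but not above score ~1 in the
  # low band and lower across the full band
  hi <- smooth_map(24, 10, 25, seed = 3)
  mix <- density_map(a$grid + 0.5 * (hi$grid - lowpass(hi, 60)$grid), 10)
  cc_low <- constrained_cc(a, mix, w, w, band = c(Inf, 60))
  cc_all <- constrained_cc(a, mix, w, w)
  expect_gt(cc_low, 0.99)
  expect_gt(cc_low, cc_all)
  expect_error(constrained_cc(a, smooth_map(32, 10, 40)), "identical")
})

test_that("particle records round-trip poses and persist as TSV", {
  recs <- particle_records(4, wedge_spec(-20, 20))
  expect_equal(nrow(recs), 4)
  expect_equal(recs$wedge_min, rep(-20, 4))
  pose <- rigid_transform(euler_to_matrix(40, 30, -20), c(5, -3, 2))
  recs <- tomopipe:::set_record_pose(recs, 2, pose)
  back <- tomopipe:::record_pose(recs, 2)
  expect_lt(rotation_distance(back$rotation, pose$rotation), 1e-9)
  expect_equal(back$translation, pose$translation, tolerance = 1e-12)
  f <- tempfile(fileext = ".tsv")
  write_particles(recs, f)
  r2 <- read_particles(f)
  expect_equal(r2$phi, recs$phi, tolerance = 1e-9)
  expect_equal(r2$tz, recs$tz, tolerance = 1e-9)
  expect_equal(r2$particle, recs$particle)
})

test_that("wedge-compensated averaging restores the missing wedge", {
  blobs <- fixture_blobs(diameter = 220, seed = 7)
  truth <- render_particle(blobs, n = 24, voxel_size = 12)
  # single particle, identity pose, near-full wedge: no resampling happens,
  # so the average reproduces the particle essentially exactly
  sub <- render_particle(blobs, n = 24, voxel_size = 12,
                         wedge = wedge_spec(-89, 89), seed = 2)
  one_rec <- particle_records(1, wedge_spec(-89, 89))
  avg1 <- average_subtomograms(list(sub), one_rec)
  expect_gt(map_correlation(avg1$grid, sub$grid - mean(sub$grid)), 0.999)
  # 24 random orientations under a +-40 wedge: orientations fill the missing
  # region, so the average tracks the unfiltered particle where any single
  # wedge-limited copy cannot
  ps <- fixture_particle_set(24, blobs, n = 24, wedge = wedge_spec(-40, 40),
                             seed = 3)
  avg <- average_subtomograms(ps$subtomos, ps$records)
  m <- soft_sphere_mask(24, 9, 2)
  cor_avg <- map_correlation(avg$grid * m, (truth$grid - mean(truth$grid)) * m)
  single <- rotate_volume(ps$subtomos[[1]],
                          invert_transform(tomopipe:::record_pose(ps$records, 1)))
  cor_one <- map_correlation(single$grid * m,
                             (truth$grid - mean(truth$grid)) * m)
  expect_gt(cor_avg, 0.95)
  expect_gt(cor_avg, cor_one)
  expect_error(average_subtomograms(ps$subtomos, ps$records[0, ]), "at least")
})

test_that("local alignment recovers known pose perturbations", {
  blobs <- fixture_blobs(diameter = 220, seed = 7)
  n <- 24; vs <- 12
  w <- wedge_spec(-60, 60)
  ref <- render_particle(blobs, n = n, voxel_size = vs)
  mask <- soft_sphere_mask(n, 9, 2)
  # pure translation
  R0 <- euler_to_matrix(30, 40, 10)
  sub_t <- render_particle(blobs, R0, shift_A = c(18, -12, 6), n = n,
                           voxel_size = vs, wedge = w)
  start <- rigid_transform(R0)
  res_t <- align_subtomogram(sub_t, w, ref, start, angular_step = 6,
                             angular_range = 6, mask = mask)
  expect_lt(max(abs(res_t$pose$translation - c(18, -12, 6))), 0.5 * vs)
  # rotation + translation from an 8-degree perturbed start: a single local
  # pass at a 32-cube halves the orientation error (the smooth phantom's
  # correlation landscape is flat, so single-shot accuracy is a few degrees;
  # iterative refinement against an evolving average does better)
  n2 <- 32
  blobs2 <- fixture_blobs(diameter = 250, seed = 7)
  ref2 <- render_particle(blobs2, n = n2, voxel_size = vs)
  mask2 <- soft_sphere_mask(n2, 13, 3)
  truthR <- R0 %*% axis_angle_matrix(c(1, 1, 0), 8)
  sub_r <- render_particle(blobs2, truthR, shift_A = c(6, 0, -6), n = n2,
                           voxel_size = vs, wedge = w)
  res_r <- align_subtomogram(sub_r, w, ref2, rigid_transform(R0),
                             angular_step = 4, angular_range = 12,
                             mask = mask2)
  expect_lt(rotation_distance(res_r$pose$rotation, truthR), 5)
  expect_lt(max(abs(res_r$pose$translation - c(6, 0, -6))), 0.5 * vs)
  # never worse than the input pose under its own objective
  in_score <- tomopipe:::score_pose(sub_r, w, ref2, rigid_transform(R0),
                                    NULL, mask2)
  expect_gte(res_r$score, in_score)
})

test_that("iterative refinement improves poses and logs a sane history", {
  blobs <- fixture_blobs(diameter = 220, seed = 7)
  n <- 24; vs <- 12
  w <- wedge_spec(-60, 60)
  ps <- fixture_particle_set(10, blobs, n = n, voxel_size = vs, wedge = w,
                             noise_sd = 0.02, seed = 8)
  # perturb the true poses by ~8 degrees / 1 voxel
  set.seed(9)
  recs <- ps$records
  for (i in 1:10) {
    p <- tomopipe:::record_pose(recs, i)
    p$rotation <- p$rotation %*% axis_angle_matrix(rnorm(3), 8)
    p$translation <- p$translation + runif(3, -vs, vs)
    recs <- tomopipe:::set_record_pose(recs, i, p)
  }
  ref0 <- lowpass(render_particle(blobs, n = n, voxel_size = vs), 40)
  mask <- soft_sphere_mask(n, 9, 2)
  out <- refine_iteratively(ps$subtomos, recs, ref0,
                            schedule = list(max_iterations = 2, mask = mask,
                                            initial_res_A = 40,
                                            polish_passes = 1),
                            mode = "conventional",
                            particle_diameter_A = 220, seed = 1)
  err0 <- err1 <- numeric(10)
  for (i in 1:10) {
    err0[i] <- rotation_distance(tomopipe:::record_pose(recs, i)$rotation,
                                 ps$rotations[[i]])
    err1[i] <- rotation_distance(tomopipe:::record_pose(out$records, i)$rotation,
                                 ps$rotations[[i]])
  }
  expect_lt(median(err1), median(err0) / 2)
  expect_true(all(c("iteration", "resolution_A", "angular_step_deg") %in%
                    names(out$history)))
  # the sampling rule: step_i = atan(res_{i-1} / D), floored at 1 degree
  expect_equal(out$history$angular_step_deg[1],
               max(1, atan(40 / 220) * 180 / pi), tolerance = 1e-9)
  expect_s3_class(out$average, "density_map")
  # gold-standard mode: fixed half sets, monotone resolution history
  gold <- refine_iteratively(ps$subtomos, recs, ref0,
                             schedule = list(max_iterations = 2, mask = mask,
                                             initial_res_A = 40,
                                             polish_passes = 1),
                             mode = "gold_standard",
                             particle_diameter_A = 220, seed = 2)
  expect_true(all(gold$records$half_set %in% 0:1))
  expect_equal(sort(unique(gold$records$half_set)), 0:1)
  expect_true(all(diff(gold$history$resolution_A) <= 1e-9))
  expect_equal(length(gold$half_averages), 2)
})

test_that("fractional CC evaluation is exact on and off the grid", {
  set.seed(5)
  n <- 24
  g <- tomopipe:::apply_fourier_filter(array(rnorm(n^3), rep(n, 3)),
                                       as.vector(band_mask(n, 1, Inf, 3)))
  s_true <- c(1.3, -2.6, 0.45)
  g2 <- tomopipe:::fourier_shift(g, s_true)
  X <- stats::fft(g2) * Conj(stats::fft(g))
  cc <- Re(stats::fft(X, inverse = TRUE))
  pk <- tomopipe:::cc_peak3d(cc)
  # at an integer shift the band-limited interpolant equals the grid value
  expect_equal(tomopipe:::cc_value_fractional(X, round(pk$shift_vox), n),
               max(cc), tolerance = 1e-9)
  # at the refined fractional peak it recovers (nearly) the true off-grid
  # maximum, far above the integer-peak value
  v_frac <- tomopipe:::cc_value_fractional(X, pk$shift_vox, n)
  v_true <- tomopipe:::cc_value_fractional(X, s_true, n)
  expect_gt(v_frac, max(cc))
  expect_gt(v_frac, 0.99 * v_true)
})
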