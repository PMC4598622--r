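test_that("frame alignment recovers known drifts", {
  base <- smooth_map(32, 10, 50, seed = 8)$grid[, , 16]
  base <- matrix(base, 32, 32)
  # identical frames: all shifts zero
  res0 <- align_frames(list(base, base, base))
  expect_lt(max(abs(res0$shifts)), 1e-6)
  # known integer drifts, noise-free
  fr <- list(base,
             fourier_shift(base, c(1, 0)),
             fourier_shift(base, c(2, 0)),
             fourier_shift(base, c(3, 0)))
  res <- align_frames(fr)
  expect_lt(max(abs(res$shifts - cbind(0:3, 0))), 0.1)
  # noisy frames with sub-5 px drifts: recovery within 0.5 px and SNR gain
  set.seed(3)
  fs <- simulate_frame_stack(base, k = 5, drift_px = 1.2, noise_sd = 0.5 * sd(base),
                             seed = 13)
  resn <- align_frames(fs$frames)
  shifts_rel <- sweep(fs$shifts, 2, fs$shifts[1, ])
  expect_lt(max(abs(resn$shifts - shifts_rel)), 0.5)
  resid_sum <- resn$sum - base
  resid_one <- fs$frames[[1]] * 5 - base
  expect_lt(sd(resid_sum), sd(resid_one))
})

test_that("strip-periodogram defocus estimation hits the simulated defocus", {
  set.seed(21)
  n <- 256
  pars <- ctf_params(defocus_um = 3.0)
  # white-spectrum specimen so the rings are visible
  img <- matrix(rnorm(n * n), n)
  s <- tomopipe:::freq_grid2d(n, 2.62)
  ctf_img <- Re(stats::fft(stats::fft(img) * ctf_eval(s, 3.0, pars),
                           inverse = TRUE)) / n^2
  est <- estimate_defocus(ctf_img, pars, 2.62, strip_width_px = 128,
                          defocus_range_um = c(1, 6))
  expect_lt(abs(est$defocus_um - 3.0), 0.05)
  expect_gt(est$quality, 0.3)
  # with noise: within 0.2 um
  noisy <- ctf_img + rnorm(n * n, 0, sd(ctf_img))
  est2 <- estimate_defocus(noisy, pars, 2.62, strip_width_px = 128,
                           defocus_range_um = c(1, 6))
  expect_lt(abs(est2$defocus_um - 3.0), 0.2)
  # a search range excluding the truth is flagged unreliable (quality 0)
  est3 <- estimate_defocus(ctf_img, pars, 2.62, strip_width_px = 128,
                           defocus_range_um = c(4.5, 6))
  expect_true(est3$defocus_um >= 4.5 && est3$defocus_um <= 6)
  expect_equal(est3$quality, 0)
  # featureless input is flagged with quality 0
  flat <- matrix(1, n, n)
  est4 <- estimate_defocus(flat, pars, 2.62, strip_width_px = 128)
  expect_equal(est4$quality, 0)
})

test_that("phase flipping preserves amplitudes and inverts its own damage", {
  set.seed(5)
  n <- 128
  pars <- ctf_params(defocus_um = 3.5)
  img <- matrix(rnorm(n * n), n)
  s <- tomopipe:::freq_grid2d(n, 2.62)
  corrupted <- Re(stats::fft(stats::fft(img) * ctf_eval(s, 3.5, pars),
                             inverse = TRUE)) / n^2
  flipped <- phase_flip(corrupted, pars, 3.5, 2.62)
  expect_lt(max(abs(Mod(stats::fft(flipped)) - Mod(stats::fft(corrupted)))),
            1e-6 * max(Mod(stats::fft(corrupted))))
  # double application is the identity
  expect_lt(max(abs(phase_flip(flipped, pars, 3.5, 2.62) - corrupted)), 1e-9)
  # flipping restores coherent (negative, as in raw micrographs) contrast:
  # the flipped spectrum is -|CTF| F(img), so it tracks -img much better than
  # the sign-oscillating corrupted image tracks either polarity
  expect_gt(cor(as.vector(flipped), -as.vector(img)),
            abs(cor(as.vector(corrupted), as.vector(img))) + 0.2)
  # a CTF without in-band zero crossings leaves the image unchanged: coarse
  # pixel so Nyquist (sqrt(2)/2 / 5 A) stays below the first zero at 0.2 um
  small <- matrix(rnorm(64), 8)
  out <- phase_flip(small, pars, 0.2, 5.0)
  expect_lt(max(abs(out - small)), 1e-9)
})

test_that("marker-based tilt alignment solves shifts to subpixel accuracy", {
  set.seed(9)
  tilt <- seq(-60, 60, 10)
  M <- 5; K <- length(tilt)
  markers <- matrix(runif(M * 3, -40, 40), M, 3)
  markers <- sweep(markers, 2, colMeans(markers))   # centroid-zero gauge
  proj <- function(shifts) {
    mk <- array(0, c(M, K, 2))
    for (i in seq_len(K)) {
      th <- tilt[i] * pi / 180
      mk[, i, 1] <- cos(th) * markers[, 1] + sin(th) * markers[, 3] + shifts[i, 1]
      mk[, i, 2] <- markers[, 2] + shifts[i, 2]
    }
    mk
  }
  # zero shifts
  fit0 <- align_tilt_series(proj(matrix(0, K, 2)), tilt)
  expect_lt(max(abs(fit0$shifts)), 1e-6)
  expect_lt(fit0$residual_rms_px, 1e-6)
  # known random shifts up to 10 px
  sh <- matrix(runif(K * 2, -10, 10), K, 2)
  fit <- align_tilt_series(proj(sh), tilt)
  expect_lt(max(abs(fit$shifts - sh)), 0.1)
  expect_lt(max(abs(fit$markers - markers)), 0.1)
  # single marker is rejected
  expect_error(align_tilt_series(proj(sh)[1, , , drop = FALSE], tilt),
               "rank-deficient")
})

test_that("weighted backprojection geometry and wedge support", {
  # single 0-degree projection of a point backprojects to a line along z
  n <- 32
  g <- array(0, rep(n, 3)); g[17, 17, 17] <- 1
  ts <- project_tilt_series(density_map(g, 10), 0, seed = 1)
  rec <- weighted_backprojection(ts)$map$grid
  line <- rec[17, 17, ]
  off <- rec[9, 9, ]
  expect_gt(min(line), max(abs(off)) * 3)
  # full-range series of a smooth phantom reconstructs the wedge-filtered truth
  v <- density_map(tomopipe:::render_blobs(list(
    list(pos = c(-40, 60, 20), sigma = 35, amp = 1),
    list(pos = c(80, -30, -50), sigma = 45, amp = 0.8)), 48, 10), 10)
  ts2 <- project_tilt_series(v, seq(-60, 60, 2), seed = 1)
  rec2 <- weighted_backprojection(ts2)
  truth_w <- tomopipe:::apply_fourier_filter(v$grid - mean(v$grid),
                                             make_wedge_mask(48, wedge_spec(-60, 60)))
  expect_gt(map_correlation(rec2$map$grid - mean(rec2$map$grid), truth_w), 0.9)
  # reduced range: Fourier support shrinks into the +-20 wedge
  rec20 <- weighted_backprojection(ts2, tilt_subset = c(-20, 20))
  expect_lt(fourier_energy_outside_wedge(rec20$map, wedge_spec(-20, 20)), 0.02)
  # support(+-20) is inside support(+-60): outside-60 leakage is no larger
  expect_lte(fourier_energy_outside_wedge(rec20$map, wedge_spec(-60, 60)),
             fourier_energy_outside_wedge(rec20$map, wedge_spec(-20, 20)))
  expect_error(weighted_backprojection(ts2, tilt_subset = c(80, 85)),
               "selects no images")
  # linearity in the projections
  tsA <- ts2; tsB <- ts2
  set.seed(2); tsB$images <- array(rnorm(length(ts2$images), 0, 0.1),
                                   dim(ts2$images))
  tsS <- ts2; tsS$images <- tsA$images + tsB$images
  rs <- weighted_backprojection(tsS)$map$grid
  ra <- weighted_backprojection(tsA)$map$grid
  rb <- weighted_backprojection(tsB)$map$grid
  expect_lt(max(abs(rs - ra - rb)), 1e-6 * max(abs(rs)))
})

test_that("subtomogram reconstruction equals the tomogram crop and books dose", {
  v <- density_map(tomopipe:::render_blobs(list(
    list(pos = c(-30, 50, 10), sigma = 30, amp = 1)), 48, 10), 10)
  ts <- project_tilt_series(v, seq(-60, 60, 2), dose_per_image = 90 / 61,
                            seed = 1)
  tomo <- weighted_backprojection(ts)$map$grid
  pos_vox <- c(18, 29, 25)
  pos_A <- (pos_vox - vol_center(48)) * 10
  sub <- reconstruct_subtomogram(ts, pos_A, 16)
  crop <- tomo[(pos_vox[1] - 8):(pos_vox[1] + 7),
               (pos_vox[2] - 8):(pos_vox[2] + 7),
               (pos_vox[3] - 8):(pos_vox[3] + 7)]
  expect_lt(max(abs(sub$map$grid - crop)), 1e-3 * max(abs(crop)))
  # the reduced range accumulates ~30 e/A2 from a 90 e/A2 series (21/61 * 90)
  red <- reconstruct_subtomogram(ts, pos_A, 16, tilt_subset = c(-20, 20))
  expect_equal(red$dose_e_A2, 21 / 61 * 90, tolerance = 1e-9)
  expect_equal(red$wedge$tilt_min, -20, tolerance = 0.01)
  expect_error(reconstruct_subtomogram(ts, pos_A, 16, tilt_subset = c(70, 80)),
               "selects no images")
  expect_error(reconstruct_subtomogram(ts, c(300, 0, 0), 16), "field edge")
})
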