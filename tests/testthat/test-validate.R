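test_that("FSC identities: self, negation, symmetry, rigid invariance", {
  m <- smooth_map(32, 10, 50, seed = 4)
  fsc_self <- fsc_curve(m, m)
  expect_true(all(abs(fsc_self$fsc - 1) < 1e-9))
  fsc_neg <- fsc_curve(m, density_map(-m$grid, 10))
  expect_true(all(abs(fsc_neg$fsc + 1) < 1e-9))
  a <- smooth_map(32, 10, 60, seed = 1)
  b <- smooth_map(32, 10, 60, seed = 2)
  expect_equal(fsc_curve(a, b)$fsc, fsc_curve(b, a)$fsc, tolerance = 1e-12)
  expect_error(fsc_curve(a, smooth_map(48, 10, 60)), "shape mismatch")
  # common rigid transform leaves the curve nearly unchanged
  R <- rigid_transform(euler_to_matrix(15, 25, 5))
  ar <- rotate_volume(a, R); br <- rotate_volume(b, R)
  f1 <- fsc_curve(a, b)$fsc; f2 <- fsc_curve(ar, br)$fsc
  expect_lt(mean(abs(f1 - f2)[1:10]), 0.1)
})

test_that("noisy half-maps follow the analytic FSC = S/(S+N) expectation", {
  n <- 32; vs <- 10
  base <- smooth_map(n, vs, 40, seed = 31)
  shell <- tomopipe:::shell_index(n)
  Ps <- tapply(as.vector(Mod(stats::fft(base$grid))^2), as.vector(shell), sum)
  sigma <- 0.3 * sd(base$grid)
  nseeds <- 50
  acc <- matrix(0, nseeds, n / 2)
  for (s in seq_len(nseeds)) {
    set.seed(1000 + s)
    h1 <- density_map(base$grid + array(rnorm(n^3, 0, sigma), rep(n, 3)), vs)
    h2 <- density_map(base$grid + array(rnorm(n^3, 0, sigma), rep(n, 3)), vs)
    acc[s, ] <- fsc_curve(h1, h2)$fsc
  }
  # expectation per shell: SNR / (SNR + 1) with SNR = shell signal / noise power
  cnt <- tapply(rep(1, n^3), as.vector(shell), sum)
  keep <- as.integer(names(Ps)); keep <- keep[keep >= 1]
  snr <- as.numeric(Ps[as.character(keep)]) /
    (as.numeric(cnt[as.character(keep)]) * sigma^2 * n^3)
  expected <- snr / (1 + snr)
  got <- colMeans(acc)[keep]
  se <- apply(acc, 2, sd)[keep] / sqrt(nseeds)
  ok <- abs(got - expected) <= 3 * pmax(se, 0.01)
  expect_gt(mean(ok), 0.9)
  # and the empirical curve decays overall
  expect_lt(mean(got[(length(got) - 3):length(got)]), mean(got[1:4]))
})

test_that("threshold crossing interpolates as computed by hand", {
  # shells at 1/10 and 1/9 with FSC 0.6 and 0.4: crossing of 0.5 by linear
  # interpolation sits at f = 0.1 + 0.5 * (1/9 - 1/10), resolution 9.4737 A
  curve <- data.frame(freq_invA = c(0.05, 0.1, 1 / 9),
                      fsc = c(0.9, 0.6, 0.4))
  res <- resolution_at_threshold(curve, 0.5, 2)
  expect_equal(res$resolution_A, 1 / (0.1 + 0.5 * (1 / 9 - 1 / 10)),
               tolerance = 1e-12)
  expect_equal(res$resolution_A, 9.47368421, tolerance = 1e-6)
  expect_false(res$is_bound)
  # a curve pinned at 1 returns the Nyquist bound flagged
  flat <- data.frame(freq_invA = (1:16 - 0.5) / 320, fsc = rep(1, 16))
  resb <- resolution_at_threshold(flat, 0.5, 10)
  expect_true(resb$is_bound)
  expect_equal(resb$resolution_A, 20)
  # the gold-standard threshold never reports worse than the conventional one
  set.seed(2)
  decay <- data.frame(freq_invA = (1:16 - 0.5) / 320,
                      fsc = exp(-(1:16) / 4))
  r05 <- resolution_at_threshold(decay, 0.5, 10)$resolution_A
  r0143 <- resolution_at_threshold(decay, 0.143, 10)$resolution_A
  expect_lte(r0143, r05)
  expect_error(resolution_at_threshold(decay, 1.2, 10), "threshold")
})

test_that("local resolution flags a blurred subregion", {
  n <- 40; vs <- 10
  set.seed(12)
  base <- smooth_map(n, vs, 30, seed = 12)
  blur <- lowpass(base, 80)
  half_a <- base$grid
  half_b <- base$grid
  # one octant of half_b replaced by its blurred version
  half_b[1:20, 1:20, 1:20] <- blur$grid[1:20, 1:20, 1:20]
  lr <- local_resolution(density_map(half_a, vs), density_map(half_b, vs),
                         box_vox = 20, stride = 10)
  expect_equal(lr$box_vox, 20)
  inside <- lr$map$grid[5:14, 5:14, 5:14]
  outside <- lr$map$grid[26:35, 26:35, 26:35]
  expect_gt(median(inside), median(outside))
  # identical half-maps are Nyquist-bound everywhere
  lr0 <- local_resolution(base, base, box_vox = 20, stride = 20)
  expect_true(all(abs(lr0$map$grid - 2 * vs) < 1e-9))
  expect_error(local_resolution(base, base, box_vox = 6), "8 voxels")
})

test_that("B-factor sharpening follows the closed form and inverts in-band", {
  m <- smooth_map(32, 10, 40, seed = 7)
  # B = -500 at s = 0.1: gain exp(500 * 0.01 / 4) = exp(1.25)
  expect_equal(exp(-(-500) * 0.1^2 / 4), 3.4903, tolerance = 1e-4)
  n <- 32; vs <- 10
  # numeric gain probe in-band (Nyquist is 0.05/A here): ratio of the B = -500
  # result to the B = 0 result cancels the shared low-pass, leaving
  # exp(-B s^2 / 4) exactly; at s = 0.03125 that is exp(0.12207)
  set.seed(42)
  mw <- density_map(array(rnorm(n^3), rep(n, 3)), vs)
  sh <- sharpen(mw, -500, 25)
  sh0 <- sharpen(mw, 0, 25)
  g <- tomopipe:::freq_grids(n)
  s2 <- (g$kr / vs)^2
  shell_s <- g$kr / vs
  Fs <- as.vector(stats::fft(sh$grid)); F0 <- as.vector(stats::fft(sh0$grid))
  probe <- which(abs(shell_s - 0.03125) < 1e-6)
  expect_gt(length(probe), 0)
  gain <- Mod(Fs[probe]) / pmax(Mod(F0[probe]), 1e-12)
  expect_lt(abs(median(gain) - exp(500 * 0.03125^2 / 4)) /
              exp(500 * 0.03125^2 / 4), 0.01)
  # B = 0 equals the low-pass alone
  expect_lt(max(abs(sharpen(m, 0, 25)$grid - lowpass(m, 25)$grid)), 1e-9)
  # applying the inverse exponential in-band recovers the input
  shm <- sharpen(m, -500, 25)
  inv <- tomopipe:::apply_fourier_filter(shm$grid,
    array(exp(-500 * s2 / 4), rep(n, 3)))
  band <- shell_s < 1 / 30
  orig_band <- tomopipe:::apply_fourier_filter(m$grid,
    as.numeric(band) * as.vector(band_mask(n, vs, Inf, 25)))
  inv_band <- tomopipe:::apply_fourier_filter(inv, array(as.numeric(band), rep(n, 3)))
  expect_lt(max(abs(inv_band - orig_band)), 1e-6 * max(abs(orig_band)))
  expect_error(sharpen(m, -500, 15), "Nyquist")
})
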