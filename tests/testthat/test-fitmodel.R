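test_that("superposition recovers exact and noisy transforms", {
  set.seed(6)
  mdl <- sec61_analog()$closed
  # self: identity, zero RMSD
  s0 <- superpose(mdl, mdl)
  expect_lt(s0$rmsd_A, 1e-9)
  expect_lt(rotation_distance(s0$transform$rotation, diag(3)), 1e-4)
  # exact recovery of a known transform
  tr <- rigid_transform(euler_to_matrix(33, 50, -10), c(5, -3, 8))
  moved <- transform_model(mdl, tr)
  s1 <- superpose(mdl, moved)
  expect_lt(max(abs(s1$transform$rotation - tr$rotation)), 1e-9)
  expect_lt(max(abs(s1$transform$translation - tr$translation)), 1e-9)
  expect_lt(s1$rmsd_A, 1e-9)
  # Gaussian noise sigma = 0.5 A per coordinate: RMSD ~ sigma * sqrt(3)
  big <- make_helix_model(500, direction = c(0.2, 0.1, 1))
  noisy <- big
  noisy$atoms[, c("x", "y", "z")] <-
    noisy$atoms[, c("x", "y", "z")] + rnorm(1500, 0, 0.5)
  s2 <- superpose(big, noisy)
  expect_lt(abs(s2$rmsd_A - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.1)
  expect_error(superpose(mdl, big), "pair")
})

test_that("rmsd closed forms hold", {
  m <- make_helix_model(25)
  expect_equal(rmsd_atoms(m, m), 0)
  shifted <- transform_model(m, rigid_transform(diag(3), c(3, 4, 0)))
  expect_equal(rmsd_atoms(m, shifted), 5, tolerance = 1e-12)
  one <- m
  one$atoms$x[7] <- one$atoms$x[7] + 3
  expect_equal(rmsd_atoms(m, one), 3 / sqrt(25), tolerance = 1e-12)
})

test_that("rigid fit recovers a perturbed pose on rendered density", {
  mdl <- sec61_analog()$closed
  dens <- model_to_density(mdl, 48, 3, resolution_A = 9)
  start <- transform_model(mdl, rigid_transform(
    axis_angle_matrix(c(0.3, 1, 0.2), 10), c(4, -2, 2)))
  fit <- rigid_fit(start, dens, resolution_A = 9)
  expect_gt(fit$score, 0.98)
  expect_lt(rmsd_atoms(fit$model, mdl), 2)
  # identity start on perfect data stays at identity
  fit0 <- rigid_fit(mdl, dens, resolution_A = 9)
  expect_lt(rmsd_atoms(fit0$model, mdl), 0.5)
})

test_that("domain-wise fitting resolves a planted lateral-gate motion", {
  ana <- sec61_analog()
  dens_open <- model_to_density(ana$open, 56, 3, resolution_A = 9)
  # whole-model rigid fit cannot match both halves at once
  whole <- rigid_fit(ana$closed, dens_open, resolution_A = 9)
  split <- fit_domains(ana$closed, dens_open,
                       list(c("N-half", "beta"),
                            c("C-half", "TMH10", "gamma")),
                       resolution_A = 9)
  expect_gt(max(vapply(split, `[[`, 0, "score")), whole$score)
  # the recovered N-half transform screw-decomposes to the planted 22 degrees
  sdn <- screw_decompose(split[["N-half+beta"]]$transform)
  expect_lt(abs(sdn$angle_deg - 22), 1.5)
  expect_error(fit_domains(ana$closed, dens_open,
                           list("N-half", c("N-half", "beta"))), "overlapping")
  # single-group split behaves like rigid_fit
  single <- fit_domains(ana$closed,
                        model_to_density(ana$closed, 48, 3, 9),
                        list(unique(ana$closed$atoms$domain)),
                        resolution_A = 9)
  expect_gt(single[[1]]$score, 0.98)
})

test_that("helix axial scan finds a planted 13 A shift", {
  ana <- sec61_analog()
  sel <- list(domain = "TMH10")
  shifted_truth <- ana$open                   # TMH10 moved 13 A along its axis
  dens <- model_to_density(shifted_truth, 56, 3, resolution_A = 9)
  # start from the open model with TMH10 put back at its closed position
  start <- ana$open
  rows <- tomopipe:::model_select(start, sel)
  start$atoms[rows, c("x", "y", "z")] <- ana$closed$atoms[rows, c("x", "y", "z")]
  scan <- shift_helix(start, sel, dens, scan_range_A = 20, step_A = 0.5,
                      resolution_A = 9)
  expect_lt(abs(abs(scan$shift_A) - 13), 0.75)
  expect_equal(max(scan$profile$score),
               scan$profile$score[which.max(scan$profile$score)])
  # zero-shift data returns ~0
  dens0 <- model_to_density(start, 56, 3, resolution_A = 9)
  scan0 <- shift_helix(start, sel, dens0, scan_range_A = 10, step_A = 0.5,
                       resolution_A = 9)
  expect_lt(abs(scan0$shift_A), 0.75)
})

test_that("flexible refinement holds a fixed point and recovers a coherent shift", {
  ana <- sec61_analog()
  dens <- model_to_density(ana$closed, 48, 3, resolution_A = 9)
  # start at the truth: restraints keep it there
  fx <- flexible_refine(ana$closed, dens, steps = 120, seed = 1)
  expect_lt(fx$rmsd_to_start_A, 0.4)
  # coherent 2 A shift of the whole model: refinement moves it back
  start <- transform_model(ana$closed, rigid_transform(diag(3), c(2, 0, 0)))
  fx2 <- flexible_refine(start, dens, steps = 250, seed = 1)
  expect_lt(rmsd_atoms(fx2$model, ana$closed),
            rmsd_atoms(start, ana$closed))
  # motions stay small at matched conditions (the deposited-model behavior)
  expect_lt(fx2$rmsd_to_start_A, 3)
})

test_that("screw decomposition round-trips and reports canonical cases", {
  # identity
  s0 <- screw_decompose(rigid_transform())
  expect_equal(s0$angle_deg, 0)
  expect_false(s0$axis_defined)
  # the 22 deg / 13.8 A constructed motion
  tr <- rigid_transform(axis_angle_matrix(c(0, 0, 1), 22), c(0, 0, 13.8))
  s1 <- screw_decompose(tr)
  expect_equal(s1$angle_deg, 22, tolerance = 1e-9)
  expect_equal(abs(s1$axis[3]), 1, tolerance = 1e-9)
  expect_equal(s1$translation_A * sign(s1$axis[3]), 13.8, tolerance = 1e-9)
  # 500 random transforms reconstruct to within 1e-6 A on probe points
  set.seed(77)
  probes <- matrix(runif(300, -50, 50), 100, 3)
  for (i in 1:500) {
    tr <- rigid_transform(random_rotation(), rnorm(3, 0, 20))
    sdc <- screw_decompose(tr)
    rec <- screw_transform(sdc)
    expect_lt(max(abs(apply_transform(tr, probes) -
                      apply_transform(rec, probes))), 1e-6)
  }
  # numerically symmetric near-identity rotation: acos rounding reports a tiny
  # nonzero angle but the skew part is exactly zero; the axis must be flagged
  # undefined instead of coming back NaN
  Rsym <- diag(c(1 - 1e-13, 1 - 1e-13, 1))
  ssym <- screw_decompose(rigid_transform(Rsym, c(1, 2, 3)))
  expect_false(ssym$axis_defined)
  expect_equal(ssym$angle_deg, 0)
  expect_true(is.finite(ssym$translation_A))
})

test_that("PDB round trip preserves coordinates and applies domain files", {
  ana <- sec61_analog()
  f <- tempfile(fileext = ".pdb")
  write_model_pdb(ana$closed, f)
  domf <- tempfile()
  writeLines(c("# domains of the alpha-subunit analog",
               "N-half A 100 599", "C-half A 600 999", "TMH10 A 1000 1099",
               "beta B 1 99", "gamma G 1 99"), domf)
  doms <- read_domain_file(domf)
  back <- read_model_pdb(f, doms)
  expect_equal(nrow(back$atoms), nrow(ana$closed$atoms))
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                    as.matrix(ana$closed$atoms[, c("x", "y", "z")]))), 1e-2)
  expect_setequal(unique(back$atoms$domain),
                  c("N-half", "C-half", "TMH10", "beta", "gamma"))
})
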