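#' Pipeline configuration with acquisition-faithful defaults
#'
#' Bundles every stage's parameters: the simulator scenario, acquisition
#' geometry (tilt range -60..60 in 2-degree steps, 3-4 um defocus, ~90 e/A^2
#' cumulative dose), detection (12.85-degree angular increment, 500 peaks),
#' the reduced -20..20 degree reconstruction range, the alignment schedule,
#' classification rounds and validation thresholds (FSC 0.5 / 0.143 / 0.33,
#' local-resolution box 20, B-factor -500).  The \code{scale} presets shrink
#' problem sizes (scene, particle count, orientation grid) so a full run is
#' minutes on one core, without touching the physics parameters.
#'
#' @param scale "tiny" (smoke-test), "desk" (default).
#' @param seed master seed; every stage derives its own from it.
#' @param ... named overrides merged into the config (top-level sections).
#' @return nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scale = c("desk", "tiny"), seed = 1, ...) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = seed,
    scene = list(n = 72, voxel_size = 21, n_particles = 20,
                 bound_fraction = 0.8, n_fiducials = 6,
                 vesicle_radius_A = 500, particle_diameter_A = 280,
                 occupancies = list(OST = 0.55, tRNA = 0.29)),
    acquisition = list(tilt_min = -60, tilt_max = 60, tilt_step = 2,
                       defocus_um = 3.5, dose_total = 90,
                       noise_sd0 = 0, shift_jitter_px = 0, use_ctf = TRUE),
    detection = list(angular_increment_deg = 12.85, n_peaks = 500,
                     binning = 2, template_lowpass_A = 50),
    reconstruction = list(reduced_tilt = c(-20, 20), box_px = 24),
    alignment = list(max_iterations = 3, initial_res_A = 80),
    classification = list(n_components = 10, round1_k = 2, round2_k = 2,
                          trna_k = 2, n_restarts = 10),
    validation = list(fsc_conventional = 0.5, fsc_gold = 0.143,
                      fsc_cross = 0.33, local_box = 20, b_factor = -500)
  )
  if (scale == "tiny") {
    cfg$scene$n_particles <- 10
    cfg$scene$n_fiducials <- 3
    cfg$detection$angular_increment_deg <- 40
    cfg$detection$n_peaks <- 40
    cfg$alignment$max_iterations <- 2
  }
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#' @param cfg \code{pipeline_config}.
#' @param path file path.
#' @return \code{read_pipeline_config} returns a \code{pipeline_config}.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config(seed = cfg$seed %||% 1)
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(cfg)), f)
  unname(tools::md5sum(f))
}

pipe_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full synthetic-data workflow end to end
#'
#' Executes simulate -> project -> phase flip -> marker-based tilt alignment
#' -> weighted backprojection -> template matching -> peak extraction ->
#' round-1 focused classification (membrane-bound vs rest) -> subtomogram
#' alignment -> round-2 classification (translocon focus) -> reduced-range
#' re-reconstruction -> conventional and gold-standard refinement ->
#' tRNA-site classification -> class averages with resolutions, then writes a
#' JSON report with every recovered-vs-truth metric.  Fully reproducible
#' given the config; production stages never read the ground truth (it is
#' used only by the report generator).
#'
#' @param cfg \code{pipeline_config}.
#' @param out_dir output directory for intermediate artifacts and the report.
#' @param resume reuse stage outputs found in \code{out_dir} when the config
#'   hash matches.
#' @param verbose log stage progress.
#' @param stop_after optional stage name (\code{"scene"}, \code{"tomogram"},
#'   \code{"match"}, \code{"round1"}, \code{"refine1"},
#'   \code{"refine_gold"}, \code{"trna"}); the run returns after that stage
#'   completes, leaving its cached artifacts for a later resumed run.
#' @return the report (named list), invisibly written to
#'   \code{out_dir/report.json}; with \code{stop_after}, a list naming the
#'   last completed stage.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("tomorun"), resume = FALSE,
                         verbose = TRUE, stop_after = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hfile <- file.path(out_dir, "config_hash.txt")
  if (resume && file.exists(hfile) && readLines(hfile)[1] != hash)
    resume <- FALSE
  writeLines(hash, hfile)
  write_pipeline_config(cfg, file.path(out_dir, "config.yaml"))
  stage <- function(name, fun) {
    f <- file.path(out_dir, paste0(name, ".rds"))
    if (resume && file.exists(f)) {
      pipe_log(verbose, name, "resumed from ", f)
      return(readRDS(f))
    }
    pipe_log(verbose, name, "running")
    val <- fun()
    saveRDS(val, f)
    val
  }
  sc <- cfg$scene; aq <- cfg$acquisition; dt <- cfg$detection
  rc <- cfg$reconstruction; al <- cfg$alignment; cl <- cfg$classification
  halt <- function(name) {
    pipe_log(verbose, name, "stopping here as requested")
    invisible(list(stopped_after = name, out_dir = out_dir))
  }

  ## ---- simulate ------------------------------------------------------
  spec <- phantom_spec(particle_diameter_A = sc$particle_diameter_A,
                       subdensities = list(
                         list(name = "OST", offset = c(0.20, 0, -0.35),
                              radius = 0.085, occupancy = sc$occupancies$OST),
                         list(name = "tRNA", offset = c(0, 0.11, 0.125),
                              radius = 0.10, occupancy = sc$occupancies$tRNA)))
  scene <- stage("scene", function()
    build_scene(spec, n = sc$n, voxel_size = sc$voxel_size,
                vesicle_radius_A = sc$vesicle_radius_A,
                n_particles = sc$n_particles,
                bound_fraction = sc$bound_fraction,
                n_fiducials = sc$n_fiducials, seed = cfg$seed))
  write_mrc(scene$volume, file.path(out_dir, "scene.mrc"))
  if (identical(stop_after, "scene")) return(halt("scene"))

  ## ---- acquire -------------------------------------------------------
  tilt <- seq(aq$tilt_min, aq$tilt_max, by = aq$tilt_step)
  dose_img <- aq$dose_total / length(tilt)
  series <- stage("series", function()
    project_tilt_series(scene$volume, tilt,
                        ctf = if (aq$use_ctf) ctf_params(defocus_um = aq$defocus_um) else NULL,
                        dose_per_image = dose_img, noise_sd0 = aq$noise_sd0,
                        shift_jitter_px = aq$shift_jitter_px,
                        seed = cfg$seed + 1))
  write_tilt_series(series, file.path(out_dir, "tiltseries"))

  ## ---- CTF correction ------------------------------------------------
  series_pf <- stage("phaseflip", function() {
    if (!aq$use_ctf) return(series)
    s <- series
    pars <- ctf_params(defocus_um = aq$defocus_um)
    for (i in seq_len(dim(s$images)[3]))
      s$images[, , i] <- phase_flip(s$images[, , i], pars, s$defocus_um[i],
                                    s$pixel_size_A)
    s
  })

  ## ---- tilt alignment from fiducial tracks ---------------------------
  align <- stage("tiltalign", function() {
    if (nrow(scene$fiducials) >= 3) {
      fid <- as.matrix(scene$fiducials)
      fid <- sweep(fid, 2, colMeans(fid))      # centroid-zero gauge
      K <- length(series$tilt_deg)
      mk <- array(NA_real_, c(nrow(fid), K, 2))
      for (i in seq_len(K)) {
        th <- series$tilt_deg[i] * pi / 180
        mk[, i, 1] <- (cos(th) * fid[, 1] + sin(th) * fid[, 3]) /
          series$pixel_size_A + series$shifts[i, 1]
        mk[, i, 2] <- fid[, 2] / series$pixel_size_A + series$shifts[i, 2]
      }
      align_tilt_series(mk, series$tilt_deg)
    } else list(shifts = matrix(0, length(series$tilt_deg), 2),
                residual_rms_px = NA_real_)
  })

  ## ---- tomogram ------------------------------------------------------
  tomo <- stage("tomogram", function()
    weighted_backprojection(series_pf, shifts = align$shifts))
  write_mrc(tomo$map, file.path(out_dir, "tomogram.mrc"))
  if (identical(stop_after, "tomogram")) return(halt("tomogram"))

  ## ---- template matching (binned) ------------------------------------
  match <- stage("match", function() {
    tb <- bin_array(tomo$map$grid, dt$binning)
    # phase flipping preserves the native contrast, so protein is negative
    # density in the tomogram; invert it to match the positive-density template
    tomo_b <- density_map(-tb, tomo$map$voxel_size * dt$binning)
    # template: sub-density-free particle rendered at the binned pixel
    nt <- 2 * ceiling(sc$particle_diameter_A * 1.25 /
                        (2 * tomo_b$voxel_size))
    tmpl_blobs <- Filter(function(b)
      b$domain %in% c("body", "foot_mobile", "foot_static"),
      scene$phantom$blobs)
    tmpl <- density_map(render_blobs(tmpl_blobs, nt, tomo_b$voxel_size),
                        tomo_b$voxel_size)
    # matching cannot use detail beyond the binned Nyquist
    tmpl <- lowpass(tmpl, max(dt$template_lowpass_A, 2 * tomo_b$voxel_size))
    msk <- soft_sphere_mask(nt, nt / 2 - 2, 2)
    mm <- match_template(tomo_b, tmpl, msk, dt$angular_increment_deg,
                         tomo$wedge, verbose = verbose)
    peaks <- extract_peaks(mm$scores,
                           min(dt$n_peaks, sc$n_particles + sc$n_fiducials + 10),
                           exclusion_radius_vox =
                             round(sc$particle_diameter_A / tomo_b$voxel_size * 0.8),
                           orient = mm$orient, grid = mm$grid)
    # drop candidates centered outside the reconstructable field
    nb <- dim(tb)[1]
    pos_A <- (as.matrix(peaks[, c("x", "y", "z")]) - vol_center(nb)) *
      tomo_b$voxel_size
    lim <- (dim(as_grid(tomo$map))[1] / 2 - 2) * tomo$map$voxel_size
    peaks <- peaks[apply(abs(pos_A) <= lim, 1, all), , drop = FALSE]
    list(peaks = peaks, binning = dt$binning,
         voxel_size = tomo_b$voxel_size, n_grid = nrow(mm$grid))
  })
  write_particles(match$peaks, file.path(out_dir, "candidates.tsv"))
  if (identical(stop_after, "match")) return(halt("match"))

  ## ---- subtomogram extraction (full tilt range) ----------------------
  subtomos_full <- stage("subtomos_full", function() {
    sf <- ramp_filter_series(series_pf)
    lapply(seq_len(nrow(match$peaks)), function(i) {
      pos <- (c(match$peaks$x[i], match$peaks$y[i], match$peaks$z[i]) -
                vol_center(dim(as_grid(tomo$map))[1] / match$binning)) *
        match$voxel_size
      reconstruct_subtomogram(sf, pos, rc$box_px, shifts = align$shifts)$map
    })
  })
  records <- particle_records(length(subtomos_full),
                              wedge_spec(aq$tilt_min, aq$tilt_max))
  records$phi <- match$peaks$phi; records$theta <- match$peaks$theta
  records$psi <- match$peaks$psi
  records$score <- match$peaks$score

  ## ---- round-1 classification: membrane-bound vs rest ----------------
  n_box <- rc$box_px
  avg0 <- average_subtomograms(subtomos_full, records)
  foot_center <- vol_center(n_box) +
    c(0, 0, -0.35 * sc$particle_diameter_A / avg0$voxel_size)
  mask_r1 <- soft_sphere_mask(n_box, 0.30 * sc$particle_diameter_A / avg0$voxel_size,
                              3, center = foot_center)
  round1 <- stage("round1", function() {
    if (nrow(records) < cl$round1_k + 2)
      return(list(labels = rep(1L, nrow(records)),
                  keep = seq_len(nrow(records))))
    feat <- cpca_features(subtomos_full, records, avg0, mask_r1,
                          n_components = min(cl$n_components,
                                             nrow(records) - 1))
    labels <- kmeans_classify(feat$features, cl$round1_k,
                              cl$n_restarts, seed = cfg$seed + 2)
    # retain the class with the higher mean matching score: membrane-bound
    # particles match the two-part template better than junk/fiducials
    means <- tapply(records$score, labels, mean)
    keep_lab <- as.integer(names(which.max(means)))
    keep <- which(labels == keep_lab)
    # a tiny retained class cannot support half-set refinement downstream
    if (length(keep) < 4) keep <- seq_len(nrow(records))
    list(labels = labels, keep = keep)
  })
  kept <- round1$keep
  if (identical(stop_after, "round1")) return(halt("round1"))

  ## ---- iterative alignment (conventional) ----------------------------
  refine1 <- stage("refine1", function() {
    recs <- records[kept, ]
    # mask to the particle itself: the box rim may hold wrapped content for
    # particles near the field edge
    mask <- soft_sphere_mask(n_box, min(n_box / 2 - 3,
                                        0.55 * sc$particle_diameter_A /
                                          avg0$voxel_size), 3)
    refine_iteratively(subtomos_full, recs,
                       lowpass(avg0, max(al$initial_res_A / 2,
                                         2 * avg0$voxel_size)),
                       schedule = list(max_iterations = al$max_iterations,
                                       mask = mask,
                                       initial_res_A = al$initial_res_A),
                       mode = "conventional",
                       particle_diameter_A = sc$particle_diameter_A,
                       seed = cfg$seed + 3)
  })

  if (identical(stop_after, "refine1")) return(halt("refine1"))

  ## ---- round-2 classification: translocon (OST) focus ----------------
  round2 <- stage("round2", function() {
    recs <- refine1$records
    ost_center <- vol_center(n_box) +
      c(0.20, 0, -0.35) * sc$particle_diameter_A / avg0$voxel_size
    mask_r2 <- soft_sphere_mask(n_box, 0.14 * sc$particle_diameter_A / avg0$voxel_size,
                                2, center = ost_center)
    feat <- cpca_features(subtomos_full, recs, refine1$average, mask_r2,
                          n_components = min(cl$n_components, nrow(recs) - 1))
    labels <- kmeans_classify(feat$features, cl$round2_k, cl$n_restarts,
                              seed = cfg$seed + 4)
    list(labels = labels)
  })

  ## ---- reduced-range re-reconstruction -------------------------------
  subtomos_red <- stage("subtomos_red", function() {
    sf <- ramp_filter_series(series_pf)
    recs <- refine1$records
    lapply(seq_len(nrow(recs)), function(r) {
      i <- recs$particle[r]
      pos <- (c(match$peaks$x[i], match$peaks$y[i], match$peaks$z[i]) -
                vol_center(dim(as_grid(tomo$map))[1] / match$binning)) *
        match$voxel_size + c(recs$tx[r], recs$ty[r], recs$tz[r])
      reconstruct_subtomogram(sf, pos, rc$box_px,
                              tilt_subset = rc$reduced_tilt,
                              shifts = align$shifts)$map
    })
  })
  red_records <- refine1$records
  red_records$particle <- seq_len(nrow(red_records))
  red_records$tx <- red_records$ty <- red_records$tz <- 0
  red_records$wedge_min <- rc$reduced_tilt[1]
  red_records$wedge_max <- rc$reduced_tilt[2]

  ## ---- final refinement: conventional + gold standard ----------------
  mask_fin <- soft_sphere_mask(n_box, n_box / 2 - 3, 3)
  refine_conv <- stage("refine_conv", function()
    refine_iteratively(subtomos_red, red_records, refine1$average,
                       schedule = list(max_iterations = al$max_iterations,
                                       mask = mask_fin,
                                       initial_res_A = al$initial_res_A),
                       mode = "conventional",
                       particle_diameter_A = sc$particle_diameter_A,
                       seed = cfg$seed + 5))
  refine_gold <- stage("refine_gold", function()
    refine_iteratively(subtomos_red, red_records, refine1$average,
                       schedule = list(max_iterations = al$max_iterations,
                                       mask = mask_fin,
                                       initial_res_A = al$initial_res_A),
                       mode = "gold_standard",
                       particle_diameter_A = sc$particle_diameter_A,
                       seed = cfg$seed + 6))
  write_mrc(refine_conv$average, file.path(out_dir, "average_conventional.mrc"))
  write_mrc(refine_gold$average, file.path(out_dir, "average_gold.mrc"))
  if (identical(stop_after, "refine_gold")) return(halt("refine_gold"))

  ## ---- tRNA-site classification --------------------------------------
  trna <- stage("trna", function() {
    recs <- refine_conv$records
    trna_center <- vol_center(n_box) +
      c(0, 0.11, 0.125) * sc$particle_diameter_A / avg0$voxel_size
    mask_t <- soft_sphere_mask(n_box, 0.16 * sc$particle_diameter_A / avg0$voxel_size,
                               2, center = trna_center)
    feat <- cpca_features(subtomos_red, recs, refine_conv$average, mask_t,
                          n_components = min(cl$n_components, nrow(recs) - 1))
    labels <- kmeans_classify(feat$features, cl$trna_k, cl$n_restarts,
                              seed = cfg$seed + 7)
    cls <- class_averages(subtomos_red, recs, labels, seed = cfg$seed + 8)
    list(labels = labels, classes = cls)
  })

  if (identical(stop_after, "trna")) return(halt("trna"))

  ## ---- sharpened final map -------------------------------------------
  res_gold <- utils::tail(refine_gold$history$resolution_A, 1)
  sharp <- sharpen(refine_gold$average, cfg$validation$b_factor,
                   max(res_gold, 2 * refine_gold$average$voxel_size))
  write_mrc(sharp, file.path(out_dir, "average_sharpened.mrc"))

  ## ---- report: recovered vs truth ------------------------------------
  truth <- scene$particles
  tomo_nb <- dim(as_grid(tomo$map))[1] / match$binning
  peak_pos <- (as.matrix(match$peaks[, c("x", "y", "z")]) -
                 vol_center(tomo_nb)) * match$voxel_size
  tol <- 2 * match$voxel_size
  truth_pos <- as.matrix(truth[, c("pos_x", "pos_y", "pos_z")])
  dists <- apply(truth_pos, 1, function(p)
    min(sqrt(rowSums(sweep(peak_pos, 2, p)^2))))
  detection_recall <- mean(dists <= tol)
  # which truth particle does each kept peak correspond to?
  peak_truth <- apply(peak_pos, 1, function(p) {
    dd <- sqrt(rowSums(sweep(truth_pos, 2, p)^2))
    if (min(dd) <= tol) which.min(dd) else NA_integer_
  })
  kept_truth <- peak_truth[refine1$records$particle]
  trna_truth <- truth$has_tRNA[kept_truth]
  lab <- trna$labels
  # map each label to tRNA presence by majority, then score
  acc <- NA_real_
  minority_fraction <- NA_real_
  if (!all(is.na(trna_truth))) {
    ok <- !is.na(trna_truth)
    tab <- table(lab[ok], trna_truth[ok])
    map_to <- apply(tab, 1, function(r) colnames(tab)[which.max(r)])
    pred <- map_to[as.character(lab[ok])]
    acc <- mean(pred == as.character(trna_truth[ok]))
    minority_fraction <- min(table(lab) / length(lab))
  }
  report <- list(
    config_hash = hash,
    n_candidates = nrow(match$peaks),
    orientation_grid_size = match$n_grid,
    tilt_align_residual_px = align$residual_rms_px,
    detection = list(recall = detection_recall, tolerance_A = tol),
    round1_retained = length(kept),
    resolution = list(
      conventional_A = utils::tail(refine_conv$history$resolution_A, 1),
      gold_standard_A = res_gold,
      history_conventional = refine_conv$history$resolution_A,
      history_gold = refine_gold$history$resolution_A),
    trna_classes = list(sizes = as.list(stats::setNames(
      as.integer(trna$classes$sizes), paste0("class", trna$classes$classes))),
      fractions = as.numeric(trna$classes$fractions),
      minority_fraction = minority_fraction,
      label_accuracy = acc),
    dose = list(full_e_A2 = sum(series$dose_e_A2),
                reduced_e_A2 = sum(series$dose_e_A2[
                  series$tilt_deg >= rc$reduced_tilt[1] &
                  series$tilt_deg <= rc$reduced_tilt[2]]))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(verbose, "done", "report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}
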