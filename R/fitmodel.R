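#' Atomic coordinate models with domain tags
#'
#' A lightweight coordinate model: one row per atom with name, residue
#' number, chain, a domain tag partitioning the atoms (e.g. "N-half",
#' "C-half", "TMH10", "beta", "gamma") and xyz in Angstrom.  PDB input/output
#' goes through bio3d; domain tags are supplied programmatically or via a
#' plain-text selection file of chain + residue ranges.
#'
#' @param atoms data.frame with columns name, resno, chain, domain, x, y, z.
#' @return object of class \code{atom_model}.
#' @export
atom_model <- function(atoms) {
  need <- c("name", "resno", "chain", "domain", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(is.na(atoms$domain)))
    stop("every atom needs exactly one domain tag")
  structure(list(atoms = atoms), class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("atom_model: %d atoms, %d chains, domains: %s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$domain), collapse = ", ")))
  invisible(x)
}

model_coords <- function(model, selection = NULL) {
  at <- model$atoms
  if (!is.null(selection)) at <- at[model_select(model, selection), ]
  as.matrix(at[, c("x", "y", "z")])
}

# selection: list(domain = tags, name = atom names, chain = chains); NULL
# components match everything
model_select <- function(model, selection) {
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(selection$domain)) keep <- keep & at$domain %in% selection$domain
  if (!is.null(selection$name)) keep <- keep & at$name %in% selection$name
  if (!is.null(selection$chain)) keep <- keep & at$chain %in% selection$chain
  keep
}

set_model_coords <- function(model, xyz, rows = NULL) {
  if (is.null(rows)) rows <- rep(TRUE, nrow(model$atoms))
  model$atoms[rows, c("x", "y", "z")] <- xyz
  model
}

#' Apply a rigid transform to (part of) a model
#' @param model \code{atom_model}.
#' @param t \code{rigid_transform}.
#' @param selection optional selection list (see Details of
#'   \code{\link{superpose}}); default all atoms.
#' @return transformed \code{atom_model}.
#' @export
transform_model <- function(model, t, selection = NULL) {
  rows <- if (is.null(selection)) rep(TRUE, nrow(model$atoms))
          else model_select(model, selection)
  xyz <- as.matrix(model$atoms[rows, c("x", "y", "z")])
  set_model_coords(model, apply_transform(t, xyz), rows)
}

#' Idealized C-alpha helix builder
#'
#' Parametric alpha-helix trace (1.5 A rise, 2.3 A radius, 100 degrees per
#' residue) along an arbitrary axis; the workhorse for synthetic
#' transmembrane-bundle models.
#'
#' @param n_res residues.
#' @param start axis start point (A).
#' @param direction axis direction (normalized internally).
#' @param chain,domain tags for the atoms.
#' @param resno_start first residue number.
#' @param phase_deg helical phase offset.
#' @return \code{atom_model} of CA atoms.
#' @export
make_helix_model <- function(n_res, start = c(0, 0, 0), direction = c(0, 0, 1),
                             chain = "A", domain = "helix", resno_start = 1,
                             phase_deg = 0) {
  u <- direction / sqrt(sum(direction^2))
  R <- align_z_to(u)
  i <- seq_len(n_res) - 1
  ang <- (phase_deg + 100 * i) * pi / 180
  local <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  xyz <- local %*% t(R) + matrix(start, n_res, 3, byrow = TRUE)
  atom_model(data.frame(name = "CA", resno = resno_start + i, chain = chain,
                        domain = domain, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3]))
}

#' Merge several models into one
#' @param ... \code{atom_model}s.
#' @return combined \code{atom_model}.
#' @export
combine_models <- function(...) {
  atom_model(do.call(rbind, lapply(list(...), function(m) m$atoms)))
}

#' Render a model into a density map
#'
#' Each atom becomes a Gaussian of width set by the target resolution
#' (sigma = resolution / 2.355); the map is centered on the volume center.
#'
#' @param model \code{atom_model}.
#' @param n cube edge (voxels).
#' @param voxel_size A/voxel.
#' @param resolution_A target resolution (default 10).
#' @return \code{density_map}.
#' @export
model_to_density <- function(model, n, voxel_size, resolution_A = 10) {
  xyz <- model_coords(model)
  sig <- resolution_A / 2.355
  blobs <- lapply(seq_len(nrow(xyz)), function(i)
    list(pos = xyz[i, ], sigma = sig, amp = 1))
  density_map(render_blobs(blobs, n, voxel_size), voxel_size)
}

#' Least-squares superposition of paired atom selections (Kabsch)
#'
#' Finds the proper rotation + translation mapping the selected atoms of
#' \code{model_a} onto those of \code{model_b} and the post-fit RMSD.
#' Selections are lists with optional elements \code{domain}, \code{name},
#' \code{chain}; the two selections must pair atoms one-to-one in order.
#'
#' @param model_a,model_b \code{atom_model}s.
#' @param selection selection applied to both models (default all atoms).
#' @return list(transform = \code{rigid_transform} a -> b, rmsd_A).
#' @export
superpose <- function(model_a, model_b, selection = NULL) {
  A <- model_coords(model_a, selection)
  B <- model_coords(model_b, selection)
  if (nrow(A) != nrow(B))
    stop("selections pair ", nrow(A), " vs ", nrow(B), " atoms")
  if (nrow(A) < 3) stop("need at least 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cb - as.numeric(R %*% ca)
  fit <- A %*% t(R) + matrix(t, nrow(A), 3, byrow = TRUE)
  list(transform = rigid_transform(R, t),
       rmsd_A = sqrt(mean(rowSums((fit - B)^2))))
}

#' RMSD between paired atom selections (no superposition)
#'
#' @param model_a,model_b \code{atom_model}s.
#' @param selection selection list applied to both.
#' @return RMSD in Angstrom.
#' @export
rmsd_atoms <- function(model_a, model_b, selection = NULL) {
  A <- model_coords(model_a, selection)
  B <- model_coords(model_b, selection)
  if (nrow(A) != nrow(B)) stop("selection length mismatch")
  sqrt(mean(rowSums((A - B)^2)))
}

# correlation between a rendered model and a target density
model_density_score <- function(model, density, resolution_A) {
  n <- dim(as_grid(density))[1]
  sim <- model_to_density(model, n, density$voxel_size, resolution_A)
  map_correlation(sim, density)
}

#' Rigid-body fit of a model into a density map
#'
#' The model is rendered as a Gaussian density at the map's resolution; a
#' coarse orientation grid with FFT translation search finds the basin, then
#' Nelder-Mead refinement of the 6 pose parameters maximizes the real-space
#' correlation.
#'
#' @param model \code{atom_model} (roughly centered on its fit position for
#'   local mode).
#' @param density target \code{density_map}.
#' @param resolution_A rendering resolution (default 10).
#' @param coarse_step_deg coarse orientation step; NULL (default) skips the
#'   global search and refines from the current pose only.
#' @param max_refine Nelder-Mead iteration budget.
#' @return list(transform = \code{rigid_transform} applied to the model,
#'   score = correlation, model = fitted \code{atom_model}).
#' @export
rigid_fit <- function(model, density, resolution_A = 10,
                      coarse_step_deg = NULL, max_refine = 400) {
  n <- dim(as_grid(density))[1]
  vs <- density$voxel_size
  xyz0 <- model_coords(model)
  center <- colMeans(xyz0)
  if (max(abs(sweep(xyz0, 2, 0))) > n / 2 * vs)
    stop("model outside the density box")
  tg <- as_grid(density)
  Ft <- stats::fft(tg - mean(tg))
  start <- rigid_transform()
  if (!is.null(coarse_step_deg)) {
    grid <- so3_grid(coarse_step_deg)
    best <- list(score = -Inf)
    for (g in seq_len(nrow(grid))) {
      R <- euler_to_matrix(grid$phi[g], grid$theta[g], grid$psi[g])
      # rotate model about its centroid, render, translational CC
      m_rot <- set_model_coords(model,
        sweep(sweep(xyz0, 2, center) %*% t(R), 2, center, `+`))
      sim <- as_grid(model_to_density(m_rot, n, vs, resolution_A))
      cc <- Re(stats::fft(Ft * Conj(stats::fft(sim - mean(sim))),
                          inverse = TRUE))
      pk <- cc_peak3d(array(cc, rep(n, 3)), max_shift_vox = n / 3)
      if (pk$value > best$score)
        best <- list(score = pk$value, R = R, shift = pk$shift_vox * vs)
    }
    start <- rigid_transform(best$R,
                             best$shift + center - as.numeric(best$R %*% center))
  }
  # local refinement of (3 rotation offsets deg, 3 translation A)
  obj <- function(p) {
    tr <- rigid_transform(euler_to_matrix(p[1], p[2], p[3]) %*% start$rotation,
                          start$translation + p[4:6])
    -model_density_score(transform_model(model, tr), density, resolution_A)
  }
  # two-stage local search; optim's Nelder-Mead starts its simplex at
  # 0.1 * parscale, so parscale encodes 10x the initial step
  opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                      control = list(maxit = max_refine, reltol = 1e-8,
                                     parscale = 10 * c(3, 3, 3, vs, vs, vs)))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = max_refine, reltol = 1e-9,
                                     parscale = 10 * c(0.5, 0.5, 0.5,
                                                       vs / 5, vs / 5, vs / 5)))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = max_refine, reltol = 1e-10,
                                     parscale = 10 * c(0.1, 0.1, 0.1,
                                                       vs / 25, vs / 25, vs / 25)))
  p <- opt$par
  final <- rigid_transform(euler_to_matrix(p[1], p[2], p[3]) %*% start$rotation,
                           start$translation + p[4:6])
  list(transform = final, score = -opt$value,
       model = transform_model(model, final))
}

#' Independent rigid fits of model domains
#'
#' Each domain is fitted with the density contribution of the other domains
#' (rendered at their current pose) subtracted from the target, so a moved
#' domain is pulled into its own density.
#'
#' @param model \code{atom_model}.
#' @param density target \code{density_map}.
#' @param domain_split list of character vectors of domain tags; must cover
#'   the model without overlap.
#' @param resolution_A rendering resolution.
#' @param coarse_step_deg forwarded to \code{\link{rigid_fit}} (NULL = local).
#' @return named list per domain group: list(transform, score, model).
#' @export
fit_domains <- function(model, density, domain_split, resolution_A = 10,
                        coarse_step_deg = NULL) {
  tags <- unlist(domain_split)
  if (any(duplicated(tags)))
    stop("overlapping domain tags: ", paste(tags[duplicated(tags)], collapse = ", "))
  if (!all(model$atoms$domain %in% tags))
    stop("domain split does not cover: ",
         paste(setdiff(unique(model$atoms$domain), tags), collapse = ", "))
  n <- dim(as_grid(density))[1]
  vs <- density$voxel_size
  out <- list()
  for (gi in seq_along(domain_split)) {
    tg <- domain_split[[gi]]
    others <- setdiff(tags, tg)
    rows <- model$atoms$domain %in% tg
    sub <- atom_model(model$atoms[rows, ])
    target <- as_grid(density)
    if (length(others) > 0) {
      rest <- atom_model(model$atoms[model$atoms$domain %in% others, ])
      target <- target - as_grid(model_to_density(rest, n, vs, resolution_A))
    }
    fit <- rigid_fit(sub, density_map(target, vs, density$origin),
                     resolution_A, coarse_step_deg)
    nm <- paste(tg, collapse = "+")
    out[[nm]] <- fit
  }
  out
}

#' Scan a helix along its own axis for the best density fit
#'
#' The helix axis is the first principal axis of the selected backbone atoms;
#' the model-density correlation of the helix alone is evaluated on a grid of
#' axial translations and the best shift applied.
#'
#' @param model \code{atom_model}.
#' @param selection selection list picking the helix (>= 5 residues).
#' @param density target \code{density_map}.
#' @param scan_range_A half-range of the axial scan (default 20).
#' @param step_A scan step (default 0.5).
#' @param resolution_A rendering resolution.
#' @return list(shift_A, model = adjusted \code{atom_model}, profile =
#'   data.frame(shift_A, score), axis).
#' @export
shift_helix <- function(model, selection, density, scan_range_A = 20,
                        step_A = 0.5, resolution_A = 10) {
  rows <- model_select(model, selection)
  xyz <- as.matrix(model$atoms[rows, c("x", "y", "z")])
  if (nrow(xyz) < 5) stop("helix selection needs at least 5 residues")
  pc <- stats::prcomp(xyz)
  axis <- pc$rotation[, 1]
  lin <- pc$sdev[1]^2 / sum(pc$sdev^2)
  if (lin < 0.7)
    warning("selection poorly linear (axis quality ", round(lin, 2),
            "); axis may be unreliable")
  helix <- atom_model(model$atoms[rows, ])
  # scan against the target with the rest of the model's contribution
  # removed, so neighboring rods do not bias the axial profile
  n <- dim(as_grid(density))[1]
  rest <- atom_model(model$atoms[!rows, ])
  target <- density_map(as_grid(density) -
                          as_grid(model_to_density(rest, n,
                                                   density$voxel_size,
                                                   resolution_A)),
                        density$voxel_size, density$origin)
  shifts <- seq(-scan_range_A, scan_range_A, by = step_A)
  scores <- vapply(shifts, function(s) {
    moved <- transform_model(helix, rigid_transform(diag(3), axis * s))
    model_density_score(moved, target, resolution_A)
  }, 0)
  best <- shifts[which.max(scores)]
  out <- model
  out$atoms[rows, c("x", "y", "z")] <-
    sweep(xyz, 2, axis * best, `+`)
  list(shift_A = best, model = out,
       profile = data.frame(shift_A = shifts, score = scores), axis = axis)
}

#' Elastic-restrained flexible refinement into a density map
#'
#' A simplified flexible-fitting surrogate: atoms ascend the interpolated
#' density gradient under harmonic restraints on bonded (consecutive-residue)
#' distances and on displacement from the start, with an annealed
#' (geometrically decaying) step size.  Deterministic given \code{seed}.
#' This is an elastic-network refinement, not a molecular-dynamics force
#' field.
#'
#' @param model starting \code{atom_model} (already rigid/domain fitted).
#' @param density target \code{density_map}.
#' @param restraint_k displacement-restraint strength (default 0.15).
#' @param bond_k bonded-distance restraint strength (default 1).
#' @param steps gradient steps (default 200).
#' @param step_A initial step size (default 0.2 A), annealed by 0.995/step.
#' @param resolution_A rendering resolution for the score trace.
#' @param seed integer (reserved for stochastic variants; the default
#'   annealing is deterministic).
#' @return list(model, rmsd_to_start_A, score_trace).
#' @export
flexible_refine <- function(model, density, restraint_k = 0.15, bond_k = 1,
                            steps = 200, step_A = 0.2, resolution_A = 10,
                            seed = 1) {
  set.seed(seed)
  g <- as_grid(density)
  n <- dim(g)[1]
  vs <- density$voxel_size
  sc <- max(abs(g))
  if (sc > 0) g <- g / sc
  # central-difference gradient volumes (per A)
  gx <- (shift_volume_real(g, c(-1, 0, 0)) - shift_volume_real(g, c(1, 0, 0))) / (2 * vs)
  gy <- (shift_volume_real(g, c(0, -1, 0)) - shift_volume_real(g, c(0, 1, 0))) / (2 * vs)
  gz <- (shift_volume_real(g, c(0, 0, -1)) - shift_volume_real(g, c(0, 0, 1))) / (2 * vs)
  xyz0 <- model_coords(model)
  xyz <- xyz0
  at <- model$atoms
  # bonded pairs: consecutive resno within a chain
  ord <- order(at$chain, at$resno)
  bonded <- which(diff(at$resno[ord]) == 1 &
                  at$chain[ord][-1] == at$chain[ord][-nrow(at)])
  bi <- ord[bonded]; bj <- ord[bonded + 1]
  d0 <- sqrt(rowSums((xyz0[bi, , drop = FALSE] - xyz0[bj, , drop = FALSE])^2))
  c0 <- vol_center(n)
  trace <- numeric(0)
  stp <- step_A
  for (it in seq_len(steps)) {
    vx <- (xyz[, 1]) / vs + c0
    vy <- (xyz[, 2]) / vs + c0
    vz <- (xyz[, 3]) / vs + c0
    if (any(vx < 2 | vx > n - 1 | vy < 2 | vy > n - 1 | vz < 2 | vz > n - 1))
      stop("divergence: atom left the density box at step ", it)
    grad <- cbind(trilinear_sample(gx, vx, vy, vz),
                  trilinear_sample(gy, vx, vy, vz),
                  trilinear_sample(gz, vx, vy, vz))
    # restraints
    grad <- grad - restraint_k * (xyz - xyz0)
    if (length(bi) > 0) {
      dv <- xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE]
      dn <- sqrt(rowSums(dv^2))
      f <- bond_k * (dn - d0) / pmax(dn, 1e-6)
      fb <- dv * f
      for (kk in seq_along(bi)) {
        grad[bi[kk], ] <- grad[bi[kk], ] - fb[kk, ]
        grad[bj[kk], ] <- grad[bj[kk], ] + fb[kk, ]
      }
    }
    gn <- sqrt(rowSums(grad^2))
    gmax <- max(gn)
    if (gmax > 0) xyz <- xyz + grad / gmax * stp
    stp <- stp * 0.995
  }
  out <- set_model_coords(model, xyz)
  trace <- model_density_score(out, density, resolution_A)
  list(model = out,
       rmsd_to_start_A = sqrt(mean(rowSums((xyz - xyz0)^2))),
       score_trace = trace)
}

#' Screw decomposition of a rigid transform (Chasles' theorem)
#'
#' Expresses a transform as a rotation by \code{angle} about a line (unit
#' \code{axis} through \code{point}) plus a \code{translation} along that
#' axis.  Reconstructing via \code{\link{screw_transform}} reproduces the
#' input.  For near-zero angles the axis is undefined and flagged.
#'
#' @param t \code{rigid_transform}.
#' @return object of class \code{screw_decomposition}: list(angle_deg, axis,
#'   translation_A, point, axis_defined).
#' @export
screw_decompose <- function(t) {
  R <- t$rotation
  tr <- sum(diag(R))
  angle <- acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
  if (angle < 1e-7) {
    return(structure(list(angle_deg = 0, axis = c(NA, NA, NA),
                          translation_A = sqrt(sum(t$translation^2)),
                          point = c(0, 0, 0), axis_defined = FALSE),
                     class = "screw_decomposition"))
  }
  if (angle > 180 - 1e-6) {
    # axis from the eigenvector of R for eigenvalue +1
    ev <- eigen(R)
    k <- which.min(Mod(ev$values - 1))
    axis <- Re(ev$vectors[, k])
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle * pi / 180))
  }
  axis_norm <- sqrt(sum(axis^2))
  if (!is.finite(axis_norm) || axis_norm < 1e-12) {
    # numerically symmetric R with trace just below 3: acos rounding reports a
    # tiny angle but the skew part vanishes, so the axis is undefined
    return(structure(list(angle_deg = 0, axis = c(NA, NA, NA),
                          translation_A = sqrt(sum(t$translation^2)),
                          point = c(0, 0, 0), axis_defined = FALSE),
                     class = "screw_decomposition"))
  }
  axis <- axis / axis_norm
  h <- sum(t$translation * axis)
  t_perp <- t$translation - h * axis
  # (I - R) p = t_perp with p orthogonal to axis (minimum-norm solution)
  A <- diag(3) - R
  sv <- svd(A)
  inv_d <- ifelse(sv$d > 1e-9, 1 / sv$d, 0)
  p <- as.numeric(sv$v %*% (inv_d * (t(sv$u) %*% t_perp)))
  structure(list(angle_deg = angle, axis = axis, translation_A = h,
                 point = p, axis_defined = TRUE),
            class = "screw_decomposition")
}

#' @export
print.screw_decomposition <- function(x, ...) {
  cat(sprintf("screw: %.2f deg about (%.3f, %.3f, %.3f), %.2f A along axis\n",
              x$angle_deg, x$axis[1], x$axis[2], x$axis[3], x$translation_A))
  invisible(x)
}

#' Rebuild a rigid transform from its screw decomposition
#' @param s \code{screw_decomposition} (or equivalent list).
#' @return \code{rigid_transform}.
#' @export
screw_transform <- function(s) {
  if (!isTRUE(s$axis_defined))
    return(rigid_transform(diag(3), c(0, 0, 0)))
  R <- axis_angle_matrix(s$axis, s$angle_deg)
  t <- as.numeric((diag(3) - R) %*% s$point) + s$translation_A * s$axis
  rigid_transform(R, t)
}

#' Write / read models as PDB through bio3d
#'
#' Domain tags are not representable in PDB; \code{read_model_pdb} assigns
#' them from a selection table (data.frame chain, resno_start, resno_end,
#' domain, as produced by \code{\link{read_domain_file}}), defaulting to the
#' chain id.
#'
#' @param model \code{atom_model}.
#' @param path file path.
#' @param domains optional domain selection data.frame.
#' @return \code{read_model_pdb} returns an \code{atom_model}.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  na <- nrow(at)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain,
                   resid = rep("ALA", na), elety = at$name,
                   o = rep(1, na), b = rep(0, na))
  invisible(path)
}

#' @rdname write_model_pdb
#' @export
read_model_pdb <- function(path, domains = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  dom <- at$chain
  if (!is.null(domains)) {
    for (i in seq_len(nrow(domains))) {
      hit <- at$chain == domains$chain[i] &
        at$resno >= domains$resno_start[i] & at$resno <= domains$resno_end[i]
      dom[hit] <- domains$domain[i]
    }
  }
  atom_model(data.frame(name = at$elety, resno = at$resno, chain = at$chain,
                        domain = dom, x = at$x, y = at$y, z = at$z))
}

#' Read a plain-text domain selection file
#'
#' Whitespace-separated columns: domain, chain, resno_start, resno_end;
#' lines starting with # are comments.
#'
#' @param path file path.
#' @return data.frame(domain, chain, resno_start, resno_end).
#' @export
read_domain_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("domain", "chain", "resno_start",
                                         "resno_end"))
  tab
}
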