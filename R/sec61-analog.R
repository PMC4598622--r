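#' Synthetic Sec61 analog: a 10-helix bundle with accessory chains
#'
#' A C-alpha-only stand-in for the protein-conducting channel used by the
#' tests and the validation workflow: ten transmembrane helices (TMH1-10) of
#' the alpha subunit arranged on two half-rings (N-half: TMH1-5, C-half:
#' TMH6-9 plus TMH10 tagged separately), one beta and one gamma helix.  It is
#' synthetic — a geometric analog, not deposited coordinates — but carries the
#' domain structure needed to exercise domain-wise fitting, helix-axis scans,
#' flexible refinement and screw-motion analysis.
#'
#' The open-gate conformer is generated from the closed one by a screw motion
#' of the N-half (rotation \code{gate_angle_deg} about a membrane-normal axis
#' through the gate, translation \code{gate_translation_A} along that axis)
#' and an axial shift of TMH10 by \code{tmh10_shift_A} towards the ribosome
#' (+z), the geometry reported for the native lateral gate.
#'
#' @param gate_angle_deg N-half rotation (default 22).
#' @param gate_translation_A N-half translation along the rotation axis
#'   (default 13.8).
#' @param tmh10_shift_A TMH10 axial shift (default 13).
#' @param n_res residues per helix (default 22).
#' @return list(closed, open = \code{atom_model}s, gate_transform =
#'   generating \code{rigid_transform} of the N-half motion, axis_point).
#' @export
sec61_analog <- function(gate_angle_deg = 22, gate_translation_A = 13.8,
                         tmh10_shift_A = 13, n_res = 22) {
  helices <- list()
  ring_r <- 16
  for (h in 1:10) {
    ang <- 2 * pi * (h - 0.5) / 10
    pos <- c(ring_r * cos(ang), ring_r * sin(ang), -16)
    # alternate slight tilts so the bundle is not degenerate
    dirv <- c(0.15 * cos(ang + h), 0.15 * sin(ang + h), 1)
    dom <- if (h <= 5) "N-half" else if (h == 10) "TMH10" else "C-half"
    helices[[h]] <- make_helix_model(n_res, start = pos, direction = dirv,
                                     chain = "A", domain = dom,
                                     resno_start = 100 * h,
                                     phase_deg = 37 * h)
  }
  beta <- make_helix_model(n_res, start = c(30, 8, -16),
                           direction = c(0.1, 0, 1), chain = "B",
                           domain = "beta")
  gamma <- make_helix_model(n_res, start = c(-28, -10, -16),
                            direction = c(-0.1, 0.05, 1), chain = "G",
                            domain = "gamma")
  closed <- do.call(combine_models, c(helices, list(beta, gamma)))

  # lateral-gate screw: axis along z through the gate-side point
  axis <- c(0, 0, 1)
  axis_point <- c(ring_r, 0, 0)
  R <- axis_angle_matrix(axis, gate_angle_deg)
  tvec <- as.numeric((diag(3) - R) %*% axis_point) + gate_translation_A * axis
  gate_transform <- rigid_transform(R, tvec)
  open <- transform_model(closed, gate_transform,
                          selection = list(domain = c("N-half", "beta")))
  # TMH10 axial shift towards the ribosome (+z)
  rows <- model_select(open, list(domain = "TMH10"))
  xyz <- as.matrix(open$atoms[rows, c("x", "y", "z")])
  pc <- stats::prcomp(xyz)
  ax10 <- pc$rotation[, 1]
  if (ax10[3] < 0) ax10 <- -ax10           # orient towards +z (ribosome side)
  open$atoms[rows, c("x", "y", "z")] <- sweep(xyz, 2, ax10 * tmh10_shift_A, `+`)
  list(closed = closed, open = open, gate_transform = gate_transform,
       axis_point = axis_point, tmh10_axis = ax10)
}
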