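## Local base-pair step and helical parameters.
##
## Step parameters (shift, slide, rise, tilt, roll, twist) use the
## symmetric mid-step-frame decomposition: the two pair frames are rotated
## by half the hinge angle onto a common mid-frame z, twist is measured
## between the half-rotated x axes, tilt/roll are the hinge angle resolved
## along the mid-frame x/y axes, and the displacement is the origin
## difference expressed in mid-frame coordinates.
##
## Local helical parameters (x/y-displacement, inclination, tip, helical
## rise, helical twist) come from the screw axis of the relative transform
## between consecutive pair frames: helical twist is the rotation angle
## about the axis, helical rise the displacement component along it,
## x/y-displacement the perpendicular offset of the pair-frame origin from
## the axis expressed in pair-frame coordinates, and inclination/tip the
## orientation angles of the pair frame relative to the axis.

#' Mid-frame of a base pair
#'
#' Averages the two base frames of a pair after flipping the complementary
#' (strand II) base's y and z axes per the standard convention, then
#' re-orthonormalizes (nearest proper rotation).
#'
#' @param frame_i Frame of the strand-I base.
#' @param frame_j Frame of the strand-II base (will be flipped).
#' @return A `base_frame` for the pair.
#' @export
pair_frame <- function(frame_i, frame_j) {
  if (is.null(frame_i) || is.null(frame_j)) stop("missing base frame")
  fj <- flip_frame(frame_j)
  axes <- nearest_rotation(frame_i$axes + fj$axes)
  new_base_frame((frame_i$origin + fj$origin) / 2, axes,
                 fit_rmsd = max(frame_i$fit_rmsd, fj$fit_rmsd))
}

#' Step and local helical parameters between two pair frames
#'
#' @param frame_i,frame_j Consecutive pair frames (orthonormal axes).
#' @return List of class `step_parameters` with elements `shift`, `slide`,
#'   `rise`, `tilt`, `roll`, `twist` (step parameters), `x_displacement`,
#'   `y_displacement`, `inclination`, `tip`, `helical_rise`,
#'   `helical_twist` (local helical parameters), and `axis` (list with
#'   unit `direction` and a `point` on the local helix axis).  Angles in
#'   degrees, lengths in Angstrom.
#' @export
step_parameters <- function(frame_i, frame_j) {
  R1 <- frame_i$axes; R2 <- frame_j$axes
  o1 <- frame_i$origin; o2 <- frame_j$origin

  ## ---- mid-frame step decomposition
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- rad2deg(acos(cg))
  cr <- cross3(z1, z2)
  if (vnorm(cr) > 1e-9) {
    hinge <- unitv(cr)
    R1p <- rotation_about(hinge, gamma / 2) %*% R1
    R2p <- rotation_about(hinge, -gamma / 2) %*% R2
  } else {
    hinge <- NULL
    R1p <- R1; R2p <- R2
  }
  zm <- R1p[, 3]
  twist <- signed_angle_about(R1p[, 1], R2p[, 1], zm)
  Rm <- nearest_rotation(R1p + R2p)
  if (!is.null(hinge)) {
    phi <- signed_angle_about(hinge, Rm[, 2], zm)
    tilt <- gamma * sin(deg2rad(phi))
    roll <- gamma * cos(deg2rad(phi))
  } else {
    tilt <- 0; roll <- 0
  }
  disp <- as.numeric(t(Rm) %*% (o2 - o1))

  ## ---- screw decomposition for the local helical parameters
  Rg <- R2 %*% t(R1)
  aa <- rotation_axis_angle(Rg)
  d <- o2 - o1
  if (aa$angle < 1e-9 || anyNA(aa$axis)) {
    ## degenerate screw: axis taken from the mean frame z (logged rule)
    u <- unitv((z1 + z2) / 2)
    h_twist <- 0
    h_rise <- sum(d * u)
    perp <- d - h_rise * u
    ## displacement defined as perpendicular offset of origin difference
    v <- -perp / 2
    axis_point <- o1 - v
  } else {
    u <- aa$axis
    ## orient the axis along the mean frame advance
    if (sum(u * (z1 + z2)) < 0) { u <- -u; aa$angle <- -aa$angle }
    h_twist <- wrap180(signed_angle_about(
      R1[, 1] - sum(R1[, 1] * u) * u,
      R2[, 1] - sum(R2[, 1] * u) * u, u))
    h_rise <- sum(d * u)
    ## axis point c: (I - Rg)(o1 - c) = perpendicular part of -d
    P <- diag(3) - u %o% u
    dperp <- as.numeric(P %*% d)
    A <- (Rg - diag(3)) %*% P
    ## solve in the plane perpendicular to u (A is rank 2)
    sol <- tryCatch(qr.solve(A + u %o% u, dperp), error = function(e) NULL)
    if (is.null(sol)) {
      axis_point <- o1; v <- c(0, 0, 0)
    } else {
      w <- as.numeric(P %*% sol)        # o1 - c, perpendicular component
      axis_point <- o1 - w
      v <- w
    }
  }
  ## perpendicular offset of the pair origin from the axis, in pair-frame
  ## coordinates of frame i
  v_local <- as.numeric(t(R1) %*% v)
  x_disp <- v_local[1]; y_disp <- v_local[2]
  ## inclination / tip from the axis direction expressed in the pair frame
  u_local <- as.numeric(t(R1) %*% u)
  czz <- max(-1, min(1, u_local[3]))
  big_gamma <- rad2deg(acos(czz))
  hcr <- cross3(c(0, 0, 1), u_local)
  if (vnorm(hcr) > 1e-9) {
    hloc <- unitv(hcr)
    inclination <- -big_gamma * hloc[1]
    tip <- -big_gamma * hloc[2]
  } else {
    inclination <- 0; tip <- 0
  }
  structure(list(shift = disp[1], slide = disp[2], rise = disp[3],
                 tilt = tilt, roll = roll, twist = wrap180(twist),
                 x_displacement = x_disp, y_displacement = y_disp,
                 inclination = inclination, tip = tip,
                 helical_rise = h_rise, helical_twist = wrap180(h_twist),
                 axis = list(direction = u, point = axis_point)),
            class = "step_parameters")
}

#' Step parameters for an ordered series of pair frames
#'
#' @param pair_frames List of pair frames in duplex order.
#' @return data.frame with one row per dinucleotide step (all twelve
#'   parameters).
#' @export
step_series <- function(pair_frames) {
  n <- length(pair_frames)
  if (n < 2) stop("need at least two pair frames for a step")
  rows <- lapply(seq_len(n - 1L), function(i) {
    sp <- step_parameters(pair_frames[[i]], pair_frames[[i + 1L]])
    data.frame(step = i, shift = sp$shift, slide = sp$slide,
               rise = sp$rise, tilt = sp$tilt, roll = sp$roll,
               twist = sp$twist, x_displacement = sp$x_displacement,
               y_displacement = sp$y_displacement,
               inclination = sp$inclination, tip = sp$tip,
               helical_rise = sp$helical_rise,
               helical_twist = sp$helical_twist)
  })
  do.call(rbind, rows)
}

.ANGLE_PARAMS <- c("tilt", "roll", "twist", "inclination", "tip",
                   "helical_twist")

#' Summarize duplex geometry from a series of steps
#'
#' Means and SDs per parameter (circular statistics for angles, arithmetic
#' for lengths), residues per turn (360 / mean helical twist) and helical
#' pitch (mean helical rise x residues per turn; the identity is enforced
#' before any rounding).
#'
#' @param steps data.frame from [step_series()].
#' @param window Optional averaging-window description recorded as
#'   provenance.
#' @param minor_groove Optional minor-groove width (Angstrom) to carry into
#'   the summary.
#' @return List of class `helix_summary`.
#' @export
summarize_helix <- function(steps, window = NULL, minor_groove = NULL) {
  if (is.null(steps) || nrow(steps) < 1) stop("empty step list")
  params <- setdiff(names(steps), "step")
  mean_of <- function(p) if (p %in% .ANGLE_PARAMS) circular_mean(steps[[p]])
                         else mean(steps[[p]], na.rm = TRUE)
  sd_of <- function(p) if (p %in% .ANGLE_PARAMS) circular_sd(steps[[p]])
                       else stats::sd(steps[[p]], na.rm = TRUE)
  means <- vapply(params, mean_of, numeric(1))
  sds <- vapply(params, sd_of, numeric(1))
  rpt <- 360 / means[["helical_twist"]]
  pitch <- means[["helical_rise"]] * rpt
  structure(list(mean = means, sd = sds, n_steps = nrow(steps),
                 residues_per_turn = rpt, helical_pitch = pitch,
                 minor_groove = minor_groove, window = window),
            class = "helix_summary")
}

#' @export
print.helix_summary <- function(x, digits = 2, ...) {
  cat("Average helical parameters (", x$n_steps, " steps",
      if (!is.null(x$window)) paste0("; window ",
                                     paste(unlist(x$window), collapse = "-")),
      ")\n", sep = "")
  show <- c("x_displacement", "inclination", "helical_rise",
            "helical_twist")
  labs <- c("X-displacement [A]", "Inclination [deg]",
            "Helical rise [A]", "Helical twist [deg]")
  for (i in seq_along(show)) {
    cat(sprintf("  %-20s %6.*f (%.*f)\n", labs[i], digits,
                x$mean[[show[i]]], digits, max(0, x$sd[[show[i]]])))
  }
  cat(sprintf("  %-20s %6.*f\n", "Residues per turn", digits,
              x$residues_per_turn))
  cat(sprintf("  %-20s %6.*f\n", "Helical pitch [A]", digits,
              x$helical_pitch))
  if (!is.null(x$minor_groove) && is.finite(x$minor_groove))
    cat(sprintf("  %-20s %6.*f\n", "Minor groove [A]", digits,
                x$minor_groove))
  invisible(x)
}

#' Minor-groove width from interstrand P-P distances
#'
#' For each phosphorus of one strand the closest phosphorus of the other
#' strand is found; widths are those distances minus 5.8 Angstrom to
#' account for the van der Waals radii of the phosphate groups.  The
#' summary statistic is the global minimum interstrand P-P distance minus
#' 5.8 (the closest approach); per-position widths are reported for
#' diagnostics.
#'
#' @param structure An `xna_structure`.
#' @param chain_pair Two chain ids.
#' @param window Optional inclusive seq-id window (applied to both chains,
#'   or a list of two windows).
#' @param vdw_correction Correction subtracted from P-P distances
#'   (default 5.8 Angstrom).
#' @return List with `width` (minimum-based summary), `per_position`
#'   (data.frame) and `n_p` (phosphate counts).  When either strand has no
#'   phosphorus in the window, `width` is `NA` and the result is flagged
#'   `undefined`.
#' @export
minor_groove_width <- function(structure, chain_pair, window = NULL,
                               vdw_correction = 5.8) {
  p_coords <- function(chain_id, rng) {
    ch <- structure$chains[[chain_id]]
    if (is.null(ch)) stop("chain not found: ", chain_id)
    out <- list()
    for (res in ch$residues) {
      if (!is.null(rng) && (res$seq_id < rng[1] || res$seq_id > rng[2]))
        next
      p <- atom_xyz(res, "P")
      if (!anyNA(p))
        out[[length(out) + 1L]] <- c(seq_id = res$seq_id, as.numeric(p))
    }
    if (!length(out)) return(NULL)
    m <- do.call(rbind, out)
    colnames(m) <- c("seq_id", "x", "y", "z")
    m
  }
  if (!is.null(window) && !is.list(window)) window <- list(window, window)
  p1 <- p_coords(chain_pair[1], window[[1]])
  p2 <- p_coords(chain_pair[2], window[[2]])
  if (is.null(p1) || is.null(p2)) {
    return(list(width = NA_real_, per_position = NULL,
                n_p = c(if (is.null(p1)) 0L else nrow(p1),
                        if (is.null(p2)) 0L else nrow(p2)),
                undefined = TRUE))
  }
  dmat <- sqrt(outer(p1[, "x"], p2[, "x"], "-")^2 +
               outer(p1[, "y"], p2[, "y"], "-")^2 +
               outer(p1[, "z"], p2[, "z"], "-")^2)
  per <- data.frame(
    seq_id = p1[, "seq_id"],
    closest_seq = p2[apply(dmat, 1, which.min), "seq_id"],
    pp_distance = apply(dmat, 1, min)
  )
  per$width <- per$pp_distance - vdw_correction
  list(width = min(dmat) - vdw_correction, per_position = per,
       n_p = c(nrow(p1), nrow(p2)), undefined = FALSE)
}
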