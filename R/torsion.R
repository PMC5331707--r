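#' Centroid of the endocardial boundary of a myocardial mask
#'
#' The endocardial boundary is the set of masked pixels 4-adjacent to the
#' blood-pool cavity (the background component containing the mask's own
#' centroid pixel). Falls back to the mask centroid if no cavity exists.
#'
#' @param mask logical myocardial mask.
#' @param pixel_spacing mm per pixel.
#' @return `c(x, y)` centroid in mm, in the image-centered coordinate frame.
#' @export
endocardial_centroid <- function(mask, pixel_spacing) {
  g <- nrow(mask)
  coord <- (seq_len(g) - 1 - (g - 1) / 2) * pixel_spacing
  pts <- which(mask)
  rows <- (pts - 1) %% g + 1
  cols <- (pts - 1) %/% g + 1
  cr <- round(mean(rows)); cc <- round(mean(cols))
  if (!mask[cr, cc] && any(!mask)) {
    cavity <- connected_component(!mask, cr, cc)
    # masked pixels with a 4-neighbor in the cavity
    nb <- matrix(FALSE, g, ncol(mask))
    nb[-1, ] <- nb[-1, ] | cavity[-g, ]
    nb[-g, ] <- nb[-g, ] | cavity[-1, ]
    nb[, -1] <- nb[, -1] | cavity[, -ncol(mask)]
    nb[, -ncol(mask)] <- nb[, -ncol(mask)] | cavity[, -1]
    boundary <- mask & nb
    if (any(boundary)) {
      bp <- which(boundary)
      return(c(x = mean(coord[(bp - 1) %/% g + 1]),
               y = mean(coord[(bp - 1) %% g + 1])))
    }
  }
  c(x = mean(coord[cols]), y = mean(coord[rows]))
}

#' Rotation (twist) curve of one slice
#'
#' Per frame, the bulk in-plane translation (mean displacement over all
#' points) is subtracted, then each myocardial point's signed rotation angle
#' about the end-diastolic endocardial centroid is computed with the
#' two-argument arctangent of the cross and dot products of its position
#' vectors before and after displacement. The slice angle is the circular
#' mean over points, in degrees, counter-clockwise positive viewed
#' foot-to-head.
#'
#' @param traj a [build_trajectories()] result.
#' @param centroid optional `c(x, y)` centroid in mm; computed from the mask
#'   at end-diastole if `NULL`.
#' @return an object of class `twist_curve` with per-frame `angles_deg`.
#' @export
rotation_curve <- function(traj, centroid = NULL) {
  stopifnot(inherits(traj, "displacement_trajectories"))
  if (length(traj$x0) == 0) stop("empty mask: no trajectories")
  if (is.null(centroid))
    centroid <- endocardial_centroid(traj$mask, traj$pixel_spacing)
  v0x <- traj$x0 - centroid[[1]]
  v0y <- traj$y0 - centroid[[2]]
  nf <- nrow(traj$ux)
  ang <- numeric(nf)
  for (f in seq_len(nf)) {
    ux <- traj$ux[f, ] - mean(traj$ux[f, ])  # bulk translation correction
    uy <- traj$uy[f, ] - mean(traj$uy[f, ])
    vtx <- v0x + ux
    vty <- v0y + uy
    a <- atan2(v0x * vty - v0y * vtx, v0x * vtx + v0y * vty)
    ang[f] <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi  # circular mean
  }
  structure(list(
    angles_deg = ang,
    frame_times = traj$frame_times,
    slice_label = traj$slice_label,
    plane_position = traj$plane_position,
    subject_id = traj$subject_id,
    acquisition_index = traj$acquisition_index
  ), class = "twist_curve")
}

#' @export
print.twist_curve <- function(x, ...) {
  cat(sprintf("<twist_curve> %s slice at %.1f mm: peak |angle| %.2f deg over %d frames\n",
              x$slice_label %||% "?", x$plane_position,
              max(abs(x$angles_deg)), length(x$angles_deg)))
  invisible(x)
}

#' Basal-apical distance from plane metadata
#'
#' Uses only the recorded plane positions (the stand-in for slice locations
#' read from image headers); true breath-hold offsets are invisible here by
#' construction.
#'
#' @param basal,apical `twist_curve` objects (or anything with a
#'   `plane_position` field in mm).
#' @return distance in cm.
#' @export
slice_distance <- function(basal, apical) {
  pb <- basal$plane_position
  pa <- apical$plane_position
  if (is.null(pb) || is.null(pa)) stop("plane positions missing")
  d <- abs(pa - pb) / 10
  if (d == 0) stop("basal and apical plane positions coincide (zero distance)")
  d
}

#' Torsion curve from a basal and an apical twist curve
#'
#' Torsion is the twist (apical minus basal rotation) divided by the
#' basal-apical distance taken from plane metadata. Peak torsion is the
#' maximum of the per-frame torsion curve.
#'
#' @param basal,apical `twist_curve` objects with equal frame counts.
#' @return an object of class `torsion_measurement` with fields `tau`
#'   (deg/cm per frame), `peak_torsion`, and `d_cm`.
#' @export
torsion_curve <- function(basal, apical) {
  if (length(basal$angles_deg) != length(apical$angles_deg))
    stop("basal and apical curves have different frame counts")
  d <- slice_distance(basal, apical)
  tau <- (apical$angles_deg - basal$angles_deg) / d
  structure(list(
    tau = tau,
    peak_torsion = max(tau),
    d_cm = d,
    frame_times = basal$frame_times,
    basal_ref = basal$acquisition_index,
    apical_ref = apical$acquisition_index,
    subject_id = basal$subject_id
  ), class = "torsion_measurement")
}

#' @export
print.torsion_measurement <- function(x, ...) {
  cat(sprintf("<torsion_measurement> peak %.3f deg/cm over d = %.2f cm\n",
              x$peak_torsion, x$d_cm))
  invisible(x)
}

#' Twist curve directly from a slice acquisition
#'
#' Convenience wrapper: reconstruct trajectories, then compute the rotation
#' curve.
#'
#' @param acq a `slice_acquisition`.
#' @param params a [recon_params()].
#' @return a `twist_curve`.
#' @export
twist_from_acquisition <- function(acq, params = recon_params()) {
  rotation_curve(build_trajectories(acq, params))
}
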