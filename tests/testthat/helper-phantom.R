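# Shared fixtures: reduced-size phantom configurations so the suite stays
# fast. Geometry and kinematics keep their default physiology; only the grid
# and frame count shrink.

small_cfg <- function(noise = 0, ...) {
  phantom_config(grid_size = 32, n_frames = 12, phase_noise_sd = noise, ...)
}

default_resp <- function(...) respiratory_config(...)

sim_slice <- function(cfg, resp, z, dz, label = "basal", idx = 1L) {
  lvtorsion:::simulate_slice_acquisition(cfg, resp, z, dz, label, idx)
}

# Independent unwrapping oracle: cumulative 1D unwrapping down the seed
# column, then along every row. Only valid for full-rectangle masks and
# smooth fields (inter-pixel steps < pi).
unwrap_rowwise_oracle <- function(wrapped, seed = c(1L, 1L)) {
  wr <- function(x) x - 2 * pi * round(x / (2 * pi))
  out <- matrix(NA_real_, nrow(wrapped), ncol(wrapped))
  sc <- seed[2]
  col <- wrapped[, sc]
  ucol <- col
  for (r in seq_along(col)[-seq_len(seed[1])])
    ucol[r] <- ucol[r - 1] + wr(col[r] - col[r - 1])
  for (r in rev(seq_len(seed[1] - 1)))
    ucol[r] <- ucol[r + 1] + wr(col[r] - col[r + 1])
  for (r in seq_len(nrow(wrapped))) {
    row <- wrapped[r, ]
    urow <- row
    urow[sc] <- ucol[r]
    for (cc in seq_along(row)[-seq_len(sc)])
      urow[cc] <- urow[cc - 1] + wr(row[cc] - row[cc - 1])
    for (cc in rev(seq_len(sc - 1)))
      urow[cc] <- urow[cc + 1] + wr(row[cc] - row[cc + 1])
    out[r, ] <- urow
  }
  out
}

# Random smooth phase field: plane ramp plus a gentle low-frequency bump,
# with inter-pixel steps safely below pi.
random_smooth_field <- function(nr, nc) {
  a <- stats::runif(1, -1.2, 1.2)
  b <- stats::runif(1, -1.2, 1.2)
  if (abs(a) + abs(b) > 0.9 * pi) {
    s <- 0.9 * pi / (abs(a) + abs(b)); a <- a * s; b <- b * s
  }
  amp <- stats::runif(1, 0, 0.5)
  phx <- stats::runif(1, 0, 2 * pi)
  outer(seq_len(nr), seq_len(nc), function(r, cc)
    a * r + b * cc + amp * sin(2 * pi * r / nr + phx) * cos(2 * pi * cc / nc))
}

# Build a displacement_trajectories object directly (unit tests of the
# quantification layer without the recon chain).
make_traj <- function(x0, y0, ux, uy, plane = 22, label = "basal", idx = 1L) {
  structure(list(
    x0 = x0, y0 = y0, ux = ux, uy = uy,
    frame_times = (seq_len(nrow(ux)) - 1) * 34,
    mask = NULL, pixel_spacing = 2.8,
    plane_position = plane, slice_label = label,
    acquisition_index = idx, subject_id = "T"
  ), class = "displacement_trajectories")
}

make_twist <- function(angles, plane, label = "basal", idx = 1L) {
  structure(list(angles_deg = angles,
                 frame_times = (seq_along(angles) - 1) * 34,
                 slice_label = label, plane_position = plane,
                 subject_id = "T", acquisition_index = idx),
            class = "twist_curve")
}
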