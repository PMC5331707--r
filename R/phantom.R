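#' Phantom configuration: geometric and kinematic truth for the synthetic LV
#'
#' The phantom is an annular short-axis cross-section of the left ventricle
#' that rotates about its long axis with a longitudinal twist gradient and
#' contracts radially over the cardiac cycle. `long_axis_length` is the
#' end-systolic endocardial long-axis length, i.e. the span over which the
#' five short-axis slices are planned.
#'
#' @param long_axis_length end-systolic endocardial long-axis length, mm.
#' @param endo_radius_ed endocardial radius at end-diastole, mm.
#' @param epi_radius_ed epicardial radius at end-diastole, mm.
#' @param twist_gradient true longitudinal gradient of rotation at
#'   end-systole, deg/cm. Default 3.4, a typical healthy-adult value.
#' @param twist_profile `"linear"` (rotation angle linear in longitudinal
#'   position, the default) or `"sigmoid"` (tanh profile with the same
#'   mid-ventricular gradient).
#' @param peak_contraction_fraction radial shortening fraction at
#'   end-systole, in `[0, 1)`.
#' @param n_frames number of cine frames (frame 1 is end-diastole).
#' @param temporal_resolution frame spacing, ms.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param grid_size image matrix size, pixels.
#' @param k displacement-encoding frequency, cycles/mm. Default 0.06.
#' @param phase_noise_sd additive phase noise SD inside the myocardium,
#'   radians.
#' @param rng_seed optional default seed carried with the config.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(long_axis_length = 88,
                           endo_radius_ed = 20,
                           epi_radius_ed = 30,
                           twist_gradient = 3.4,
                           twist_profile = c("linear", "sigmoid"),
                           peak_contraction_fraction = 0.10,
                           n_frames = 24,
                           temporal_resolution = 34,
                           pixel_spacing = 2.8,
                           grid_size = 48,
                           k = 0.06,
                           phase_noise_sd = 0.1,
                           rng_seed = NULL) {
  twist_profile <- match.arg(twist_profile)
  stopifnot(
    is.numeric(long_axis_length), long_axis_length > 0,
    endo_radius_ed > 0, epi_radius_ed > endo_radius_ed,
    is.finite(twist_gradient),
    peak_contraction_fraction >= 0, peak_contraction_fraction < 1,
    n_frames >= 2, n_frames == round(n_frames),
    temporal_resolution > 0, pixel_spacing > 0,
    grid_size >= 8, k > 0, phase_noise_sd >= 0
  )
  structure(list(
    long_axis_length = long_axis_length,
    endo_radius_ed = endo_radius_ed,
    epi_radius_ed = epi_radius_ed,
    twist_gradient = twist_gradient,
    twist_profile = twist_profile,
    peak_contraction_fraction = peak_contraction_fraction,
    n_frames = as.integer(n_frames),
    temporal_resolution = temporal_resolution,
    pixel_spacing = pixel_spacing,
    grid_size = as.integer(grid_size),
    k = k,
    phase_noise_sd = phase_noise_sd,
    rng_seed = rng_seed
  ), class = "phantom_config")
}

#' Respiratory configuration: end-expiratory offset model and gating windows
#'
#' End-expiratory diaphragm positions vary between breath-holds. They are
#' modeled as draws from a zero-mean truncated normal with SD `end_exp_sd`;
#' the truncation bound is `±end_exp_range`, calibrated so the expected range
#' of 10 draws matches `end_exp_range` (the within-subject range/SD ratio of
#' roughly 3.1 observed in vivo is what an essentially untruncated normal
#' produces for 10 draws). Defaults reproduce the reported intra-subject
#' variability (range 10.2 mm, SD 3.3 mm over 10 breath-holds).
#'
#' @param end_exp_sd SD of end-expiratory positions, mm.
#' @param end_exp_range target expected range of 10 consecutive
#'   end-expiratory positions, mm; also sets the truncation bound.
#' @param navigator_window_halfwidth navigator acceptance half-window, mm.
#' @param wide_window_halfwidth monitoring-only window that never rejects, mm.
#' @param diaphragm_to_heart_coupling fraction of the diaphragm offset
#'   transmitted to the cardiac long-axis position, in `[0, 1]`.
#' @param rng_seed optional default seed.
#' @return an object of class `respiratory_config`.
#' @export
respiratory_config <- function(end_exp_sd = 3.3,
                               end_exp_range = 10.2,
                               navigator_window_halfwidth = 3,
                               wide_window_halfwidth = 50,
                               diaphragm_to_heart_coupling = 1.0,
                               rng_seed = NULL) {
  stopifnot(
    end_exp_sd >= 0, end_exp_range >= 0,
    navigator_window_halfwidth >= 0, wide_window_halfwidth >= 0,
    diaphragm_to_heart_coupling >= 0, diaphragm_to_heart_coupling <= 1
  )
  structure(list(
    end_exp_sd = end_exp_sd,
    end_exp_range = end_exp_range,
    navigator_window_halfwidth = navigator_window_halfwidth,
    wide_window_halfwidth = wide_window_halfwidth,
    diaphragm_to_heart_coupling = diaphragm_to_heart_coupling,
    rng_seed = rng_seed
  ), class = "respiratory_config")
}

#' Plan five equidistant short-axis slices over the long axis
#'
#' Five slice planes are spread evenly over the end-systolic endocardial
#' long-axis length; the 2nd and 4th are the basal and apical imaging
#' locations, so the nominal basal-apical distance is half the long-axis
#' length. The longitudinal coordinate increases base to apex.
#'
#' @param cfg a [phantom_config()].
#' @return an `acquisition_plan` with fields `slice_positions` (mm),
#'   `basal_index`, `apical_index`, `d_nominal` (mm).
#' @export
plan_slices <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  pos <- seq(0, cfg$long_axis_length, length.out = 5)
  structure(list(
    slice_positions = pos,
    basal_index = 2L,
    apical_index = 4L,
    d_nominal = pos[4L] - pos[2L]
  ), class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat("Slice plan:", paste(format(x$slice_positions), collapse = ", "), "mm\n")
  cat(sprintf("basal = slice %d (%.1f mm), apical = slice %d (%.1f mm), d = %.1f mm\n",
              x$basal_index, x$slice_positions[x$basal_index],
              x$apical_index, x$slice_positions[x$apical_index], x$d_nominal))
  invisible(x)
}

#' Sample end-expiratory breath-hold positions
#'
#' Draws the mode diaphragm position of `n` consecutive breath-holds from the
#' truncated-normal end-expiratory model (see [respiratory_config()]).
#'
#' @param resp a [respiratory_config()].
#' @param n number of breath-holds (>= 1).
#' @param seed optional integer seed (falls back to `resp$rng_seed`).
#' @return a data.frame of class `breathhold_records` with columns
#'   `mode_position` (mm), `accepted`, `window_center`, `window_halfwidth`.
#' @export
sample_breathhold_positions <- function(resp, n, seed = NULL) {
  stopifnot(inherits(resp, "respiratory_config"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  seed <- seed %||% resp$rng_seed
  pos <- with_seed(seed,
    rtruncnorm(n, 0, resp$end_exp_sd, -resp$end_exp_range, resp$end_exp_range))
  structure(data.frame(
    mode_position = pos,
    accepted = TRUE,
    window_center = 0,
    window_halfwidth = Inf
  ), class = c("breathhold_records", "data.frame"))
}

#' Subject-specific minimum, middle and maximum end-expiratory positions
#'
#' The middle position is the recorded position closest to the median of all
#' recorded positions; ties are broken toward the smaller value.
#'
#' @param records a `breathhold_records` data.frame or a numeric vector of
#'   mode positions (>= 3 values).
#' @return named numeric vector `c(min=, mid=, max=)` in mm.
#' @export
select_min_mid_max <- function(records) {
  pos <- if (is.data.frame(records)) records$mode_position else as.numeric(records)
  if (length(pos) < 3) stop("need at least 3 breath-hold records")
  med <- stats::median(pos)
  dev <- abs(pos - med)
  cand <- pos[dev == min(dev)]
  c(min = min(pos), mid = min(cand), max = max(pos))
}

# Cardiac cycle shape: 0 at end-diastole (frame index 0), rising as a
# quarter-sine to exactly 1 at end-systole (~40% of the cycle, snapped to a
# frame so peak values are sampled), then a cosine relaxation toward 0.
cycle_shape <- function(cfg) {
  nf <- cfg$n_frames
  f <- seq_len(nf) - 1
  fes <- max(1, round(0.4 * (nf - 1)))
  s <- ifelse(f <= fes,
              sin(pi / 2 * f / fes),
              cos(pi / 2 * (f - fes) / (nf - 1 - fes)))
  s
}

# End-systolic rotation angle (deg) at longitudinal position z (mm).
# Reference z is mid-ventricle so the base rotates clockwise (negative) and
# the apex counter-clockwise (positive), viewed foot-to-head.
twist_angle_es <- function(cfg, z) {
  zref <- cfg$long_axis_length / 2
  switch(cfg$twist_profile,
    linear = cfg$twist_gradient * (z - zref) / 10,
    sigmoid = {
      w <- cfg$long_axis_length / 4
      cfg$twist_gradient * (w / 10) * tanh((z - zref) / w)
    }
  )
}

# Pixel-center coordinate grid (mm, origin at image center; x rightward,
# y downward) and the end-diastolic annular myocardial mask.
phantom_grid <- function(cfg) {
  g <- cfg$grid_size
  coord <- (seq_len(g) - 1 - (g - 1) / 2) * cfg$pixel_spacing
  x <- matrix(coord, g, g, byrow = TRUE)   # column index -> x
  y <- matrix(coord, g, g)                 # row index -> y
  r <- sqrt(x^2 + y^2)
  mask <- r >= cfg$endo_radius_ed & r <= cfg$epi_radius_ed
  list(x = x, y = y, r = r, mask = mask)
}

#' True displacement field of a slice at one cine frame
#'
#' Material points of the end-diastolic annulus are rotated about the slice
#' centroid by the twist angle at longitudinal position `z` and contracted
#' radially, both scaled by the cycle shape (0 at end-diastole, 1 at
#' end-systole).
#'
#' @param cfg a [phantom_config()].
#' @param z longitudinal position, mm, in `[0, long_axis_length]`.
#' @param frame cine frame, 1-based (frame 1 = end-diastole).
#' @return list with `ux`, `uy` (mm displacement matrices), `mask`, and the
#'   applied rotation `theta_deg`.
#' @export
generate_displacement_field <- function(cfg, z, frame) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (z < 0 || z > cfg$long_axis_length)
    stop("longitudinal position z outside the ventricle")
  if (frame < 1 || frame > cfg$n_frames) stop("frame out of range")
  s <- cycle_shape(cfg)[frame]
  theta <- twist_angle_es(cfg, z) * s * pi / 180
  rho <- 1 - cfg$peak_contraction_fraction * s
  gr <- phantom_grid(cfg)
  ct <- cos(theta); st <- sin(theta)
  xn <- rho * (ct * gr$x - st * gr$y)
  yn <- rho * (st * gr$x + ct * gr$y)
  list(ux = xn - gr$x, uy = yn - gr$y, mask = gr$mask,
       theta_deg = theta * 180 / pi)
}

#' Encode a displacement field into wrapped phase images
#'
#' Phase is `2*pi*k*u` plus i.i.d. Gaussian noise inside the mask, wrapped to
#' `[-pi, pi)`; pixels outside the mask are zero.
#'
#' @param ux,uy displacement components, mm.
#' @param mask logical myocardial mask.
#' @param k displacement-encoding frequency, cycles/mm.
#' @param noise_sd phase noise SD, radians.
#' @param seed optional seed.
#' @return list `phase_x`, `phase_y` of wrapped phase matrices.
#' @export
encode_phase <- function(ux, uy, mask, k, noise_sd = 0, seed = NULL) {
  stopifnot(k > 0, noise_sd >= 0)
  with_seed(seed, {
    px <- 2 * pi * k * ux
    py <- 2 * pi * k * uy
    if (noise_sd > 0) {
      px[mask] <- px[mask] + stats::rnorm(sum(mask), 0, noise_sd)
      py[mask] <- py[mask] + stats::rnorm(sum(mask), 0, noise_sd)
    }
    px <- wrap_to_pi(px); py <- wrap_to_pi(py)
    px[!mask] <- 0; py[!mask] <- 0
    list(phase_x = px, phase_y = py)
  })
}

# One gated/breath-hold draw of the diaphragm offset: the end-expiratory
# distribution restricted to the navigator acceptance window. halfwidth 0
# pins the offset at the window center.
draw_offset_in_window <- function(resp, center, halfwidth) {
  if (halfwidth == 0) return(center)
  lo <- max(center - halfwidth, -resp$end_exp_range)
  hi <- min(center + halfwidth, resp$end_exp_range)
  if (lo > hi) { lo <- center - halfwidth; hi <- center + halfwidth }
  rtruncnorm(1, 0, resp$end_exp_sd, lo, hi)
}

# Simulate one slice acquisition: a full cine stack at effective longitudinal
# position planned + coupling * dz. The recorded plane_position stays at the
# planned value -- header metadata cannot see the breath-hold offset; that is
# the confound under study.
simulate_slice_acquisition <- function(cfg, resp, z_planned, dz, slice_label,
                                       acq_index, subject_id = "S1",
                                       seed = NULL) {
  z_eff <- z_planned + resp$diaphragm_to_heart_coupling * dz
  z_eff <- min(max(z_eff, 0), cfg$long_axis_length)
  g <- cfg$grid_size; nf <- cfg$n_frames
  gr <- phantom_grid(cfg)
  phase_x <- array(0, c(g, g, nf))
  phase_y <- array(0, c(g, g, nf))
  magnitude <- array(0, c(g, g, nf))
  # unimodal magnitude so the automatic unwrap seed (max magnitude) is unique
  mag2d <- ifelse(gr$mask, 2 - gr$r / cfg$epi_radius_ed, 0.05) +
    1e-6 * gr$x + 2e-7 * gr$y
  with_seed(seed, for (f in seq_len(nf)) {
    fld <- generate_displacement_field(cfg, z_eff, f)
    ph <- encode_phase(fld$ux, fld$uy, gr$mask, cfg$k, cfg$phase_noise_sd)
    phase_x[, , f] <- ph$phase_x
    phase_y[, , f] <- ph$phase_y
    magnitude[, , f] <- mag2d
  })
  structure(list(
    magnitude = magnitude,
    phase_x = phase_x,
    phase_y = phase_y,
    myocardial_mask = gr$mask,
    plane_position = z_planned,
    true_diaphragm_offset = dz,
    slice_label = slice_label,
    acquisition_index = as.integer(acq_index),
    subject_id = subject_id,
    pixel_spacing = cfg$pixel_spacing,
    k = cfg$k,
    frame_times = (seq_len(nf) - 1) * cfg$temporal_resolution
  ), class = "slice_acquisition")
}

#' @export
print.slice_acquisition <- function(x, ...) {
  cat(sprintf("<slice_acquisition> %s #%d subject %s: %dx%d x %d frames, plane %.1f mm (true offset %+.2f mm)\n",
              x$slice_label, x$acquisition_index, x$subject_id,
              dim(x$magnitude)[1], dim(x$magnitude)[2], dim(x$magnitude)[3],
              x$plane_position, x$true_diaphragm_offset))
  invisible(x)
}

#' Simulate the enforced-variability protocol (experiment 1)
#'
#' Ten scout breath-holds establish the subject's minimum, middle and maximum
#' end-expiratory positions. Basal and apical slices are then acquired with
#' the navigator window centered at each of the three positions, and the
#' middle-window pair is acquired twice (8 acquisitions in all). Each
#' acquisition's diaphragm offset is drawn independently within its window;
#' the two middle repeats therefore differ only by within-window variation.
#'
#' @param cfg a [phantom_config()].
#' @param resp a [respiratory_config()].
#' @param plan an [plan_slices()] result (defaults to `plan_slices(cfg)`).
#' @param subject_id subject label.
#' @param seed integer seed.
#' @return a `dense_session` list: `acquisitions` (8 [slice_acquisition]s,
#'   windows min/mid/max/mid_repeat x basal/apical), `scout_positions` (the
#'   10 observable scout breath-hold positions), and a `truth` record (all
#'   sampled offsets and configs, for oracle tests only -- the analysis path
#'   must not read it).
#' @export
simulate_experiment1 <- function(cfg, resp, plan = plan_slices(cfg),
                                 subject_id = "S1", seed = NULL) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(resp, "respiratory_config"))
  seed <- seed %||% cfg$rng_seed %||% 1L
  scout <- sample_breathhold_positions(resp, 10, seed = derive_seed(seed, "scout"))
  mmm <- select_min_mid_max(scout)
  windows <- c(min = unname(mmm["min"]), mid = unname(mmm["mid"]),
               max = unname(mmm["max"]), mid_repeat = unname(mmm["mid"]))
  z_b <- plan$slice_positions[plan$basal_index]
  z_a <- plan$slice_positions[plan$apical_index]
  hw <- resp$navigator_window_halfwidth
  acqs <- list()
  truth_dz <- data.frame(window = character(0), slice = character(0), dz = numeric(0))
  idx <- 0L
  for (w in names(windows)) {
    for (sl in c("basal", "apical")) {
      idx <- idx + 1L
      dz <- with_seed(derive_seed(seed, "exp1", w, sl),
                      draw_offset_in_window(resp, windows[[w]], hw))
      acq <- simulate_slice_acquisition(
        cfg, resp, if (sl == "basal") z_b else z_a, dz, sl, idx, subject_id,
        seed = derive_seed(seed, "noise1", w, sl))
      acq$window <- w
      acqs[[paste(w, sl, sep = ".")]] <- acq
      truth_dz <- rbind(truth_dz, data.frame(window = w, slice = sl, dz = dz))
    }
  }
  structure(list(
    experiment = 1L,
    subject_id = subject_id,
    acquisitions = acqs,
    scout_positions = scout$mode_position,
    plan = plan,
    truth = list(cfg = cfg, resp = resp, windows = windows, offsets = truth_dz,
                 seed = seed)
  ), class = "dense_session")
}

#' Simulate the natural-variability protocol (experiment 2)
#'
#' `n_pairs` basal and apical slices are acquired with two protocols:
#' consecutive breath-holds (navigator enabled with a wide monitoring window
#' that never rejects, so offsets follow the free end-expiratory
#' distribution) and consecutive navigator-gated acquisitions with a single
#' acceptance window centered at 0. Acquisitions alternate basal, apical,
#' basal, apical in temporal order.
#'
#' @param cfg,resp,plan,subject_id,seed as in [simulate_experiment1()].
#' @param n_pairs number of basal/apical pairs per protocol (>= 2).
#' @return a `dense_session` with `protocols$breath_hold` and
#'   `protocols$navigator` (each `2 * n_pairs` acquisitions in temporal
#'   order), per-protocol `navigator_log` of measured diaphragm positions
#'   (observable), and a `truth` record.
#' @export
simulate_experiment2 <- function(cfg, resp, plan = plan_slices(cfg),
                                 n_pairs = 10, subject_id = "S1", seed = NULL) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(resp, "respiratory_config"))
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  seed <- seed %||% cfg$rng_seed %||% 1L
  z_b <- plan$slice_positions[plan$basal_index]
  z_a <- plan$slice_positions[plan$apical_index]
  make_protocol <- function(name, halfwidth) {
    acqs <- vector("list", 2L * n_pairs)
    log <- numeric(2L * n_pairs)
    for (i in seq_len(2L * n_pairs)) {
      sl <- if (i %% 2L == 1L) "basal" else "apical"
      dz <- with_seed(derive_seed(seed, "exp2", name, i),
                      draw_offset_in_window(resp, 0, halfwidth))
      acq <- simulate_slice_acquisition(
        cfg, resp, if (sl == "basal") z_b else z_a, dz, sl, i, subject_id,
        seed = derive_seed(seed, "noise2", name, i))
      acq$protocol <- name
      acqs[[i]] <- acq
      log[i] <- dz  # the navigator measures the diaphragm even when not gating
    }
    list(acquisitions = acqs, navigator_log = log)
  }
  bh <- make_protocol("breath_hold", resp$wide_window_halfwidth)
  nav <- make_protocol("navigator", resp$navigator_window_halfwidth)
  structure(list(
    experiment = 2L,
    subject_id = subject_id,
    n_pairs = as.integer(n_pairs),
    protocols = list(breath_hold = bh$acquisitions, navigator = nav$acquisitions),
    navigator_log = list(breath_hold = bh$navigator_log, navigator = nav$navigator_log),
    plan = plan,
    truth = list(cfg = cfg, resp = resp, seed = seed,
                 offsets = list(breath_hold = bh$navigator_log,
                                navigator = nav$navigator_log))
  ), class = "dense_session")
}

#' Closed-form peak torsion for a basal/apical offset pair
#'
#' With the linear twist profile and no noise, the measured peak torsion of a
#' basal slice acquired at diaphragm offset `dz_basal` and an apical slice at
#' `dz_apical` is `twist_gradient * (1 + coupling * (dz_apical - dz_basal) /
#' d_nominal)`: the metadata distance `d_nominal` does not see the offsets,
#' while the sampled twist difference does. Used as the independent oracle
#' for the full simulate/reconstruct/quantify chain.
#'
#' @param cfg a [phantom_config()] (linear profile).
#' @param dz_basal,dz_apical diaphragm offsets, mm.
#' @param d_nominal planned basal-apical distance, mm.
#' @param coupling diaphragm-to-heart coupling fraction.
#' @return peak torsion, deg/cm.
#' @export
torsion_oracle <- function(cfg, dz_basal, dz_apical, d_nominal, coupling = 1) {
  stopifnot(cfg$twist_profile == "linear")
  cfg$twist_gradient * (1 + coupling * (dz_apical - dz_basal) / d_nominal)
}
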