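test_that("config validation rejects impossible geometry and kinematics", {
  expect_error(phantom_config(endo_radius_ed = 30, epi_radius_ed = 20))
  expect_error(phantom_config(peak_contraction_fraction = 1))
  expect_error(phantom_config(n_frames = 1))
  expect_error(phantom_config(k = 0))
  expect_error(respiratory_config(navigator_window_halfwidth = -1))
  expect_error(respiratory_config(diaphragm_to_heart_coupling = 1.5))
})

test_that("slice planning spans the end-systolic long axis equidistantly", {
  plan <- plan_slices(phantom_config(long_axis_length = 88))
  expect_equal(plan$slice_positions, c(0, 22, 44, 66, 88))
  expect_equal(plan$d_nominal, 44)
  expect_identical(plan$basal_index, 2L)
  expect_identical(plan$apical_index, 4L)
  # d is always half the planned span
  for (L in c(70, 81.3, 102)) {
    p <- plan_slices(phantom_config(long_axis_length = L))
    expect_equal(diff(p$slice_positions), rep(L / 4, 4))
    expect_equal(p$d_nominal, (p$slice_positions[5] - p$slice_positions[1]) / 2)
  }
})

test_that("breath-hold positions: degenerate, deterministic, bounded", {
  resp0 <- respiratory_config(end_exp_sd = 0)
  expect_equal(sample_breathhold_positions(resp0, 5, seed = 1)$mode_position,
               rep(0, 5))
  resp <- default_resp()
  a <- sample_breathhold_positions(resp, 10, seed = 42)
  b <- sample_breathhold_positions(resp, 10, seed = 42)
  expect_identical(a, b)
  expect_true(all(abs(a$mode_position) <= resp$end_exp_range))
  expect_true(all(a$accepted))
  expect_error(sample_breathhold_positions(resp, 0))
})

test_that("expected 10-breath-hold range matches the configured range", {
  # Monte-Carlo oracle: mean sample range over many seeded subjects should
  # calibrate to end_exp_range (10.2 mm) within 20%.
  resp <- default_resp()
  rg <- vapply(1:400, function(s)
    diff(range(sample_breathhold_positions(resp, 10, seed = s)$mode_position)),
    numeric(1))
  expect_lt(abs(mean(rg) - resp$end_exp_range) / resp$end_exp_range, 0.2)
})

test_that("min/mid/max selection follows the closest-to-median tie rule", {
  expect_equal(select_min_mid_max(c(-5, 0, 5)), c(min = -5, mid = 0, max = 5))
  expect_equal(select_min_mid_max(c(1, 1, 1, 1)), c(min = 1, mid = 1, max = 1))
  # median 0.5; 0 and 1 tie at distance 0.5 -> smaller wins
  expect_equal(select_min_mid_max(c(-6, -2, 0, 1, 3, 8)),
               c(min = -6, mid = 0, max = 8))
  expect_error(select_min_mid_max(c(1, 2)))
})

test_that("displacement field: reference frame, closed-form twist, isometry", {
  cfg <- small_cfg()
  f0 <- generate_displacement_field(cfg, 22, 1)
  expect_true(all(f0$ux == 0) && all(f0$uy == 0))
  # linear profile: ES twist difference between planes is exact
  plan <- plan_slices(cfg)
  es <- which.max(lvtorsion:::cycle_shape(cfg))
  fb <- generate_displacement_field(cfg, plan$slice_positions[2], es)
  fa <- generate_displacement_field(cfg, plan$slice_positions[4], es)
  expect_equal(fa$theta_deg - fb$theta_deg,
               cfg$twist_gradient * plan$d_nominal / 10)
  # pure rotation preserves radii
  cfg_rot <- small_cfg(peak_contraction_fraction = 0)
  fr <- generate_displacement_field(cfg_rot, 66, es)
  gr <- lvtorsion:::phantom_grid(cfg_rot)
  r0 <- gr$r[gr$mask]
  r1 <- sqrt((gr$x + fr$ux)[gr$mask]^2 + (gr$y + fr$uy)[gr$mask]^2)
  expect_equal(r1, r0, tolerance = 1e-12)
  expect_error(generate_displacement_field(cfg, -1, 2))
  expect_error(generate_displacement_field(cfg, cfg$long_axis_length + 1, 2))
})

test_that("phase encoding wraps to [-pi, pi) with the half-open boundary", {
  cfg <- small_cfg()
  gr <- lvtorsion:::phantom_grid(cfg)
  z <- matrix(0, cfg$grid_size, cfg$grid_size)
  ph <- encode_phase(z, z, gr$mask, cfg$k)
  expect_true(all(ph$phase_x == 0) && all(ph$phase_y == 0))
  # u = 10 mm at k = 0.06: 2*pi*0.6 wraps past one full cycle
  u10 <- matrix(10, cfg$grid_size, cfg$grid_size)
  ph10 <- encode_phase(u10, z, gr$mask, 0.06)
  expect_equal(ph10$phase_x[gr$mask][1], -2.513274, tolerance = 1e-6)
  # u = 1/(2k): exactly at the wrap boundary -> maps to -pi
  ub <- matrix(1 / (2 * 0.06), cfg$grid_size, cfg$grid_size)
  phb <- encode_phase(ub, z, gr$mask, 0.06)
  expect_equal(phb$phase_x[gr$mask][1], -pi)
  # noisy phases stay in range
  phn <- encode_phase(u10, u10, gr$mask, 0.06, noise_sd = 2, seed = 1)
  expect_true(all(phn$phase_x >= -pi & phn$phase_x < pi))
  expect_true(all(phn$phase_y >= -pi & phn$phase_y < pi))
})

test_that("experiment 1 sessions have the published structure", {
  cfg <- small_cfg(noise = 0.05)
  resp <- default_resp()
  ses <- simulate_experiment1(cfg, resp, subject_id = "S1", seed = 11)
  expect_s3_class(ses, "dense_session")
  expect_length(ses$acquisitions, 8)
  labs <- vapply(ses$acquisitions, function(a) a$slice_label, character(1))
  expect_equal(sum(labs == "basal"), 4)
  expect_equal(sum(labs == "apical"), 4)
  # metadata never reflects the diaphragm offset
  plan <- plan_slices(cfg)
  for (a in ses$acquisitions) {
    expect_true(a$plane_position %in%
                  plan$slice_positions[c(plan$basal_index, plan$apical_index)])
    expect_true(all(a$phase_x >= -pi & a$phase_x < pi))
  }
  # mid-window acquisitions sit within +/-3 mm of the mid position
  off <- ses$truth$offsets
  mid <- ses$truth$windows[["mid"]]
  expect_true(all(abs(off$dz[off$window %in% c("mid", "mid_repeat")] - mid) <=
                    resp$navigator_window_halfwidth))
  # determinism: bit-identical containers under a fixed seed
  ses2 <- simulate_experiment1(cfg, resp, subject_id = "S1", seed = 11)
  expect_identical(ses, ses2)
})

test_that("experiment 1 with a zero-width window pins the mid repeats", {
  cfg <- small_cfg(noise = 0)
  resp <- respiratory_config(navigator_window_halfwidth = 0)
  ses <- simulate_experiment1(cfg, resp, seed = 3)
  off <- ses$truth$offsets
  mids <- off[off$window %in% c("mid", "mid_repeat"), ]
  expect_equal(unique(mids$dz), ses$truth$windows[["mid"]])
  q <- quantify_experiment1(ses)
  expect_equal(q$ref_pair[1], q$ref_pair[2], tolerance = 1e-10)
})

test_that("experiment 2 sessions have the published structure", {
  cfg <- small_cfg(noise = 0.05)
  resp <- default_resp()
  ses <- simulate_experiment2(cfg, resp, n_pairs = 10, seed = 5)
  expect_length(ses$protocols$breath_hold, 20)
  expect_length(ses$protocols$navigator, 20)
  for (proto in names(ses$protocols)) {
    labs <- vapply(ses$protocols[[proto]], function(a) a$slice_label, character(1))
    expect_equal(labs, rep(c("basal", "apical"), 10))
    idx <- vapply(ses$protocols[[proto]], function(a) a$acquisition_index, integer(1))
    expect_equal(idx, 1:20)
  }
  expect_true(all(abs(ses$navigator_log$navigator) <=
                    resp$navigator_window_halfwidth))
  # zero-width navigator window: all gated offsets equal
  ses0 <- simulate_experiment2(cfg, respiratory_config(navigator_window_halfwidth = 0),
                               n_pairs = 2, seed = 5)
  expect_equal(unique(ses0$navigator_log$navigator), 0)
  expect_error(simulate_experiment2(cfg, resp, n_pairs = 1))
})

test_that("breath-hold offsets reproduce the end-expiratory SD", {
  # Monte-Carlo oracle over seeds: free (wide-window) offsets should have
  # the configured SD up to mild truncation shrinkage.
  resp <- default_resp()
  dz <- unlist(lapply(1:40, function(s) {
    cfg <- small_cfg()
    ses <- simulate_experiment2(cfg, resp, n_pairs = 5, seed = s)
    ses$navigator_log$breath_hold
  }))
  expect_lt(abs(sd(dz) - resp$end_exp_sd) / resp$end_exp_sd, 0.1)
})

test_that("masks agree across encoding directions and phases stay wrapped", {
  cfg <- small_cfg(noise = 0.3)
  resp <- default_resp()
  acq <- sim_slice(cfg, resp, 22, 2.5)
  expect_true(all(acq$phase_x >= -pi & acq$phase_x < pi))
  expect_true(all(acq$phase_y >= -pi & acq$phase_y < pi))
  # the same myocardial mask applies to both directions by construction
  expect_identical(dim(acq$phase_x), dim(acq$phase_y))
  expect_equal(acq$phase_x[, , 1][!acq$myocardial_mask],
               acq$phase_y[, , 1][!acq$myocardial_mask])
})
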