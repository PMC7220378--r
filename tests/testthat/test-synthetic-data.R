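test_that("speed trace follows the motorized protocol kinematics", {
  tr <- gen_speed_trace(protocol_params())
  at <- function(t) which(abs(tr$time_s - t) < 1e-9)

  # linear ramp: 1.5 s at 10/3 cm/s^2 -> 5 cm/s
  expect_equal(tr$speed_cmps[at(8.5)], 5.0)
  # plateau held at 10 cm/s until 23 s
  expect_equal(tr$speed_cmps[at(15)], 10)
  expect_equal(tr$speed_cmps[at(22.9)], 10)
  # zero outside the motorized segment
  expect_true(all(tr$speed_cmps[tr$time_s < 7] == 0))
  expect_true(all(tr$speed_cmps[tr$time_s >= 26] == 0))

  # total motorized distance: 15 (ramp) + 130 (plateau) + 15 (ramp) = 160 cm
  expect_equal(max(tr$position_cm), 160)
  expect_equal(tr$position_cm[nrow(tr)], 160)

  # speed continuous to within one frame step of acceleration
  expect_lte(max(abs(diff(tr$speed_cmps))), 10 / 3 / 30 + 1e-12)

  # position is the running integral of speed (closed form vs trapezoid)
  trap <- cumsum((tr$speed_cmps + c(0, head(tr$speed_cmps, -1))) / 2) / 30
  expect_equal(tr$position_cm, trap, tolerance = 1e-3)
})

test_that("inconsistent protocol times are rejected", {
  expect_error(protocol_params(t_accel_start = 5), "inconsistent")
  expect_error(protocol_params(v_max = 100), "ramp")
})

test_that("locomotion block generator is reproducible and honest about its design", {
  p <- loco_gen_params(n_rois = 6, seed = 42)
  g1 <- gen_locomotion_block(p)
  g2 <- gen_locomotion_block(p)
  expect_identical(g1, g2)
  g3 <- gen_locomotion_block(loco_gen_params(n_rois = 6, seed = 43))
  expect_false(identical(g1$truth$b, g3$truth$b))

  # no drug effect, no decay -> designed pre and post values equal per ROI
  p0 <- loco_gen_params(n_rois = 5, effect_slope = 0, effect_noise_sd = 0,
                        decay_B = 0, seed = 1)
  g0 <- gen_locomotion_block(p0)
  expect_equal(g0$truth$L[, 1], g0$truth$L[, ncol(g0$truth$L)])
})

test_that("with zero jitter the window percentile equals the designed value exactly", {
  p <- loco_gen_params(n_rois = 4, jitter_sd = 0, seed = 9)
  g <- gen_locomotion_block(p)
  dffm <- normalize_to_rest(g$block, select_least_active(g$block))
  L <- sapply(seq_along(dffm$dff), function(j)
    sapply(1:4, function(i)
      locomotion_fluorescence(dffm$dff[[j]][i, ], frame_rate = 30)))
  expect_equal(L, g$truth$L, tolerance = 1e-12)
})

test_that("planted baselines and changes match the analytic population correlation", {
  # rho = slope*sigma_b / sqrt(slope^2 sigma_b^2 + sigma_eps^2)
  slope <- -0.65; sb <- 0.6; se <- 0.597
  rho <- slope * sb / sqrt(slope^2 * sb^2 + se^2)
  rs <- sapply(1:5, function(s) {
    g <- gen_locomotion_block(loco_gen_params(n_rois = 2000, jitter_sd = 0,
                                              seed = s))
    cor(g$truth$b, g$truth$d)
  })
  expect_equal(mean(rs), rho, tolerance = 0.02)
})

test_that("ROI scenes carry exactly computable overlap ground truth", {
  # unperturbed: every pair overlaps fully after undoing the shift
  s0 <- gen_roi_scene(6, shift_px = c(3L, 2L), perturb_px = 0L, seed = 2)
  expect_true(all(s0$truth$ratio == 1))
  # 10x10 squares offset by 5 px share a 5x10 strip: 50 / 150
  s1 <- gen_roi_scene(4, roi_px = c(10L, 10L), shift_px = c(0L, 0L),
                      perturb_px = 5L, seed = 3)
  expect_equal(s1$truth$ratio, rep(50 / 150, 4))
  # 0.333 >= 0.3 (inclusive rule), so all pairs should match
  expect_true(all(s1$truth$should_match))
  expect_true(all(s1$truth$ratio >= 0.3))
  expect_error(gen_roi_scene(500, field_px = c(64L, 64L)), "field")
})

test_that("stimulation datasets have the designed drug/control ratio", {
  g0 <- gen_stim_dataset(stim_gen_params(n_cells = 8, m = 0, seed = 1))
  ctrl <- g0$table$peak_dff[g0$table$condition == "control"]
  drug <- g0$table$peak_dff[g0$table$condition == "drug"]
  expect_equal(drug / ctrl, rep(1, 8))

  g1 <- gen_stim_dataset(stim_gen_params(n_cells = 10, m = 1.1277,
                                         peak_noise_sd = 0, seed = 2))
  ctrl <- g1$table$peak_dff[g1$table$condition == "control"]
  drug <- g1$table$peak_dff[g1$table$condition == "drug"]
  expect_equal(drug / ctrl, rep(1 / 2.1277, 10))
  expect_equal(g1$truth$true_ratio, 0.470, tolerance = 1e-3)

  g2 <- gen_stim_dataset(stim_gen_params(n_cells = 5, m = 1e6, seed = 3))
  expect_lt(g2$truth$true_ratio, 1e-5)
})

test_that("EM generator respects its radial design", {
  # all mass in the first band -> nothing beyond 50 nm
  g1 <- gen_em_sample(em_gen_params(particle_count = 200,
                                    radial_profile = c(1, 0, 0, 0, 0),
                                    seed = 4))
  d <- edge_distance(g1$sample$particles, g1$sample$psd_polygon)
  expect_true(all(d$distance_nm < 50))
  expect_true(all(!d$inside))

  # empty sample
  g0 <- gen_em_sample(em_gen_params(particle_count = 0, seed = 5))
  expect_equal(nrow(g0$sample$particles), 0)
  prof <- annulus_density_profile(g0$sample)
  expect_true(all(prof$bands$count == 0))

  # determinism
  gp <- em_gen_params(particle_count = 50, seed = 6)
  expect_identical(gen_em_sample(gp), gen_em_sample(gp))
})

test_that("uniform EM fields give flat annulus densities (Poisson null)", {
  g <- gen_em_sample(em_gen_params(particle_count = 40000,
                                   radial_profile = "uniform",
                                   field_extent = 600, seed = 7))
  prof <- annulus_density_profile(g$sample)
  dens <- prof$bands$density_per_um2
  # all five band densities within Monte-Carlo error of the field intensity
  lambda <- g$truth$intensity_per_um2
  for (b in seq_along(dens)) {
    se <- 1e6 * sqrt(prof$bands$count[b]) / prof$bands$area_nm2[b]
    expect_lt(abs(dens[b] - lambda), 4 * se + 1e-9)
  }
})
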