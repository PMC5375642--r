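test_that("crossmodal rule: linearity at g = 0, bonus gating, monotonicity", {
  expect_equal(crossmodal_rule(2, 3, 0, 10), 5)
  expect_equal(crossmodal_rule(2, 3, 1, 10), 7)
  expect_equal(crossmodal_rule(12, 3, 1, 10), 15)
  expect_error(crossmodal_rule(-1, 3, 1, 10), ">= 0")
  # monotone non-decreasing in v and h within each gate regime (the hard
  # threshold itself introduces a downward jump by construction)
  set.seed(1)
  for (i in 1:100) {
    v <- runif(1, 0, 2); h <- runif(1, 0, 2); g <- runif(1, 0, 3)
    th <- runif(1, 0, 2); dv <- runif(1, 0, 0.5)
    same_gate_v <- (v < th) == (v + dv < th)
    same_gate_h <- (h < th) == (h + dv < th)
    if (same_gate_v)
      expect_gte(crossmodal_rule(v + dv, h, g, th),
                 crossmodal_rule(v, h, g, th))
    if (same_gate_h)
      expect_gte(crossmodal_rule(v, h + dv, g, th),
                 crossmodal_rule(v, h, g, th))
  }
})

test_that("generators are deterministic given seed and config", {
  cfg <- sim_config(seed = 3, width = 48, height = 48, n_blocks = 1)
  cells <- sim_cell_population(3, cfg)
  m1 <- simulate_movie(cfg, cells)
  m2 <- simulate_movie(cfg, cells)
  expect_identical(m1$movie$frames, m2$movie$frames)
  expect_identical(m1$truth$shifts, m2$truth$shifts)

  bcfg <- sim_behavior_config(seed = 5, n_tadpoles = 3)
  expect_identical(simulate_swim_trials(bcfg)$trials,
                   simulate_swim_trials(bcfg)$trials)

  scfg <- sim_startle_config(seed = 5, n_control_low = 4, n_control_high = 4,
                             n_mk801_low = 4)
  expect_identical(simulate_startle_sessions(scfg)$sessions,
                   simulate_startle_sessions(scfg)$sessions)

  ecfg <- sim_ephys_config(seed = 5)
  e1 <- simulate_ephys(ecfg, 3); e2 <- simulate_ephys(ecfg, 3)
  expect_identical(e1$traces[[1]]$samples, e2$traces[[1]]$samples)
})

test_that("an empty cell list yields a pure-background movie", {
  cfg <- sim_config(seed = 2, width = 32, height = 32, n_blocks = 1,
                    noise_sd = 0, neuropil_response = 0, bleach_tau = 1e9)
  sim <- simulate_movie(cfg, data.frame())
  # without cells, responses, noise or bleach every frame is the static scene
  expect_equal(sim$movie$frames[1, , ], sim$movie$frames[100, , ])
  expect_equal(nrow(sim$truth$cells), 0)
})

test_that("g = 0 construction sums linearly through the imaging pipeline", {
  cfg <- sim_config(seed = 4, width = 64, height = 64, n_blocks = 1,
                    noise_sd = 0, gain = 0)
  cells <- sim_cell_population(5, cfg)
  sim <- simulate_movie(cfg, cells)
  res <- analyze_movie(sim$movie, sim$rois, r = cfg$neuropil_mix)
  expect_equal(res$cells$multisensory,
               res$cells$visual + res$cells$mechanosensory,
               tolerance = 0.02)
})

test_that("overlapping cells are flagged in the truth record", {
  cfg <- sim_config(seed = 1, width = 40, height = 40, n_blocks = 1)
  cells <- data.frame(x = c(15, 17, 30), y = c(15, 15, 30), radius = 3,
                      visual_amp = 0.5, mech_amp = 0.3, gain = 0)
  sim <- simulate_movie(cfg, cells)
  expect_equal(sim$truth$cells$overlap, c(TRUE, TRUE, FALSE))
})

test_that("swim generator: null enhancement gives MSIn near zero, enhanced contrast dominates", {
  null_cfg <- sim_behavior_config(seed = 12, n_tadpoles = 12,
                                  enhancement = c(0, 0, 0, 0))
  tr <- score_trials(simulate_swim_trials(null_cfg)$trials, "speed")
  ms <- aggregate_msin(session_msin(tr))
  expect_true(all(abs(ms$mean) <= 3 * ms$sem))

  enh_cfg <- sim_behavior_config(seed = 12, n_tadpoles = 12,
                                 enhancement = c(0, 2, 0, 0))
  tre <- score_trials(simulate_swim_trials(enh_cfg)$trials, "speed")
  mse <- aggregate_msin(session_msin(tre))
  expect_equal(mse$contrast[which.max(mse$mean)], 25)
})

test_that("an all-inactive tadpole is generated and excluded", {
  cfg <- sim_behavior_config(seed = 13, n_tadpoles = 6, inactive_fraction = 0.4)
  sim <- simulate_swim_trials(cfg)
  expect_true(any(sim$truth$inactive))
  tr <- score_trials(sim$trials, "speed")
  exc <- exclude_inactive(tr)
  expect_setequal(exc$excluded$tadpole, which(sim$truth$inactive))
})

test_that("ephys generator obeys the linearity contracts", {
  # blocked: VH area = V + H within numerical tolerance
  cfgb <- sim_ephys_config(seed = 6, blocked = TRUE, noise_sd = 0)
  rb <- analyze_ephys_trials(simulate_ephys(cfgb, 4)$traces,
                             simulate_ephys(cfgb, 4)$meta)
  expect_equal(rb$linearity$ratio, 1, tolerance = 0.02)

  # g > 0 at small amplitudes: supralinear
  cfgs <- sim_ephys_config(seed = 6, g_nmda = 1, noise_sd = 0)
  rs <- analyze_ephys_trials(simulate_ephys(cfgs, 4)$traces,
                             simulate_ephys(cfgs, 4)$meta)
  expect_gt(rs$linearity$ratio, 1.1)
  expect_equal(rs$threshold_class, "subthreshold")

  # amplitudes above the bound: bonus disabled, ratio back to 1
  cfgl <- sim_ephys_config(seed = 6, v_amp = 200, h_amp = 180, g_nmda = 1,
                           noise_sd = 0)
  rl <- analyze_ephys_trials(simulate_ephys(cfgl, 4)$traces,
                             simulate_ephys(cfgl, 4)$meta)
  expect_equal(rl$linearity$ratio, 1, tolerance = 0.02)
  expect_equal(rl$threshold_class, "suprathreshold")
})
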