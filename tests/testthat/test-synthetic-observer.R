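test_that("default stimulus grid matches the experimental design", {
  grid <- build_stimulus_grid(simulation_config())
  # 6 conditions x 13 stimuli; 13 x 9 disparity levels = 117 trial types
  expect_equal(nrow(grid), 78)
  counts <- table(grid$condition_id)
  expect_true(all(counts == 13))
  expect_equal(sum(grid$condition_id == "stat36_slow") *
                 length(attr(grid, "pixels")), 117)
  # four head-stationary conditions at three distances, two translating
  stat <- grid[grid$head_state == "stationary", ]
  expect_equal(sort(unique(stat$f_cm)), c(36, 54, 72))
  expect_equal(length(unique(stat$condition_id)), 4)
  expect_equal(sort(unique(grid$f_cm[grid$head_state == "translating"])),
               c(36, 72))
  # all ratios within the tested range; printed anchors present
  expect_true(all(grid$ratio >= 0.042 & grid$ratio <= 0.25))
  expect_true(all(c(0.042, 0.083, 0.167, 0.25) %in% round(stat$ratio, 4)))
  expect_true(all(c(1.1, 4.15, 4.95, 5.81, 6.6, 11.57) %in% stat$dalpha_deg_s))
  # the 4.95 deg/s pursuit speed replicates across both 36 cm conditions
  expect_true(4.95 %in% stat$dalpha_deg_s[stat$condition_id == "stat36_slow"])
  expect_true(4.95 %in% stat$dalpha_deg_s[stat$condition_id == "stat36_fast"])
  # stationary retinal speeds within the instrumented range
  expect_true(all(stat$dtheta_deg_s >= 0.14 & stat$dtheta_deg_s <= 1.65))
  # disparity levels follow pixel geometry (level 9 at 36 cm)
  expect_equal(attr(grid, "disparity")[["36"]][9],
               pixel_to_angle(9, 0.244, 36))
  expect_equal(attr(grid, "disparity")[["36"]][9], 20.97, tolerance = 1e-3)
})

test_that("grid construction rejects out-of-range ratios", {
  bad <- data.frame(condition_id = "x", head_state = "stationary", f_cm = 36,
                    dtheta_deg_s = 5, dalpha_deg_s = 4)
  expect_error(build_stimulus_grid(simulation_config(pairs = bad)),
               "\\(0, 1\\)")
})

test_that("trial generation is deterministic given the seed", {
  cfg <- tiny_config()
  grid <- build_stimulus_grid(cfg)
  a <- simulate_trials(grid, cfg, seed = 99)
  b <- simulate_trials(grid, cfg, seed = 99)
  expect_identical(a, b)
  ht_a <- simulate_head_translation_session(grid, cfg, seed = 99)
  ht_b <- simulate_head_translation_session(grid, cfg, seed = 99)
  expect_identical(ht_a, ht_b)
  ca <- simulate_depth_constancy_control(cfg, seed = 99)
  cb <- simulate_depth_constancy_control(cfg, seed = 99)
  expect_identical(ca, cb)
  # and written files are byte-identical
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trials(a, f1, provenance = list(seed = 99))
  write_trials(b, f2, provenance = list(seed = 99))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noise-free responses form an exact step at the matching disparity", {
  cfg <- simulation_config(noise_cv = 0, n_observers = 1, n_blocks = 1)
  grid <- build_stimulus_grid(cfg)
  tr <- simulate_trials(grid, cfg, seed = 5, keep_internal = TRUE)
  one <- tr[tr$condition_id == "stat36_fast" &
              abs(tr$dtheta_deg_s - 0.25 * 4.95) < 1e-9, ]
  d_mp <- empirical_depth(transducer_model(),
                          dtheta = 0.25 * 4.95, dalpha = 4.95, f = 36)
  expect_equal(unique(one$mp_internal), d_mp)
  # responses are the indicator stereo depth > d_mp
  d_st <- disparity_to_depth(one$disparity_arcmin, 36)
  expect_identical(one$response_stereo_deeper, d_st > d_mp)
  # fitted PSE identified to within one disparity level of d_mp * i / f^2
  fits <- fit_session(tr[tr$condition_id == "stat36_fast", ])
  expected_pse <- depth_to_disparity(
    empirical_depth(fits, model = transducer_model()), f = 36)
  spacing <- pixel_to_angle(1, 0.244, 36)
  expect_true(all(abs(fits$pse - expected_pse) <= spacing))
})

test_that("mean internal depth converges to the transducer prediction", {
  pair <- data.frame(condition_id = "one", head_state = "stationary",
                     f_cm = 36, dtheta_deg_s = 0.5, dalpha_deg_s = 4.95)
  cfg <- simulation_config(noise_cv = 0.15, n_observers = 1, n_blocks = 1120,
                           pairs = pair)
  grid <- build_stimulus_grid(cfg)
  tr <- simulate_trials(grid, cfg, seed = 8, keep_internal = TRUE)
  expect_gte(nrow(tr), 1e4)
  d_true <- empirical_depth(transducer_model(),
                            dtheta = 0.5, dalpha = 4.95, f = 36)
  expect_equal(mean(tr$mp_internal) / d_true, 1, tolerance = 0.01)
})

test_that("fitted PSEs increase with dtheta at fixed dalpha and f", {
  pairs <- data.frame(condition_id = "mono", head_state = "stationary",
                      f_cm = 36, dtheta_deg_s = c(0.3, 0.6, 0.9, 1.2),
                      dalpha_deg_s = 4.95)
  cfg <- simulation_config(n_observers = 1, n_blocks = 300, pairs = pairs)
  grid <- build_stimulus_grid(cfg)
  tr <- simulate_trials(grid, cfg, seed = 13)
  fits <- fit_session(tr)
  fits <- fits[order(fits$dtheta_deg_s), ]
  expect_true(all(diff(fits$pse) > 0))
})

test_that("head-translating sessions record speeds and honor the pursuit gain", {
  cfg <- tiny_config()
  grid <- build_stimulus_grid(cfg)
  ht <- simulate_head_translation_session(grid, cfg, seed = 2)
  expect_true(all(ht$head_state == "translating"))
  expect_true(all(is.finite(ht$head_speed_cm_s) & ht$head_speed_cm_s > 0))
  expect_equal(mean(ht$head_speed_cm_s[ht$f_cm == 36]), 11.0, tolerance = 0.05)
  expect_equal(mean(ht$head_speed_cm_s[ht$f_cm == 72]), 12.1, tolerance = 0.05)
  # mean total compensatory eye speed ~ 17.5 deg/s at 36 cm
  tot <- head_speed_to_pursuit_rate(ht$head_speed_cm_s[ht$f_cm == 36], 36)
  expect_equal(mean(tot), 17.5, tolerance = 0.05 * 17.5)
  bad_cfg <- tiny_config(); bad_cfg$pursuit_gain <- 1.5
  expect_error(simulate_head_translation_session(grid, bad_cfg, seed = 1),
               "pursuit_gain")
})

test_that("translating depth matches equal stationary matches at the pursuit-scaled rate", {
  pairs <- default_stimulus_pairs()
  tp <- pairs[pairs$condition_id == "trans36", ]
  cfg <- simulation_config(n_observers = 1, n_blocks = 100)
  g_t <- build_stimulus_grid(simulation_config(pairs = tp))
  tr_t <- simulate_head_translation_session(g_t, cfg, seed = 31)
  f_t <- fit_session(tr_t)
  eff <- cfg$pursuit_gain * head_speed_to_pursuit_rate(11.0, 36)
  sp <- tp
  sp$head_state <- "stationary"
  sp$dalpha_deg_s <- eff
  sp$dtheta_deg_s <- sp$ratio * eff
  g_s <- build_stimulus_grid(simulation_config(pairs = sp))
  tr_s <- simulate_trials(g_s, cfg, seed = 131)
  f_s <- fit_session(tr_s)
  ratio <- f_t$d_mp[order(f_t$dtheta_deg_s)] / f_s$d_mp[order(f_s$dtheta_deg_s)]
  expect_equal(mean(ratio), 1, tolerance = 0.02)
})

test_that("depth-constancy control reproduces its observer models", {
  cfg <- simulation_config(n_control_observers = 9, n_control_blocks = 2)
  ctrl <- simulate_depth_constancy_control(cfg, "perfect_constancy", seed = 41)
  res <- analyze_depth_constancy(ctrl)
  expect_true(all(res$converged))
  # near-perfect depth constancy at the study's trial counts
  expect_true(all(res$normalized_match > 0.98 & res$normalized_match < 1.02))
  # the geometric PSE: 23.3 * (36/72)^2 = 5.825 arcmin
  expect_equal(res$pse_arcmin[res$condition_id == "control_fix36"], 5.825,
               tolerance = 0.03)

  # disparity matching ignores distance: PSE at the standard's disparity,
  # a four-fold depth mismatch (needs a widened variable range to observe)
  wide <- control_design()
  wide$variable_min_arcmin <- c(15, 2)
  wide$variable_max_arcmin <- c(32, 10)
  dm <- simulate_depth_constancy_control(cfg, "disparity_matcher",
                                         design = wide, seed = 42)
  res_dm <- analyze_depth_constancy(dm)
  expect_equal(res_dm$pse_arcmin[res_dm$condition_id == "control_fix36"],
               23.3, tolerance = 0.04 * 23.3)
  expect_equal(res_dm$normalized_match[res_dm$condition_id == "control_fix36"],
               4, tolerance = 0.2)

  # a 10% distance mis-estimate shifts the PSE by the squared factor
  mm <- simulate_depth_constancy_control(cfg, "distance_misestimate",
                                         misestimate = 0.10, seed = 43)
  res_mm <- analyze_depth_constancy(mm)
  expect_equal(res_mm$pse_arcmin[res_mm$condition_id == "control_fix36"],
               5.825 / 0.9^2, tolerance = 0.04 * 7.2)
  expect_equal(res_mm$pse_arcmin[res_mm$condition_id == "control_fix72"],
               18.64 / 1.1^2, tolerance = 0.04 * 15.4)
  expect_error(simulate_depth_constancy_control(cfg, "telepathy"),
               "arg")
})
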