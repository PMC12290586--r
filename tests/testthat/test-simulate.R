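test_that("vigilance trajectory is a bounded OU path with exact null cases", {
  cfg <- sim_config(seed = 40)
  set.seed(40)
  v <- simulate_vigilance_trajectory(cfg)
  expect_length(v, 700)
  vm <- cfg$vigilance_model
  expect_true(all(v >= vm$v_min & v <= vm$v_max))

  # zero diffusion -> constant at the initial (mean) value
  cfg0 <- sim_config(vigilance_model = list(ou_theta = 1 / 300, ou_sigma = 0,
                                            v_min = 0.3, v_max = 2.2))
  set.seed(1)
  expect_equal(simulate_vigilance_trajectory(cfg0),
               rep((0.3 + 2.2) / 2, 700))

  # strong mean reversion: sample mean near the stationary mean.
  # var(time average of OU) ~ 2 sigma^2 / (theta^2 T) for T >> 1/theta
  cfgs <- sim_config(session_duration_s = 6300,
                     vigilance_model = list(ou_theta = 0.5, ou_sigma = 0.1,
                                            v_min = 0.3, v_max = 2.2))
  set.seed(41)
  vs <- simulate_vigilance_trajectory(cfgs)
  se <- sqrt(2 * 0.1^2 / (0.5^2 * 6300))
  expect_lt(abs(mean(vs) - 1.25), 3 * se)

  expect_error(simulate_vigilance_trajectory(
    sim_config(vigilance_model = list(ou_theta = -1, ou_sigma = 1,
                                      v_min = 0, v_max = 1))))
})

test_that("identical config and seed reproduce the session bit for bit", {
  cfg <- sim_config(seed = 42)
  expect_identical(simulate_session(cfg, "task"),
                   simulate_session(cfg, "task"))
  cfg2 <- sim_config(seed = 43)
  expect_false(identical(simulate_session(cfg2, "rest")$vigilance,
                         simulate_session(cfg, "rest")$vigilance))
})

test_that("autonomic truth encodes the drowsiness direction and clipping", {
  cfg <- sim_config(autonomic_fluct = list(tau_s = 30, hr_sd_bpm = 0, rv_sd = 0,
                                           pwa_sd = 0, drowsy_scale = 0))
  v <- seq(0.3, 2.2, length.out = 100)
  tr <- simulate_autonomic_truth(v, cfg)
  # heart slows, breathing deepens, pulse amplitude grows as vigilance falls
  expect_true(all(diff(tr$ibi_true) < 0))
  expect_true(all(diff(tr$hr_true) > 0))
  expect_true(all(diff(tr$rv_true) < 0))
  expect_true(all(diff(tr$pwa_true) < 0))
  expect_equal(tr$hr_true, 60 / tr$ibi_true)
  # coupling gain is monotone non-increasing in vigilance
  g_hi <- vigicov:::drowsiness(2.2, cfg)
  g_lo <- vigicov:::drowsiness(0.3, cfg)
  expect_equal(c(g_hi, g_lo), c(0, 1))
})

test_that("constant vigilance with zero noise gives constant physiology", {
  cfg <- sim_config(seed = 44, session_duration_s = 210, physio_noise_sd = 0,
                    vigilance_model = list(ou_theta = 1 / 300, ou_sigma = 0,
                                           v_min = 0.3, v_max = 2.2),
                    autonomic_fluct = list(tau_s = 30, hr_sd_bpm = 0, rv_sd = 0,
                                           pwa_sd = 0, drowsy_scale = 0))
  s <- simulate_session(cfg, "rest", waveforms = TRUE)
  expect_equal(diff(range(s$truth$ibi_true)), 0)
  feats <- physio_features(s$physio, cfg$physio_rate_hz, cfg$tr_s,
                           length(s$vigilance), lowpass = FALSE)
  expect_equal(feats$hr, rep(60 / s$truth$ibi_true[1],
                             length(s$vigilance)), tolerance = 0.5)
})

test_that("event trains respect ISI bounds, miss rates, and the 4-s rule", {
  cfg <- sim_config(seed = 45)
  set.seed(45)
  v <- simulate_vigilance_trajectory(cfg)
  ev <- simulate_events(cfg, v)
  isi <- diff(ev$onset_s)
  expect_true(all(isi >= 29 & isi <= 41))
  expect_true(all(is.na(ev$rt_s) | (ev$rt_s > 0 & ev$rt_s <= 4)))
  # expected event count for fixed ISI: floor(1470 / 35) = 42
  expect_equal(floor(1470 / 35), 42)
  expect_gt(nrow(ev), 1470 / 41 - 2)
  expect_lt(nrow(ev), 1470 / 29 + 2)

  # p_miss = 0: every event gets a response (up to the 4-s censoring rule)
  cfg0 <- sim_config(seed = 46, task = list(isi_min_s = 29, isi_max_s = 41,
                                            p_miss_low_vig = 0))
  set.seed(46)
  ev0 <- simulate_events(cfg0, rep(2.2, 700))   # fully alert: fast RTs
  expect_true(all(ev0$responded))
})

test_that("noiseless fMRI with constant gain is fully explained by the design", {
  cfg <- sim_config(seed = 47,
                    coupling = list(gain_high_vig = 0.8, gain_low_vig = 0.8),
                    noise = list(ar1_phi = 0.4, sigma = 0, voxel_sigma = 0))
  s <- simulate_session(cfg, "rest", waveforms = FALSE)
  an <- analyze_global_r2(s)
  expect_equal(an$r2$r2_pct, rep(100, 11), tolerance = 1e-6)
})

test_that("doubled low-vigilance gain raises R^2 in the drowsiest tertile", {
  pooled <- pooled_sessions(401:420)
  st <- stage_tertiles(pooled$baseline)
  r2 <- setNames(pooled$r2$r2_pct, as.character(pooled$r2$window_id))
  ids <- intersect(names(st$stage), names(r2))
  expect_gt(mean(r2[ids[st$stage[ids] == "low"]]),
            mean(r2[ids[st$stage[ids] == "high"]]))
})
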