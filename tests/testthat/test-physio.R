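test_that("windowed std follows amplitude semantics", {
  fs <- 100
  t <- seq(-3, 63, by = 1 / fs)
  centers <- seq(3, 57, by = 2.1)
  # constant signal
  expect_equal(windowed_std(rep(5, length(t)), t, centers),
               rep(0, length(centers)))
  # unit sine, integer cycles per 6-s window -> A/sqrt(2)
  s <- sin(2 * pi * 0.5 * t)
  expect_equal(windowed_std(s, t, centers), rep(1 / sqrt(2),
                                                length(centers)),
               tolerance = 0.01)
  # two-point window: population std of {0, 2} is 1
  expect_equal(windowed_std(c(9, 0, 2, 9), c(-1, 0, 0.1, 1.1), 0.05,
                            half_width_s = 0.07), 1)
  # window past the recording edge
  expect_error(windowed_std(s, t, 62), "past the recording")
  # linearity in amplitude
  expect_equal(windowed_std(3 * s, t, centers),
               3 * windowed_std(s, t, centers), tolerance = 1e-12)
})

test_that("autonomic low-pass keeps slow components and rejects fast ones", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  expect_equal(lowpass_autonomic(rep(2.5, length(t)), fs),
               rep(2.5, length(t)), tolerance = 1e-6)
  slow <- sin(2 * pi * 0.01 * t)
  out <- lowpass_autonomic(slow, fs)
  expect_gte(max(abs(out[100:5900])), 0.95)
  fast <- sin(2 * pi * 0.3 * t)
  expect_lte(max(abs(lowpass_autonomic(fast, fs)[100:5900])), 0.2)
})

test_that("PPG band-pass passes the pulse band and rejects drift", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  mid <- 2000:10000
  pulse <- sin(2 * pi * 1 * t)
  expect_equal(max(abs(bandpass_ppg(pulse, fs)[mid])), 1, tolerance = 0.1)
  drift <- sin(2 * pi * 0.05 * t)
  expect_lt(max(abs(bandpass_ppg(drift, fs)[mid])), 0.1)
  expect_equal(bandpass_ppg(numeric(1000), fs), numeric(1000))
  expect_error(bandpass_ppg(pulse, 3), "exceed 4 Hz")
})

test_that("peak detection applies height and spacing rules", {
  fs <- 100
  # 1-Hz pulse train over 60 s
  t <- seq(0, 60, by = 1 / fs)
  x <- vigicov:::ppg_pulse((t %% 1))
  pk <- detect_peaks(x, fs)
  expect_equal(length(pk), 60, tolerance = 1)
  expect_equal(median(diff(pk)), 1, tolerance = 0.02)

  # two equal peaks 0.4 s apart: one survives (minimum distance 0.55 s)
  y <- numeric(300)
  y[100] <- 1; y[140] <- 1; y[250] <- 0.9
  pk2 <- detect_peaks(y, fs)
  expect_equal(sum(abs(pk2 - 0.99) < 0.45), 1)
  # earlier of the tied pair is kept
  expect_true(any(abs(pk2 - 0.99) < 0.01))

  # minimum admissible spacing corresponds to 109.09 bpm
  expect_equal(60 / 0.55, 109.09, tolerance = 1e-3)

  expect_error(detect_peaks(numeric(100), fs), "no PPG peaks")
})

test_that("IBI cleaning interpolates artifacts and reports the fraction", {
  clean <- ibi_clean(cumsum(c(0, rep(1, 30))))
  expect_equal(clean$interpolated_fraction, 0)
  expect_equal(clean$ibi_s, rep(1, 30))

  # one 3-s gap in a 1-s train -> flagged and replaced by ~1 s
  pk <- cumsum(c(0, rep(1, 15), 3, rep(1, 15)))
  fixed <- ibi_clean(pk)
  expect_equal(fixed$interpolated_fraction, 1 / 31, tolerance = 1e-9)
  expect_equal(fixed$ibi_s[16], 1, tolerance = 0.01)

  # everything out of bounds -> unusable
  expect_error(ibi_clean(cumsum(c(0, rep(0.25, 20)))), "unusable")
  expect_error(ibi_clean(c(0, 1)), "at least 3 peaks")
})

test_that("per-window heart rate uses the median IBI", {
  ibi <- list(ibi_s = rep(1, 20), ibi_time_s = seq(0.5, 19.5))
  expect_equal(hr_per_tr(ibi, c(5, 10)), c(60, 60))
  ibi2 <- list(ibi_s = c(0.5, 0.5, 0.6), ibi_time_s = c(4, 5, 6))
  expect_equal(hr_per_tr(ibi2, 5), 120)
  ibi3 <- list(ibi_s = rep(0.55, 20), ibi_time_s = seq(0.5, 19.5) * 0.55)
  expect_equal(hr_per_tr(ibi3, 3), 109.09, tolerance = 1e-2)
  # empty window carries nearest value with a warning
  expect_warning(hr <- hr_per_tr(ibi2, c(5, 50)), "no IBIs")
  expect_equal(hr[2], hr[1])
})

test_that("HR pipeline recovers a known IBI trajectory within 1 bpm", {
  # artifact-free synthetic session, deterministic physiology
  cfg <- sim_config(seed = 11, physio_noise_sd = 0,
                    autonomic_fluct = list(tau_s = 30, hr_sd_bpm = 0,
                                           rv_sd = 0, pwa_sd = 0,
                                           drowsy_scale = 0))
  set.seed(cfg$seed)
  vig <- simulate_vigilance_trajectory(cfg)
  ph <- simulate_physio(vig, cfg)
  n_tr <- length(vig)
  feats <- physio_features(ph$physio, cfg$physio_rate_hz, cfg$tr_s, n_tr,
                           lowpass = FALSE)
  expect_equal(nrow(feats), n_tr)
  # oracle: 60 / median of the true beat-to-beat intervals in each window
  true_ibi <- diff(ph$beats_s)
  mid <- (head(ph$beats_s, -1) + tail(ph$beats_s, -1)) / 2
  centers <- (seq_len(n_tr) - 1) * cfg$tr_s + cfg$tr_s / 2
  hr_oracle <- vapply(centers, function(ct) {
    60 / median(true_ibi[abs(mid - ct) <= 3])
  }, numeric(1))
  expect_lt(max(abs(feats$hr - hr_oracle)), 1)
  expect_true(all(feats$hr > 20 & feats$hr < 200))
  expect_true(all(feats$rv >= 0 & feats$pwa >= 0))
})

test_that("zero respiration depth gives zero RV in every window", {
  cfg <- sim_config(seed = 12, physio_noise_sd = 0, session_duration_s = 210,
                    autonomic_fluct = list(tau_s = 30, hr_sd_bpm = 0, rv_sd = 0,
                                           pwa_sd = 0, drowsy_scale = 0))
  set.seed(12)
  vig <- simulate_vigilance_trajectory(cfg)
  truth <- simulate_autonomic_truth(vig, cfg)
  truth$rv_true[] <- 0
  ph <- simulate_physio(vig, cfg, truth)
  rv <- windowed_std(ph$physio$resp, ph$physio$time_s,
                     (seq_along(vig) - 1) * cfg$tr_s + cfg$tr_s / 2)
  expect_equal(rv, rep(0, length(vig)))
})

test_that("doubling pulse amplitude doubles the windowed PPG std", {
  cfg <- sim_config(seed = 13, physio_noise_sd = 0, session_duration_s = 420,
                    autonomic_fluct = list(tau_s = 30, hr_sd_bpm = 0, rv_sd = 0,
                                           pwa_sd = 0, drowsy_scale = 0))
  set.seed(13)
  vig <- simulate_vigilance_trajectory(cfg)
  truth <- simulate_autonomic_truth(vig, cfg)
  n <- length(vig)
  truth$pwa_true <- rep(c(1, 2), each = n / 2)
  ph <- simulate_physio(vig, cfg, truth)
  centers <- (seq_len(n) - 1) * cfg$tr_s + cfg$tr_s / 2
  pwa <- windowed_std(ph$physio$ppg, ph$physio$time_s, centers)
  first <- median(pwa[10:(n / 2 - 10)])
  second <- median(pwa[(n / 2 + 10):(n - 10)])
  expect_equal(second / first, 2, tolerance = 0.05)
})
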