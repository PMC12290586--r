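# Shared fixtures: lean single-session analysis used by the recovery,
# calibration and staging tests. Sessions are generated from the TR-level
# ground truth (no waveform synthesis) unless the test exercises the
# waveform feature-extraction path explicitly.

lean_session <- function(seed, gain_high = 0.5, gain_low = 1.0,
                         condition = "rest", waveforms = FALSE, ...) {
  cfg <- sim_config(seed = seed,
                    coupling = list(gain_high_vig = gain_high,
                                    gain_low_vig = gain_low), ...)
  simulate_session(cfg, condition, waveforms = waveforms)
}

truth_autonomic <- function(session) {
  n <- length(session$truth$rv_true)
  data.frame(tr_index = seq_len(n) - 1L, rv = session$truth$rv_true,
             hr = session$truth$hr_true, pwa = session$truth$pwa_true)
}

# windowed R^2 of the global signal vs baseline vigilance for one session;
# returns pieces for pooling across sessions
analyze_global_r2 <- function(session, window_len_tr = 60, n_discard = 7,
                              group = "autonomic") {
  tr_s <- session$config$tr_s
  design <- build_design(truth_autonomic(session), tr_s,
                         events = session$events, n_discard = n_discard)
  design <- highpass_design(design, window_len_tr * tr_s)
  global <- rowMeans(session$fmri$roi)[-seq_len(n_discard)]
  g <- highpass_for_windows(global, 1 / tr_s, window_len_tr * tr_s)
  w <- segment_windows(length(g), window_len_tr,
                       session = session$config$seed)
  b <- baseline_vigilance(vigilance_index(session$eeg)[-seq_len(n_discard)],
                          w, shift_trs = 2)
  r2 <- windowed_r2(g, design, w, group = group,
                    model_stimuli = !is.null(session$events))
  list(r2 = r2, baseline = b, windows = w, global_hp = g, design = design)
}

pooled_sessions <- function(seeds, gain_high = 0.5, gain_low = 1.0, ...) {
  parts <- lapply(seeds, function(sd) {
    analyze_global_r2(lean_session(sd, gain_high, gain_low), ...)
  })
  list(r2 = do.call(rbind, lapply(parts, `[[`, "r2")),
       baseline = do.call(c, lapply(parts, `[[`, "baseline")),
       parts = parts)
}
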