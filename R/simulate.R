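#' Configuration for a synthetic EEG-fMRI-autonomic session
#'
#' Defines the study conditions emulated by the generator: a 24.5-min scan
#' at TR = 2.1 s, physiological waveforms at 100 Hz, a slow latent vigilance
#' trajectory (Ornstein-Uhlenbeck, minutes-scale correlation time) driving
#' EEG alpha/theta power, inter-beat intervals, respiration depth and pulse
#' amplitude, a vigilance-dependent coupling gain between convolved
#' autonomic signals and fMRI series, and a sparse auditory task with
#' 29-41 s inter-stimulus intervals.
#'
#' @param session_duration_s scan length in seconds (default 1470).
#' @param tr_s repetition time in seconds (default 2.1).
#' @param physio_rate_hz waveform sampling rate (default 100 Hz; a config
#'   field so higher acquisition rates can be matched).
#' @param n_rois number of ROI/network series (default 8: seven cortical
#'   networks plus subcortex).
#' @param n_voxels_per_roi voxels simulated per ROI (default 4).
#' @param vigilance_model list: `ou_theta` (1/s, mean-reversion rate),
#'   `ou_sigma` (a.u./sqrt(s), diffusion), `v_min`, `v_max` (bounds of the
#'   latent index, on the alpha/theta-ratio scale).
#' @param coupling list: `gain_high_vig`, `gain_low_vig` -- the fMRI-autonomic
#'   coupling gain at full alertness and at the drowsy floor. The default
#'   doubles the gain from high to low vigilance; `gain_low_vig >=
#'   gain_high_vig >= 0` is required (stronger coupling when drowsy).
#' @param noise list: `ar1_phi`, `sigma` (% signal) for the fMRI AR(1)
#'   noise, and `voxel_sigma` for independent voxel-level noise. The default
#'   `sigma` places the windowed variance explained by the autonomic
#'   regressors in a realistic mid range rather than near its ceiling.
#' @param autonomic_fluct list: `tau_s` (correlation time) and `hr_sd_bpm`,
#'   `rv_sd`, `pwa_sd` -- scales of the Ornstein-Uhlenbeck fluctuations each
#'   autonomic measure carries independently of vigilance (heart rate on the
#'   beats-per-minute scale, where its variability is conventionally
#'   quantified), so that RV, HR and PWA are correlated through the
#'   vigilance drive but not collinear; `drowsy_scale` multiplies every
#'   fluctuation's innovation scale by `1 + drowsy_scale * drowsiness`.
#' @param task list: `isi_min_s`, `isi_max_s`, `p_miss_low_vig` (miss
#'   probability at the drowsy floor; misses scale linearly with
#'   drowsiness).
#' @param physio_noise_sd beat-level IBI jitter (s); 0 gives fully
#'   deterministic physiology given the vigilance path.
#' @param roi_weights optional `n_rois` x 3 matrix of per-ROI weights on the
#'   convolved RV/HR/PWA drives (default all 1).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(session_duration_s = 1470, tr_s = 2.1,
                       physio_rate_hz = 100, n_rois = 8,
                       n_voxels_per_roi = 4,
                       vigilance_model = list(ou_theta = 1 / 300,
                                              ou_sigma = 0.0449,
                                              v_min = 0.3, v_max = 2.2),
                       coupling = list(gain_high_vig = 0.5,
                                       gain_low_vig = 1.0),
                       noise = list(ar1_phi = 0.4, sigma = 1.5,
                                    voxel_sigma = 0.5),
                       autonomic_fluct = list(tau_s = 30, hr_sd_bpm = 2.5,
                                              rv_sd = 0.15, pwa_sd = 0.15,
                                              drowsy_scale = 1),
                       task = list(isi_min_s = 29, isi_max_s = 41,
                                   p_miss_low_vig = 0.5),
                       physio_noise_sd = 0.005,
                       roi_weights = NULL, seed = 1L) {
  n_tr_exact <- session_duration_s / tr_s
  if (abs(n_tr_exact - round(n_tr_exact)) > 1) {
    stop("session duration must be within 1 TR of a whole number of volumes")
  }
  stopifnot(tr_s > 0, physio_rate_hz > 0, vigilance_model$ou_theta > 0,
            vigilance_model$ou_sigma >= 0,
            vigilance_model$v_min < vigilance_model$v_max,
            task$isi_min_s < task$isi_max_s)
  if (!(coupling$gain_low_vig >= coupling$gain_high_vig &&
        coupling$gain_high_vig >= 0)) {
    stop("coupling must satisfy gain_low_vig >= gain_high_vig >= 0")
  }
  if (is.null(roi_weights)) roi_weights <- matrix(1, n_rois, 3)
  structure(list(session_duration_s = session_duration_s, tr_s = tr_s,
                 physio_rate_hz = physio_rate_hz, n_rois = n_rois,
                 n_voxels_per_roi = n_voxels_per_roi,
                 vigilance_model = vigilance_model, coupling = coupling,
                 noise = noise, autonomic_fluct = autonomic_fluct,
                 task = task,
                 physio_noise_sd = physio_noise_sd,
                 roi_weights = roi_weights, seed = as.integer(seed)),
            class = "sim_config")
}

# drowsiness in [0, 1]: 0 at v_max (alert), 1 at v_min (drowsy floor)
drowsiness <- function(v, config) {
  vm <- config$vigilance_model
  pmin(pmax((vm$v_max - v) / (vm$v_max - vm$v_min), 0), 1)
}

#' Latent vigilance trajectory
#'
#' Exact-discretization Ornstein-Uhlenbeck path on the TR grid, reflected
#' into `[v_min, v_max]`, with stationary mean at the interval midpoint.
#' Vigilance therefore drifts slowly and mean-reverts on the
#' `1/ou_theta`-second time scale. With `ou_sigma = 0` the path is constant
#' at its initial (mean) value.
#'
#' @param config a `sim_config`. Set the RNG seed before calling (or use
#'   [simulate_session()], which seeds once for the whole session).
#' @return per-TR latent vigilance, length `floor(duration / TR)`.
#' @export
simulate_vigilance_trajectory <- function(config) {
  vm <- config$vigilance_model
  if (vm$ou_theta <= 0 || vm$ou_sigma < 0) {
    stop("OU parameters must be positive (sigma may be zero)")
  }
  n_tr <- floor(config$session_duration_s / config$tr_s)
  mu <- (vm$v_min + vm$v_max) / 2
  a <- exp(-vm$ou_theta * config$tr_s)
  s <- vm$ou_sigma * sqrt((1 - a^2) / (2 * vm$ou_theta))
  v <- numeric(n_tr)
  v[1] <- mu
  eps <- rnorm(n_tr)
  for (t in seq_len(n_tr - 1)) {
    x <- mu + (v[t] - mu) * a + s * eps[t]
    # reflect into the admissible band
    while (x < vm$v_min || x > vm$v_max) {
      if (x < vm$v_min) x <- 2 * vm$v_min - x
      if (x > vm$v_max) x <- 2 * vm$v_max - x
    }
    v[t + 1] <- x
  }
  v
}

# zero-mean OU path on the TR grid with given baseline sd and correlation
# time; `scale` multiplies the innovation sd per sample (heteroscedastic)
ou_path <- function(n, tr_s, sd, tau_s, scale = 1) {
  if (sd == 0) return(numeric(n))
  a <- exp(-tr_s / tau_s)
  innov <- rnorm(n, sd = sd * sqrt(1 - a^2)) * scale
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = rnorm(1, sd = sd)))
}

#' Autonomic ground truth from a vigilance path
#'
#' Per-TR true autonomic state: each measure is an affine function of
#' drowsiness (heart slowing, deeper breathing, larger pulse amplitude as
#' vigilance falls) plus an independent Ornstein-Uhlenbeck fluctuation whose
#' innovation scale grows with drowsiness (`1 + drowsy_scale * drowsiness`),
#' so vigilance drives both the mean and the variability of the autonomic
#' state while the three measures stay non-collinear. With
#' `autonomic_fluct` scales set to 0 the truth is a deterministic function
#' of the vigilance path.
#'
#' @param vigilance per-TR latent vigilance.
#' @param config a `sim_config`.
#' @return list: `ibi_true` (s), `rv_true`, `pwa_true` (a.u.), `hr_true`
#'   (bpm), per TR.
#' @export
simulate_autonomic_truth <- function(vigilance, config) {
  n_tr <- length(vigilance)
  d <- drowsiness(vigilance, config)
  fl <- config$autonomic_fluct
  dsc <- if (is.null(fl$drowsy_scale)) 0 else fl$drowsy_scale
  sc <- 1 + dsc * d
  # heart rate: slowing with drowsiness plus bpm-scale variability
  hr <- 60 / (0.85 + 0.30 * d) +
    ou_path(n_tr, config$tr_s, fl$hr_sd_bpm, fl$tau_s, sc)
  ibi <- 60 / pmin(pmax(hr, 25), 180)
  if (any(ibi <= 0.3 | ibi >= 3)) {
    warning("true IBI outside (0.3, 3) s; clipping")
    ibi <- pmin(pmax(ibi, 0.31), 2.99)
  }
  rv <- pmax(1 + 0.6 * d + ou_path(n_tr, config$tr_s, fl$rv_sd, fl$tau_s, sc),
             0.05)
  pwa <- pmax(1 + 0.8 * d + ou_path(n_tr, config$tr_s, fl$pwa_sd, fl$tau_s,
                                    sc),
              0.05)
  list(ibi_true = ibi, rv_true = rv, pwa_true = pwa, hr_true = 60 / ibi)
}

# asymmetric gamma-shaped pulse, ~0.3 s wide, unit peak
ppg_pulse <- function(u_s) {
  shape <- 3; scale <- 0.04
  p <- dgamma(u_s, shape = shape, scale = scale)
  p / dgamma((shape - 1) * scale, shape = shape, scale = scale)
}

#' Physiological waveforms and ground truth from a vigilance path
#'
#' Maps latent vigilance to autonomic ground truth and synthesizes the raw
#' waveforms:
#' \itemize{
#'   \item inter-beat interval lengthens as vigilance falls (heart-rate
#'     slowing toward sleep onset): `ibi = 0.85 + 0.30 * drowsiness` s;
#'   \item pulse amplitude rises with drowsiness (peripheral vasodilation):
#'     `pwa = 1 + 0.8 * drowsiness`;
#'   \item respiration depth rises with drowsiness: `rv = 1 + 0.6 *
#'     drowsiness`, around a slowly wandering ~0.25 Hz breathing rate;
#'   \item the PPG is a train of gamma-shaped pulses (0.3 s wide) at the
#'     beat times with the local `pwa` amplitude; the respiration belt is a
#'     sinusoid with the local depth.
#' }
#' Waveforms are sampled at `physio_rate_hz` from 4 s before the first
#' trigger to 4 s after the session, so every centered 6-s feature window
#' is covered.
#'
#' @param vigilance per-TR latent vigilance.
#' @param config a `sim_config`.
#' @param truth optional ground truth from [simulate_autonomic_truth()];
#'   generated if missing.
#' @return list: `physio` (data.frame `time_s`, `resp`, `ppg`), `truth`
#'   (list `ibi_true`, `rv_true`, `pwa_true`, `hr_true` per TR), and
#'   `beats_s` (true beat times, the ground truth for peak detection).
#' @export
simulate_physio <- function(vigilance, config, truth = NULL) {
  n_tr <- length(vigilance)
  tr <- config$tr_s
  if (is.null(truth)) truth <- simulate_autonomic_truth(vigilance, config)
  ibi_true <- truth$ibi_true
  rv_true <- truth$rv_true
  pwa_true <- truth$pwa_true

  pad <- 4
  fs <- config$physio_rate_hz
  t0 <- -pad
  t1 <- config$session_duration_s + pad
  time_s <- seq(t0, t1, by = 1 / fs)
  tr_centers <- (seq_len(n_tr) - 1) * tr + tr / 2
  at_time <- function(x, t) approx(tr_centers, x, xout = t, rule = 2)$y

  # beat train: step through IBIs, jittered at beat level
  beats <- numeric(0)
  t <- t0
  while (t < t1) {
    beats <- c(beats, t)
    step <- at_time(ibi_true, t)
    if (config$physio_noise_sd > 0) {
      step <- step + rnorm(1, sd = config$physio_noise_sd)
    }
    t <- t + max(step, 0.31)
  }
  ppg <- numeric(length(time_s))
  support <- 0.35
  for (b in beats) {
    lo <- max(1, ceiling((b - t0) * fs) + 1)
    hi <- min(length(time_s), floor((b + support - t0) * fs) + 1)
    if (hi >= lo) {
      idx <- lo:hi
      ppg[idx] <- ppg[idx] + at_time(pwa_true, b) * ppg_pulse(time_s[idx] - b)
    }
  }

  # respiration: sinusoid with wandering rate and drowsiness-scaled depth
  rate <- 0.25 + 0.03 * sin(2 * pi * time_s / 300)
  phase <- cumsum(rate) / fs
  resp <- at_time(rv_true, time_s) * sin(2 * pi * phase)

  list(physio = data.frame(time_s = time_s, resp = resp, ppg = ppg),
       truth = truth, beats_s = beats)
}

#' Auditory task events with vigilance-dependent behavior
#'
#' Stimulus onsets follow independent uniform inter-stimulus intervals on
#' `[isi_min_s, isi_max_s]`. Each stimulus is responded to with probability
#' `1 - p_miss_low_vig * drowsiness`; reaction times lengthen with
#' drowsiness (`rt = 0.25 + 1.4 * drowsiness + noise` s) and responses
#' slower than 4 s are recorded as missing.
#'
#' @param config a `sim_config`.
#' @param vigilance per-TR latent vigilance.
#' @return data.frame: `onset_s`, `rt_s` (NA for misses and >4 s responses),
#'   `responded` (logical: a response occurred within 4 s).
#' @export
simulate_events <- function(config, vigilance) {
  tk <- config$task
  onsets <- numeric(0)
  t <- runif(1, tk$isi_min_s, tk$isi_max_s)
  while (t < config$session_duration_s) {
    onsets <- c(onsets, t)
    t <- t + runif(1, tk$isi_min_s, tk$isi_max_s)
  }
  tr_centers <- (seq_along(vigilance) - 1) * config$tr_s + config$tr_s / 2
  d <- drowsiness(approx(tr_centers, vigilance, xout = onsets, rule = 2)$y,
                  config)
  responded <- runif(length(onsets)) < 1 - tk$p_miss_low_vig * d
  rt <- 0.25 + 1.4 * d + rnorm(length(onsets), sd = 0.15)
  rt <- pmax(rt, 0.15)
  rt[!responded | rt > 4] <- NA
  data.frame(onset_s = onsets, rt_s = rt, responded = !is.na(rt))
}

#' fMRI series with vigilance-dependent autonomic coupling
#'
#' Each ROI series (percent signal change, full pre-discard grid) is
#' \deqn{y(t) = g(t) \sum_k w_k \tilde{x}_k(t) + \text{stim}(t) + \epsilon(t),}
#' where \eqn{\tilde{x}_k} are the z-scored convolutions of the true RV, HR
#' and PWA with their response functions (respiratory, cardiac, and
#' canonical hemodynamic kernel respectively, PWA advanced 2 TRs), the gain
#' \eqn{g(t)} is affine in vigilance -- `gain_high_vig` at full alertness,
#' `gain_low_vig` at the drowsy floor, clamped between -- responded stimuli
#' add a canonical-HRF response, and \eqn{\epsilon} is AR(1) noise with
#' innovation scale chosen to give marginal sd `noise$sigma`.
#'
#' @param vigilance per-TR latent vigilance.
#' @param physio_truth `truth` list from [simulate_physio()].
#' @param config a `sim_config`.
#' @param events optional event table from [simulate_events()].
#' @return list: `roi` (TR x n_rois matrix), `voxels` (TR x total-voxel
#'   matrix), `voxel_roi` (ROI label per voxel), `coupling_gain` (per TR),
#'   `drive` (the common convolved autonomic drive per TR).
#' @export
simulate_fmri <- function(vigilance, physio_truth, config, events = NULL) {
  n_tr <- length(vigilance)
  tr <- config$tr_s
  d <- drowsiness(vigilance, config)
  gain <- config$coupling$gain_high_vig +
    (config$coupling$gain_low_vig - config$coupling$gain_high_vig) * d

  rrf_k <- rrf_kernel(tr)$amplitude
  crf_k <- crf_kernel(tr)$amplitude
  hrf_k <- hrf_kernel(tr)$amplitude
  pwa_adv <- c(physio_truth$pwa_true[-(1:2)],
               rep(physio_truth$pwa_true[n_tr], 2))
  conv1 <- function(x, k) convolve(x, rev(k), type = "open")[seq_len(n_tr)]
  drives <- cbind(rv = zscore_vec(conv1(physio_truth$rv_true, rrf_k)),
                  hr = zscore_vec(conv1(physio_truth$hr_true, crf_k)),
                  pwa = zscore_vec(conv1(pwa_adv, hrf_k)))

  stim <- numeric(n_tr)
  if (!is.null(events) && any(events$responded)) {
    train <- numeric(n_tr)
    idx <- pmin(floor(events$onset_s[events$responded] / tr) + 1, n_tr)
    train[idx] <- 1
    stim <- conv1(train, hrf_k)
  }

  ar1 <- function(n) {
    phi <- config$noise$ar1_phi
    innov_sd <- config$noise$sigma * sqrt(1 - phi^2)
    as.numeric(stats::filter(rnorm(n, sd = innov_sd), phi,
                             method = "recursive"))
  }
  roi <- matrix(0, n_tr, config$n_rois)
  for (j in seq_len(config$n_rois)) {
    w <- config$roi_weights[j, ]
    noise <- if (config$noise$sigma > 0) ar1(n_tr) else numeric(n_tr)
    roi[, j] <- gain * (drives %*% w) + stim + noise
  }
  colnames(roi) <- paste0("roi", seq_len(config$n_rois))

  nvox <- config$n_rois * config$n_voxels_per_roi
  voxel_roi <- rep(seq_len(config$n_rois), each = config$n_voxels_per_roi)
  voxels <- roi[, voxel_roi, drop = FALSE] +
    matrix(rnorm(n_tr * nvox, sd = config$noise$voxel_sigma), n_tr, nvox)
  colnames(voxels) <- paste0("vox", seq_len(nvox))

  list(roi = roi, voxels = voxels, voxel_roi = voxel_roi,
       coupling_gain = gain, drive = drives)
}

# per-TR EEG band amplitudes whose alpha/theta ratio tracks latent vigilance
simulate_eeg_power <- function(vigilance, config, noise_sd = 0.05) {
  n_tr <- length(vigilance)
  d <- drowsiness(vigilance, config)
  theta <- exp(rnorm(n_tr, sd = noise_sd))
  alpha <- vigilance * theta * exp(rnorm(n_tr, sd = noise_sd))
  delta <- 0.8 * (1 + 0.4 * d) * exp(rnorm(n_tr, sd = noise_sd))
  data.frame(tr_index = seq_len(n_tr) - 1L, alpha = alpha, theta = theta,
             delta = delta)
}

#' Simulate a full synthetic session
#'
#' Seeds the RNG once from `config$seed` and generates, in a fixed order,
#' the latent vigilance path, physiological ground truth (optionally with
#' raw waveforms), per-TR EEG band powers, task events (task condition
#' only), and fMRI ROI/voxel series. Identical configs produce identical
#' sessions.
#'
#' @param config a `sim_config`.
#' @param condition `"rest"` or `"task"`.
#' @param waveforms logical; synthesize the raw 100-Hz physio waveforms
#'   (needed to exercise the feature-extraction pipeline) or only the
#'   TR-level ground truth (faster, used in large Monte-Carlo runs).
#' @return list of class `sim_session`: `config`, `condition`, `vigilance`,
#'   `truth`, `physio` (or NULL), `eeg`, `events` (or NULL), `fmri`.
#' @export
simulate_session <- function(config, condition = c("rest", "task"),
                             waveforms = TRUE) {
  condition <- match.arg(condition)
  set.seed(config$seed)
  vig <- simulate_vigilance_trajectory(config)
  truth <- simulate_autonomic_truth(vig, config)
  physio <- if (waveforms) simulate_physio(vig, config, truth)$physio else
    NULL
  eeg <- simulate_eeg_power(vig, config)
  events <- if (condition == "task") simulate_events(config, vig) else NULL
  fmri <- simulate_fmri(vig, truth, config, events = events)
  structure(list(config = config, condition = condition, vigilance = vig,
                 truth = truth, physio = physio, eeg = eeg, events = events,
                 fmri = fmri),
            class = "sim_session")
}
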