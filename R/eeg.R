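#' Per-TR EEG band RMS amplitudes
#'
#' For each channel, band-pass filters the cleaned EEG into the alpha
#' (8-12 Hz), theta (3-7 Hz) and delta (0.5-2 Hz) bands with a 4th-order
#' zero-phase Butterworth, takes the root-mean-square amplitude over each
#' volume's acquisition interval, and averages across channels to give one
#' value per band per volume.
#'
#' @param eeg numeric matrix, channels in rows, samples in columns.
#' @param rate_hz EEG sampling rate (Hz).
#' @param tr_s repetition time (s).
#' @param n_vols number of volumes; the recording must cover
#'   `n_vols * tr_s` seconds from its first sample.
#' @param bands named list of band edges in Hz.
#' @return data.frame of class `vigilance_series`: `tr_index` (0-based) and
#'   one column per band.
#' @export
band_rms_per_tr <- function(eeg, rate_hz, tr_s, n_vols,
                            bands = list(alpha = c(8, 12), theta = c(3, 7),
                                         delta = c(0.5, 2))) {
  eeg <- as.matrix(eeg)
  n_samp <- ncol(eeg)
  need <- ceiling(n_vols * tr_s * rate_hz)
  if (n_samp < need) {
    stop("EEG recording (", n_samp, " samples) shorter than ", n_vols,
         " volumes at TR ", tr_s, " s")
  }
  idx <- lapply(seq_len(n_vols) - 1, function(v) {
    lo <- floor(v * tr_s * rate_hz) + 1
    hi <- min(floor((v + 1) * tr_s * rate_hz), n_samp)
    lo:hi
  })
  out <- data.frame(tr_index = seq_len(n_vols) - 1L)
  for (bn in names(bands)) {
    per_chan <- apply(eeg, 1, function(ch) {
      filt <- zerophase_butter(ch, rate_hz, bands[[bn]], type = "pass",
                               order = 4)
      vapply(idx, function(i) sqrt(mean(filt[i]^2)), numeric(1))
    })
    out[[bn]] <- rowMeans(per_chan)
  }
  class(out) <- c("vigilance_series", "data.frame")
  out
}

#' EEG vigilance index
#'
#' Per-TR ratio of alpha to theta band amplitude (the primary vigilance
#' index; higher values indicate alert wakefulness, lower values
#' drowsiness), or the alternative alpha/(delta + theta) form.
#'
#' @param series data.frame with `alpha`, `theta` (and `delta` for the
#'   alternative mode) columns.
#' @param mode `"alpha/theta"` or `"alpha/(delta+theta)"`.
#' @return per-TR ratio.
#' @export
vigilance_index <- function(series, mode = c("alpha/theta",
                                             "alpha/(delta+theta)")) {
  mode <- match.arg(mode)
  denom <- if (mode == "alpha/theta") series$theta else
    series$delta + series$theta
  if (any(denom <= 0)) {
    stop("vigilance index undefined: non-positive band power in denominator")
  }
  series$alpha / denom
}

#' Baseline (window-mean) vigilance
#'
#' Mean of the per-TR vigilance index over each analysis window, after
#' advancing the EEG series by `shift_trs` volumes relative to the fMRI
#' grid (default 2 TRs = 4.2 s, approximating the ~5-s hemodynamic peak
#' latency so that windowed EEG state aligns with windowed BOLD
#' consequences). Windows whose shifted span runs past the end of the
#' series are dropped.
#'
#' @param ratio per-TR vigilance index on the retained TR grid.
#' @param windows a `window_set` from [segment_windows()].
#' @param shift_trs non-negative shift in volumes (0 or 2 in practice).
#' @return named numeric vector, one baseline value per retained window;
#'   names are window ids.
#' @export
baseline_vigilance <- function(ratio, windows, shift_trs = 2) {
  if (shift_trs < 0) stop("shift must be non-negative")
  if (shift_trs >= windows$window_len_tr) {
    stop("shift of ", shift_trs, " TRs exceeds the window length")
  }
  n <- length(ratio)
  out <- numeric(0)
  for (i in seq_len(nrow(windows$boundaries))) {
    lo <- windows$boundaries$start_tr[i] + shift_trs
    hi <- windows$boundaries$end_tr[i] + shift_trs   # half-open
    if (hi > n) next                                  # shifted past the tail
    out[as.character(windows$boundaries$window_id[i])] <-
      mean(ratio[(lo + 1):hi])
  }
  out
}

#' Behavioral validation of the vigilance index
#'
#' Correlates window-mean reaction time with baseline vigilance across task
#' windows (Spearman), with a two-tailed permutation test shuffling the
#' vigilance values. Missing RTs (no response within 4 s) are either
#' dropped or imputed at the 4-s ceiling.
#'
#' @param baseline named per-window baseline vigilance (names = window ids).
#' @param events event table with `onset_s`, `rt_s` (NA = missing).
#' @param windows a `window_set`.
#' @param tr_s repetition time (s), to place event onsets on the TR grid.
#' @param missing_policy `"drop"` or `"impute_4s"`.
#' @param B permutation count.
#' @return list: `rho`, `p_perm`, `n_windows`, `mean_rt` per window.
#' @export
validate_vigilance <- function(baseline, events, windows, tr_s,
                               missing_policy = c("drop", "impute_4s"),
                               B = 10000) {
  missing_policy <- match.arg(missing_policy)
  rt <- events$rt_s
  if (missing_policy == "impute_4s") rt[is.na(rt)] <- 4
  onset_tr <- floor(events$onset_s / tr_s)
  mean_rt <- vapply(seq_len(nrow(windows$boundaries)), function(i) {
    inw <- onset_tr >= windows$boundaries$start_tr[i] &
      onset_tr < windows$boundaries$end_tr[i]
    mean(rt[inw], na.rm = TRUE)
  }, numeric(1))
  names(mean_rt) <- as.character(windows$boundaries$window_id)
  common <- intersect(names(baseline), names(mean_rt)[is.finite(mean_rt)])
  if (length(common) < 5) {
    stop("fewer than 5 windows with RT data; cannot validate")
  }
  test <- spearman_perm_test(mean_rt[common], baseline[common], B = B)
  list(rho = test$rho, p_perm = test$p, n_windows = length(common),
       mean_rt = mean_rt)
}
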