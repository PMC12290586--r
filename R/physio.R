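#' Windowed standard deviation around each fMRI volume
#'
#' Population standard deviation of a waveform inside a symmetric window of
#' half-width `half_width_s` centred on each volume acquisition time. This
#' is the amplitude summary used for respiratory volume (on the respiration
#' belt) and pulse wave amplitude (on the PPG).
#'
#' @param signal waveform samples.
#' @param time_s sample times (s), uniform and strictly increasing.
#' @param center_times_s one centre per fMRI volume (s).
#' @param half_width_s window half-width, default 3 s (6-s windows).
#' @return one value per centre.
#' @export
windowed_std <- function(signal, time_s, center_times_s, half_width_s = 3) {
  stopifnot(length(signal) == length(time_s))
  vapply(center_times_s, function(ct) {
    if (ct - half_width_s < time_s[1] - 1e-9 ||
        ct + half_width_s > time_s[length(time_s)] + 1e-9) {
      stop(sprintf("window centred at %.3f s extends past the recording", ct))
    }
    w <- signal[time_s >= ct - half_width_s & time_s <= ct + half_width_s]
    sqrt(mean((w - mean(w))^2))   # population sd: amplitude semantics
  }, numeric(1))
}

#' Detect pulse peaks in a band-pass filtered PPG
#'
#' Local maxima with height at least 5% of the signal's interquartile range
#' and pairwise spacing at least `min_dist_s` (0.55 s, i.e. 109.09 beats per
#' minute). When two candidates fall within the minimum distance the taller
#' one is kept (earlier on ties).
#'
#' @param filtered_ppg band-passed PPG waveform.
#' @param rate_hz sampling rate (Hz).
#' @param min_dist_s minimum peak spacing in seconds.
#' @param height_frac_iqr minimum height as a fraction of the IQR.
#' @return peak times in seconds from the start of the waveform.
#' @export
detect_peaks <- function(filtered_ppg, rate_hz, min_dist_s = 0.55,
                         height_frac_iqr = 0.05) {
  x <- filtered_ppg
  n <- length(x)
  hmin <- height_frac_iqr * stats::IQR(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] >= hmin]
  if (length(cand) == 0) {
    stop("no PPG peaks found (", n, " samples, min height ",
         signif(hmin, 3), "); check signal polarity and scaling")
  }
  # greedy non-maximum suppression: tallest first, earlier index on ties
  ord <- cand[order(-x[cand], cand)]
  min_gap <- min_dist_s * rate_hz
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept - 1) / rate_hz
}

#' Clean an inter-beat-interval series
#'
#' Flags IBIs outside [0.33, 2] s or deviating more than `mad_k` scaled
#' median absolute deviations from a running median, and replaces flagged
#' values by linear interpolation over beat index. Mirrors a visual
#' artifact-rejection pass with an automated, logged rule.
#'
#' @param peak_times_s pulse peak times (s), at least 3.
#' @param mad_k MAD multiplier for the outlier rule.
#' @param bounds_s admissible IBI range in seconds.
#' @param max_fraction maximum tolerated flagged fraction before the signal
#'   is declared unusable.
#' @return list: `ibi_s` cleaned IBIs, `ibi_time_s` midpoint time of each
#'   interval, `interpolated_fraction`.
#' @export
ibi_clean <- function(peak_times_s, mad_k = 3, bounds_s = c(0.33, 2),
                      max_fraction = 0.25) {
  if (length(peak_times_s) < 3) stop("need at least 3 peaks to form IBIs")
  ibi <- diff(peak_times_s)
  mid <- (head(peak_times_s, -1) + tail(peak_times_s, -1)) / 2
  k <- min(11, length(ibi) - (1 - length(ibi) %% 2))  # odd, <= series length
  runmed_ibi <- if (k >= 3) stats::runmed(ibi, k) else rep(median(ibi), length(ibi))
  dev <- abs(ibi - runmed_ibi)
  mad_all <- mad(ibi)
  bad <- ibi < bounds_s[1] | ibi > bounds_s[2] |
    (mad_all > 0 & dev > mad_k * mad_all)
  frac <- mean(bad)
  if (frac > max_fraction) {
    stop(sprintf("%.1f%% of IBIs flagged as artifactual; signal unusable",
                 100 * frac))
  }
  if (any(bad)) {
    if (all(bad)) stop("all IBIs flagged; signal unusable")
    ibi[bad] <- approx(which(!bad), ibi[!bad], xout = which(bad),
                       rule = 2)$y
  }
  list(ibi_s = ibi, ibi_time_s = mid, interpolated_fraction = frac)
}

#' Per-volume heart rate from cleaned IBIs
#'
#' Heart rate for each volume is 60 divided by the median of the IBIs whose
#' midpoints fall inside the 6-s window centred on the volume. A window with
#' no IBIs carries the nearest valid volume's value, with a warning.
#'
#' @param ibi list from [ibi_clean()].
#' @param center_times_s volume acquisition times (s).
#' @param half_width_s window half-width, default 3 s.
#' @return heart rate in beats per minute, one value per volume.
#' @export
hr_per_tr <- function(ibi, center_times_s, half_width_s = 3) {
  hr <- vapply(center_times_s, function(ct) {
    w <- ibi$ibi_s[abs(ibi$ibi_time_s - ct) <= half_width_s]
    if (length(w) == 0) NA_real_ else 60 / median(w)
  }, numeric(1))
  if (anyNA(hr)) {
    if (all(is.na(hr))) stop("no window contains any IBIs")
    warning(sum(is.na(hr)), " window(s) contained no IBIs; carrying nearest value")
    ok <- which(!is.na(hr))
    for (i in which(is.na(hr))) hr[i] <- hr[ok[which.min(abs(ok - i))]]
  }
  hr
}

#' Extract per-volume autonomic features from raw waveforms
#'
#' Full feature pipeline from a raw physiological recording to the
#' TR-sampled autonomic series used in all downstream analyses:
#' \itemize{
#'   \item RV: windowed (6-s) standard deviation of the respiration belt;
#'   \item PWA: windowed standard deviation of the raw PPG;
#'   \item HR: band-pass (0.5-2 Hz) PPG, peak detection, IBI cleaning, then
#'     60 / median IBI per 6-s window;
#' }
#' each followed by a zero-phase 0.15-Hz low-pass on the TR grid.
#'
#' @param physio data.frame with columns `time_s`, `resp`, `ppg`; time zero
#'   is the first retained scanner trigger. The recording must cover
#'   [-3 s, session end + 3 s] so every 6-s window is full.
#' @param rate_hz waveform sampling rate (Hz).
#' @param tr_s repetition time (s).
#' @param n_vols number of volumes on the pre-discard grid.
#' @param lowpass logical; apply the 0.15-Hz low-pass (default TRUE).
#' @return data.frame of class `autonomic_series`: `tr_index` (0-based),
#'   `rv`, `hr`, `pwa`, plus attribute `ibi_interpolated_fraction`.
#' @export
physio_features <- function(physio, rate_hz, tr_s, n_vols, lowpass = TRUE) {
  centers <- (seq_len(n_vols) - 1) * tr_s + tr_s / 2
  rv <- windowed_std(physio$resp, physio$time_s, centers)
  pwa <- windowed_std(physio$ppg, physio$time_s, centers)
  ppg_f <- bandpass_ppg(physio$ppg, rate_hz)
  peaks <- detect_peaks(ppg_f, rate_hz) + physio$time_s[1]
  ibi <- ibi_clean(peaks)
  hr <- hr_per_tr(ibi, centers)
  if (lowpass) {
    fs <- 1 / tr_s
    rv <- lowpass_autonomic(rv, fs)
    pwa <- lowpass_autonomic(pwa, fs)
    hr <- lowpass_autonomic(hr, fs)
  }
  out <- data.frame(tr_index = seq_len(n_vols) - 1L, rv = rv, hr = hr,
                    pwa = pwa)
  attr(out, "ibi_interpolated_fraction") <- ibi$interpolated_fraction
  class(out) <- c("autonomic_series", "data.frame")
  out
}
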