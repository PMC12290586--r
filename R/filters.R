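#' Zero-phase Butterworth filtering
#'
#' Forward-backward application of a Butterworth filter with odd-reflection
#' end padding, so that step/trend edge transients do not leak into the
#' filtered series. All filtering in the package (respiration/PPG
#' conditioning, EEG band isolation, per-window high-pass) goes through this
#' helper, which keeps the phase response identically zero -- important for
#' the lagged cross-correlation analyses, where a causal filter would bias
#' peak lags.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param cutoff_hz scalar (low/high) or length-2 (pass) corner frequency.
#' @param type "low", "high" or "pass".
#' @param order Butterworth order (of the underlying one-pass filter; the
#'   forward-backward application squares the magnitude response).
#' @return filtered series, same length as `x`.
#' @export
zerophase_butter <- function(x, fs, cutoff_hz, type = c("low", "high", "pass"),
                             order = 2) {
  type <- match.arg(type)
  n <- length(x)
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2)) {
    stop("cutoff must lie strictly inside (0, fs/2); got ",
         paste(cutoff_hz, collapse = ", "), " Hz at fs = ", fs, " Hz")
  }
  w <- cutoff_hz / (fs / 2)
  bf <- signal::butter(order, w, type = type)
  if (n < 3 * order + 1) {
    stop("series too short to filter stably: length ", n)
  }
  # demean so the reflected padding carries no step; restore the mean only
  # for the low-pass (DC gain 1) case
  mu <- mean(x)
  x <- x - mu
  # pad long enough for the transient of the narrowest corner to settle
  padlen <- min(n - 1, max(3 * order, ceiling(6 / min(w))))
  xp <- c(2 * x[1] - x[(padlen + 1):2], x,
          2 * x[n] - x[(n - 1):(n - padlen)])
  yp <- signal::filter(bf, xp)
  yp <- rev(signal::filter(bf, rev(yp)))
  out <- yp[(padlen + 1):(padlen + n)]
  if (type == "low") out <- out + mu
  out
}

#' Low-pass filter for per-volume autonomic series
#'
#' Smooths the RV/HR/PWA series sampled on the TR grid with a zero-phase
#' Butterworth low-pass with a 0.15 Hz passband edge, removing residual
#' beat-to-beat and breath-to-breath jitter while preserving the slow
#' autonomic fluctuations of interest.
#'
#' @param series numeric series on the TR grid (or any uniform grid).
#' @param fs sampling rate in Hz (1/TR for per-volume series).
#' @param cutoff_hz passband edge, default 0.15 Hz.
#' @return filtered series; DC gain is 1.
#' @export
lowpass_autonomic <- function(series, fs, cutoff_hz = 0.15) {
  stopifnot(all(is.finite(series)))
  zerophase_butter(series, fs, cutoff_hz, type = "low", order = 4)
}

#' Band-pass filter for PPG pulse detection
#'
#' 2nd-order zero-phase Butterworth band-pass from 0.5 to 2 Hz, isolating the
#' cardiac pulse component of the photoplethysmogram before peak detection.
#'
#' @param ppg raw PPG waveform.
#' @param rate_hz waveform sampling rate; must exceed 4 Hz so the 2 Hz upper
#'   corner is resolvable.
#' @return filtered waveform.
#' @export
bandpass_ppg <- function(ppg, rate_hz) {
  if (rate_hz <= 4) stop("PPG sampling rate must exceed 4 Hz, got ", rate_hz)
  zerophase_butter(ppg, rate_hz, c(0.5, 2), type = "pass", order = 2)
}

#' High-pass filter matched to the sliding-window length
#'
#' Removes fluctuations slower than one window length before windowed
#' variance, regression, cross-correlation and connectivity analyses, so that
#' between-window offsets cannot masquerade as within-window (co)variance.
#' The cutoff is 1/window-length (e.g. 1/126 Hz for 60-TR windows at
#' TR = 2.1 s).
#'
#' @param series numeric series on the TR grid.
#' @param fs sampling rate in Hz (1/TR).
#' @param window_len_s analysis window length in seconds.
#' @return filtered series with DC removed.
#' @export
highpass_for_windows <- function(series, fs, window_len_s) {
  zerophase_butter(series, fs, 1 / window_len_s, type = "high", order = 2)
}
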