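#' Segment a session into non-overlapping analysis windows
#'
#' Tiles the retained TR grid into consecutive, disjoint windows of
#' `window_len_tr` volumes (60 TRs = 126 s and 115 TRs = 241.5 s are the two
#' standard lengths); an incomplete tail is discarded. Indexing is 0-based
#' and half-open.
#'
#' @param n_tr number of retained volumes.
#' @param window_len_tr window length in volumes.
#' @param condition optional condition label attached to every window.
#' @param session optional session id prefixed to window ids, so windows
#'   pooled across sessions keep distinct names.
#' @return object of class `window_set`: list with `window_len_tr` and
#'   `boundaries` (data.frame: `window_id`, `start_tr`, `end_tr`,
#'   `condition`).
#' @export
segment_windows <- function(n_tr, window_len_tr, condition = NA_character_,
                            session = NULL) {
  if (n_tr < window_len_tr) {
    stop("session of ", n_tr, " TRs shorter than one window (",
         window_len_tr, " TRs)")
  }
  k <- floor(n_tr / window_len_tr)
  start <- (seq_len(k) - 1) * window_len_tr
  ids <- if (is.null(session)) as.character(seq_len(k)) else
    paste0(session, "_", seq_len(k))
  structure(list(window_len_tr = window_len_tr,
                 boundaries = data.frame(window_id = ids, start_tr = start,
                                         end_tr = start + window_len_tr,
                                         condition = condition)),
            class = "window_set")
}

# rows of `series` (or elements of a vector) belonging to window i
window_slice <- function(windows, i) {
  (windows$boundaries$start_tr[i] + 1):windows$boundaries$end_tr[i]
}

#' Per-window sample variance
#'
#' @param series high-pass filtered series on the retained TR grid.
#' @param windows a `window_set`.
#' @return named vector of sample variances (denominator n - 1), one per
#'   window.
#' @export
window_variance <- function(series, windows) {
  v <- vapply(seq_len(nrow(windows$boundaries)),
              function(i) var(series[window_slice(windows, i)]), numeric(1))
  names(v) <- as.character(windows$boundaries$window_id)
  v
}

#' Stage windows into pooled vigilance tertiles
#'
#' Splits the pooled distribution of baseline vigilance values (across all
#' sessions of a condition) at its empirical 33.3% and 66.7% quantiles
#' (linear interpolation). Windows at or below the lower cut are staged
#' "low", at or above the upper cut "high", and "mid" otherwise, so ties at
#' a cut point fall into the extreme stage.
#'
#' @param baseline_values pooled per-window baseline vigilance.
#' @return list: `stage` (factor low/mid/high, same order and names as the
#'   input) and `cuts` (the two quantiles).
#' @export
stage_tertiles <- function(baseline_values) {
  if (length(baseline_values) < 3) stop("need at least 3 windows to stage")
  if (diff(range(baseline_values)) == 0) {
    stop("all baseline vigilance values identical; tertiles undefined")
  }
  cuts <- quantile(baseline_values, c(1, 2) / 3, names = FALSE, type = 7)
  stage <- ifelse(baseline_values <= cuts[1], "low",
                  ifelse(baseline_values >= cuts[2], "high", "mid"))
  stage <- factor(stage, levels = c("low", "mid", "high"))
  names(stage) <- names(baseline_values)
  list(stage = stage, cuts = cuts)
}
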