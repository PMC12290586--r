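#' Normalized lagged cross-correlation
#'
#' Cross-correlation between an fMRI window and a physiological or EEG
#' window over a grid of integer TR lags, normalized so that the zero-lag
#' autocorrelation of any series with itself is exactly 1:
#' \deqn{r(\ell) = \frac{\sum_t (x_{t+\ell} - \bar x)(y_t - \bar y)}
#'   {\sqrt{\sum_t (x_t - \bar x)^2 \sum_t (y_t - \bar y)^2}},}
#' with full-window means and sums but overlap-only products, so the
#' attainable magnitude shrinks toward the extreme lags. Positive lags mean
#' the second series leads the first (for `xcov_normalized(fmri, autonomic)`,
#' positive lags have the autonomic signal preceding its fMRI correlate, the
#' physiologically expected direction).
#'
#' @param x first series (fMRI), high-passed, one window.
#' @param y second series (autonomic or EEG), same length.
#' @param lags_tr integer lag grid in TR units; default -5 to 15
#'   (-10.5 s to +31.5 s at TR = 2.1 s).
#' @return data.frame: `lag_tr`, `r`.
#' @export
xcov_normalized <- function(x, y, lags_tr = -5:15) {
  n <- length(x)
  stopifnot(length(y) == n)
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) stop("zero-variance input: cross-correlation undefined")
  r <- vapply(lags_tr, function(l) {
    if (l >= 0) {
      idx <- seq_len(n - l)
      sum(xc[idx + l] * yc[idx])
    } else {
      idx <- seq_len(n + l)
      sum(xc[idx] * yc[idx - l])
    }
  }, numeric(1)) / den
  data.frame(lag_tr = lags_tr, r = r)
}

#' Stage-averaged cross-correlations
#'
#' Averages per-window cross-correlation curves within each pooled
#' vigilance tertile stage, returning the mean and standard error of the
#' mean per lag.
#'
#' @param xcorrs list of data.frames from [xcov_normalized()], one per
#'   window (all on the same lag grid), named by window id.
#' @param stages factor of stage labels (low/mid/high) named by window id,
#'   from [stage_tertiles()].
#' @return data.frame: `stage`, `lag_tr`, `mean_r`, `sem_r`, `n_windows`.
#' @export
staged_average <- function(xcorrs, stages) {
  ids <- intersect(names(xcorrs), names(stages))
  if (length(ids) == 0) stop("no windows shared between curves and stages")
  out <- list()
  for (st in levels(stages)) {
    in_stage <- ids[stages[ids] == st]
    if (length(in_stage) == 0) {
      stop("stage '", st, "' contains no windows")
    }
    R <- sapply(in_stage, function(id) xcorrs[[id]]$r)
    R <- matrix(R, ncol = length(in_stage))
    out[[st]] <- data.frame(stage = st, lag_tr = xcorrs[[in_stage[1]]]$lag_tr,
                            mean_r = rowMeans(R),
                            sem_r = apply(R, 1, sd) / sqrt(ncol(R)),
                            n_windows = ncol(R))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average fMRI series within tissue compartments
#'
#' Unweighted per-TR mean over the voxels of each mask (grey matter, white
#' matter, ventricles, or any labeled compartment).
#'
#' @param fmri matrix, TR by voxel.
#' @param masks named list of logical or integer voxel selectors.
#' @return matrix, TR by compartment.
#' @export
tissue_average <- function(fmri, masks) {
  fmri <- as.matrix(fmri)
  out <- sapply(names(masks), function(nm) {
    sel <- masks[[nm]]
    if ((is.logical(sel) && !any(sel)) || length(sel) == 0) {
      stop("mask '", nm, "' selects no voxels")
    }
    rowMeans(fmri[, sel, drop = FALSE])
  })
  matrix(out, nrow = nrow(fmri), dimnames = list(NULL, names(masks)))
}
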