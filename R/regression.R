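#' Variance explained within one window
#'
#' Ordinary least squares of an fMRI window on a regressor group, returning
#' the coefficient of determination as a percentage of signal variance.
#' Design columns are (re-)z-scored within the window; stimulus nuisance
#' columns, when supplied, are removed from the target first
#' (Frisch-Waugh residualization) so the reported percentage reflects the
#' group of interest only. Rank-deficient designs drop dependent columns
#' with a warning.
#'
#' @param y fMRI series within one window.
#' @param X regressor matrix for the group of interest (same rows as `y`).
#' @param nuisance optional matrix of regressors of no interest removed from
#'   `y` before the fit.
#' @param adjust logical; also return the adjusted percentage
#'   `100 * max(0, 1 - (1 - R2) (n - 1) / (n - p - 1))`, used when groups of
#'   different size are compared.
#' @return list: `r2_pct`, `r2_adj_pct` (NA unless `adjust`),
#'   `n_regressors`, `n`.
#' @export
window_r2 <- function(y, X, nuisance = NULL, adjust = FALSE) {
  X <- as.matrix(X)
  n <- length(y)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    y <- ols_residuals(y, nuisance)
  }
  X <- zscore_columns(X, drop_constant = TRUE)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    keep_aug <- qx$pivot[seq_len(qx$rank)]
    keep <- sort(keep_aug[keep_aug > 1] - 1)
    warning("rank-deficient design: dropping ", ncol(X) - length(keep),
            " dependent column(s)")
    X <- X[, keep, drop = FALSE]
    qx <- qr(cbind(1, X))
  }
  p <- ncol(X)
  if (n <= p + 2) {
    stop("window of ", n, " samples too short for ", p, " regressors")
  }
  res <- qr.resid(qx, y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant fMRI window: R^2 undefined")
  r2 <- 1 - sum(res^2) / sst
  r2_adj <- NA_real_
  if (adjust) {
    r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    if (r2_adj < 0) {
      message("adjusted R^2 below zero (", signif(r2_adj, 3), "); floored at 0")
      r2_adj <- 0
    }
  }
  list(r2_pct = 100 * r2, r2_adj_pct = 100 * r2_adj, n_regressors = p, n = n)
}

# OLS residuals of y (vector or matrix) on X plus an intercept
ols_residuals <- function(y, X) {
  qr.resid(qr(cbind(1, as.matrix(X))), y)
}

#' Windowed variance explained across a session
#'
#' Applies [window_r2()] to every window of a session: the fMRI series and
#' each design column are sliced by window, columns re-z-scored within the
#' window, and the percentage of variance explained by the requested group
#' computed with or without stimulus covariates as nuisance.
#'
#' @param fmri fMRI series on the retained TR grid (already high-passed).
#' @param design a `design_matrix` from [build_design()] (rows on the same
#'   grid).
#' @param windows a `window_set`.
#' @param group name of the design group to evaluate (e.g. "autonomic",
#'   "rv", "fast_eeg").
#' @param model_stimuli logical; when TRUE and the design has a stimulus
#'   group, those columns are removed from the target first.
#' @param adjust passed to [window_r2()].
#' @return data.frame: `window_id`, `r2_pct`, `r2_adj_pct`.
#' @export
windowed_r2 <- function(fmri, design, windows, group = "autonomic",
                        model_stimuli = FALSE, adjust = FALSE) {
  cols <- design$groups[[group]]
  if (is.null(cols)) stop("design has no group '", group, "'")
  stim <- if (model_stimuli && !is.null(design$groups$stimulus)) {
    design$groups$stimulus
  } else NULL
  out <- lapply(seq_len(nrow(windows$boundaries)), function(i) {
    sl <- window_slice(windows, i)
    nu <- if (is.null(stim)) NULL else design$columns[sl, stim, drop = FALSE]
    fit <- window_r2(fmri[sl], design$columns[sl, cols, drop = FALSE],
                     nuisance = nu, adjust = adjust)
    data.frame(window_id = windows$boundaries$window_id[i],
               r2_pct = fit$r2_pct, r2_adj_pct = fit$r2_adj_pct)
  })
  do.call(rbind, out)
}

#' Association between windowed variance explained and baseline vigilance
#'
#' Spearman correlation between per-window R-squared values and the
#' (shifted) baseline vigilance of the same windows, pooled across sessions,
#' with a two-tailed permutation test shuffling the vigilance values.
#'
#' @param r2 data.frame from [windowed_r2()] (or any data.frame with
#'   `window_id` and a value column named by `value_col`), possibly row-bound
#'   across sessions.
#' @param baseline named per-window baseline vigilance (pooled).
#' @param B number of permutations (default 10000).
#' @param value_col which column of `r2` to correlate.
#' @return list: `rho`, `p_perm`, `n_windows`.
#' @export
vigilance_association <- function(r2, baseline, B = 10000,
                                  value_col = "r2_pct") {
  common <- intersect(as.character(r2$window_id), names(baseline))
  if (length(common) < 6) {
    stop("need at least 6 matched windows, got ", length(common))
  }
  v <- setNames(r2[[value_col]], as.character(r2$window_id))[common]
  test <- spearman_perm_test(v, baseline[common], B = B)
  list(rho = test$rho, p_perm = test$p, n_windows = length(common))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control across a family of permutation
#' p-values: flags every p at or below the largest p_(k) with
#' p_(k) <= k q / m.
#'
#' @param p_values finite p-values.
#' @param q target false discovery rate (default 0.05).
#' @return logical flags, same order as the input.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(is.finite(p_values)))
  p.adjust(p_values, method = "BH") <= q
}

#' Bootstrap confidence interval for a vigilance association
#'
#' Percentile 95% interval of the Spearman correlation under resampling of
#' the paired windows with replacement. Degenerate resamples in which either
#' variable is constant are redrawn (and counted).
#'
#' @param values per-window statistic (e.g. R-squared percentages).
#' @param baseline matching baseline vigilance values.
#' @param B bootstrap draws (default 2000).
#' @param conf confidence level.
#' @return list: `ci` (length 2), `rho` (point estimate), `n_redrawn`.
#' @export
bootstrap_ci <- function(values, baseline, B = 2000, conf = 0.95) {
  stopifnot(length(values) == length(baseline))
  n <- length(values)
  rho_b <- numeric(B)
  redrawn <- 0
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (sd(rank(values[idx])) > 0 && sd(rank(baseline[idx])) > 0) break
      redrawn <- redrawn + 1
    }
    rho_b[b] <- spearman_rho(values[idx], baseline[idx])
  }
  a <- (1 - conf) / 2
  list(ci = quantile(rho_b, c(a, 1 - a), names = FALSE),
       rho = spearman_rho(values, baseline), n_redrawn = redrawn)
}

#' Partial one regressor group out of another
#'
#' Replaces each column of the target group by its OLS residual on the full
#' nuisance group (plus intercept) and re-z-scores, isolating the target's
#' unique variance. Columns whose residual is numerically zero (the column
#' lay in the nuisance span) are dropped with a warning.
#'
#' @param target matrix of regressors to residualize.
#' @param nuisance matrix of regressors to remove.
#' @return residualized, z-scored matrix (possibly fewer columns).
#' @export
partial_out <- function(target, nuisance) {
  target <- as.matrix(target); nuisance <- as.matrix(nuisance)
  if (ncol(nuisance) + 1 >= nrow(target)) {
    stop("nuisance rank reaches the window length; residuals undefined")
  }
  res <- ols_residuals(target, nuisance)
  zscore_columns(res, drop_constant = TRUE)
}

#' Stimulus-autonomic collinearity check
#'
#' Per-window variance of an HRF-convolved all-stimuli regressor explained
#' by the autonomic group, summarizing how much task structure the autonomic
#' signals absorb.
#'
#' @param stimulus_column convolved all-stimuli regressor on the retained
#'   TR grid.
#' @param design a `design_matrix` with an `autonomic` group.
#' @param windows a `window_set`.
#' @return list: `per_window` (R-squared %), `mean`, `sd`.
#' @export
collinearity_check <- function(stimulus_column, design, windows) {
  r2 <- windowed_r2(stimulus_column, design, windows, group = "autonomic")
  list(per_window = r2$r2_pct, mean = mean(r2$r2_pct), sd = sd(r2$r2_pct))
}

#' Remove the autonomic design from fMRI series
#'
#' OLS-residualizes each fMRI series (column) on the convolved, z-scored
#' autonomic regressors, per window, leaving the signal used for
#' autonomic-partialled functional connectivity.
#'
#' @param fmri matrix of fMRI series (TR by region) on the retained grid,
#'   or a single series.
#' @param design a `design_matrix`.
#' @param windows a `window_set`; residualization is done within each
#'   window.
#' @param group design group to remove (default "autonomic").
#' @return residualized series, same shape as `fmri`; TRs outside complete
#'   windows are returned unchanged.
#' @export
remove_autonomic_from_fmri <- function(fmri, design, windows,
                                       group = "autonomic") {
  fmri <- as.matrix(fmri)
  out <- fmri
  cols <- design$groups[[group]]
  for (i in seq_len(nrow(windows$boundaries))) {
    sl <- window_slice(windows, i)
    X <- zscore_columns(design$columns[sl, cols, drop = FALSE],
                        drop_constant = TRUE)
    out[sl, ] <- ols_residuals(fmri[sl, , drop = FALSE], X)
  }
  out
}
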