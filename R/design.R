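#' Convolve a TR-sampled series with a kernel basis
#'
#' Causal discrete convolution on the TR grid: column j of the result is
#' `sum_k basis[k, j] * x[t - k]`, truncated to the length of `x`. With an
#' impulse input the columns reproduce the kernels themselves.
#'
#' @param x series on the TR grid.
#' @param basis a `kernel_basis` (or a numeric matrix of kernel columns).
#' @return matrix with `length(x)` rows, one column per basis kernel.
#' @export
convolve_basis <- function(x, basis) {
  K <- if (inherits(basis, "kernel_basis")) basis$kernels else as.matrix(basis)
  n <- length(x)
  out <- matrix(0, n, ncol(K))
  for (j in seq_len(ncol(K))) {
    k <- K[, j]
    # open convolution, keep first n samples (causal FIR)
    out[, j] <- convolve(x, rev(k), type = "open")[seq_len(n)]
  }
  colnames(out) <- colnames(K)
  out
}

#' Stimulus covariates from an event table
#'
#' Builds the task nuisance regressors: stimuli are split by whether a
#' response followed, each class becomes a binary on/off train on a 1-Hz
#' grid covering the scan, each train is convolved with the canonical
#' double-gamma basis (HRF + temporal + dispersion derivative) sampled at
#' 1 Hz, and the convolved series are linearly resampled onto the TR grid
#' before the initial `n_discard` volumes are dropped. With both classes
#' present this yields 6 columns; a class with no events is omitted with a
#' message.
#'
#' @param events data.frame with columns `onset_s` and `rt_s` (NA = no
#'   response within 4 s).
#' @param tr_s repetition time in seconds.
#' @param n_tr number of volumes acquired (pre-discard).
#' @param n_discard leading volumes to drop (default 7).
#' @return matrix with `n_tr - n_discard` rows and up to 6 columns.
#' @export
stimulus_covariates <- function(events, tr_s, n_tr, n_discard = 7) {
  dur_s <- n_tr * tr_s
  if (nrow(events) == 0) {
    return(matrix(0, n_tr - n_discard, 0))
  }
  responded <- !is.na(events$rt_s)
  grid_1hz <- seq(0, ceiling(dur_s) + 33, by = 1)
  basis_1hz <- add_derivatives(hrf_kernel(1), n_temporal = 1, n_dispersion = 1)
  t_tr <- (seq_len(n_tr) - 1) * tr_s
  cols <- list()
  for (class in c("responded", "unresponded")) {
    keep <- if (class == "responded") responded else !responded
    if (!any(keep)) {
      message("no ", class, " stimuli; omitting its covariate columns")
      next
    }
    train <- numeric(length(grid_1hz))
    idx <- pmin(floor(events$onset_s[keep]) + 1, length(grid_1hz))
    train[idx] <- 1
    conv <- convolve_basis(train, basis_1hz)
    resampled <- apply(conv, 2, function(y) {
      approx(grid_1hz, y, xout = t_tr, rule = 2)$y
    })
    colnames(resampled) <- paste0("stim_", class, "_", colnames(conv))
    cols <- c(cols, list(resampled))
  }
  out <- do.call(cbind, cols)
  out[-seq_len(n_discard), , drop = FALSE]
}

#' Assemble the convolved, z-scored design matrix
#'
#' Builds the regressor groups for the windowed variance-explained analyses:
#' \itemize{
#'   \item RV convolved with the respiratory response function plus two
#'     temporal and two dispersion derivatives (5 columns);
#'   \item HR convolved with the cardiac response function basis (5 columns);
#'   \item PWA advanced by `pwa_shift_tr` volumes (default 2, i.e. 4.2 s, to
#'     absorb the pulse-amplitude-to-BOLD latency) and convolved with the
#'     canonical HRF basis (3 columns) -- 13 autonomic columns in total;
#'   \item optionally, per-TR EEG alpha, delta and theta band power each
#'     convolved with the canonical HRF basis (9 "fast EEG" columns);
#'   \item optionally, 6 stimulus covariate columns from
#'     [stimulus_covariates()].
#' }
#' Convolution uses the full pre-discard series so lagged responses to early
#' events bleed correctly into the first analysis window; the first
#' `n_discard` volumes are dropped afterwards and every column is z-scored
#' over the retained span.
#'
#' @param autonomic data.frame with columns `rv`, `hr`, `pwa` on the full
#'   pre-discard TR grid.
#' @param tr_s repetition time (s).
#' @param fast_eeg optional data.frame with columns `alpha`, `delta`,
#'   `theta` on the same grid.
#' @param events optional event table for stimulus covariates.
#' @param n_discard leading volumes to drop (default 7).
#' @param pwa_shift_tr forward shift of the PWA series in volumes.
#' @return list of class `design_matrix`: `columns` (z-scored matrix on the
#'   retained TR grid), `groups` (named list of column indices), `tr_s`,
#'   `z_scored = TRUE`.
#' @export
build_design <- function(autonomic, tr_s, fast_eeg = NULL, events = NULL,
                         n_discard = 7, pwa_shift_tr = 2) {
  n_tr <- nrow(autonomic)
  if (n_tr <= n_discard + 16) {
    stop("autonomic series must cover the pre-discard span: got ", n_tr,
         " volumes")
  }
  rrf_b <- add_derivatives(rrf_kernel(tr_s), 2, 2)
  crf_b <- add_derivatives(crf_kernel(tr_s), 2, 2)
  hrf_b <- add_derivatives(hrf_kernel(tr_s), 1, 1)

  pwa_adv <- c(autonomic$pwa[-seq_len(pwa_shift_tr)],
               rep(autonomic$pwa[n_tr], pwa_shift_tr))
  X <- cbind(convolve_basis(autonomic$rv, rrf_b),
             convolve_basis(autonomic$hr, crf_b),
             convolve_basis(pwa_adv, hrf_b))
  colnames(X) <- c(paste0("rv_", colnames(rrf_b$kernels)),
                   paste0("hr_", colnames(crf_b$kernels)),
                   paste0("pwa_", colnames(hrf_b$kernels)))
  groups <- list(autonomic = seq_len(13),
                 rv = 1:5, hr = 6:10, pwa = 11:13)

  if (!is.null(fast_eeg)) {
    E <- cbind(convolve_basis(fast_eeg$alpha, hrf_b),
               convolve_basis(fast_eeg$delta, hrf_b),
               convolve_basis(fast_eeg$theta, hrf_b))
    colnames(E) <- c(paste0("alpha_", colnames(hrf_b$kernels)),
                     paste0("delta_", colnames(hrf_b$kernels)),
                     paste0("theta_", colnames(hrf_b$kernels)))
    groups$fast_eeg <- ncol(X) + seq_len(ncol(E))
    X <- cbind(X, E)
  }

  X <- X[-seq_len(n_discard), , drop = FALSE]

  if (!is.null(events)) {
    S <- stimulus_covariates(events, tr_s, n_tr, n_discard)
    if (ncol(S) > 0) {
      groups$stimulus <- ncol(X) + seq_len(ncol(S))
      X <- cbind(X, S)
    }
  }

  structure(list(columns = zscore_columns(X), groups = groups, tr_s = tr_s,
                 z_scored = TRUE),
            class = "design_matrix")
}

#' High-pass filter a design matrix for windowed analysis
#'
#' Applies the same zero-phase 1/window-length high-pass used on the fMRI
#' series to every design column, then re-z-scores, so the windowed
#' regressions compare like with like (both sides filtered identically).
#'
#' @param design a `design_matrix`.
#' @param window_len_s analysis window length in seconds.
#' @return the design with filtered, re-z-scored columns.
#' @export
highpass_design <- function(design, window_len_s) {
  fs <- 1 / design$tr_s
  design$columns <- zscore_columns(
    apply(design$columns, 2, highpass_for_windows, fs = fs,
          window_len_s = window_len_s))
  design
}
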