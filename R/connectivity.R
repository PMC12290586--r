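#' Windowed functional connectivity
#'
#' Pairwise Pearson correlations between network-mean fMRI series within one
#' window, Fisher z-transformed. Correlations numerically at +/-1 raise an
#' error rather than being clipped, since an infinite z would silently
#' corrupt downstream permutation nulls.
#'
#' @param roi_series matrix, TR (one window) by network.
#' @return symmetric matrix of Fisher z values with NA diagonal.
#' @export
window_fc <- function(roi_series) {
  roi_series <- as.matrix(roi_series)
  if (any(apply(roi_series, 2, sd) == 0)) {
    stop("constant network series in window: correlation undefined")
  }
  r <- cor(roi_series)
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12)) {
    stop("network pair perfectly correlated within window: Fisher z infinite")
  }
  z <- atanh(r)
  diag(z) <- NA
  z
}

#' Vectorize the lower triangle of an FC matrix
#'
#' Fixed row-major lower-triangle ordering; 8 networks give
#' choose(8, 2) = 28 pairs.
#'
#' @param z_matrix symmetric FC matrix.
#' @return named vector of length `choose(n, 2)`.
#' @export
fc_vectorize <- function(z_matrix) {
  nets <- colnames(z_matrix)
  if (is.null(nets)) nets <- paste0("net", seq_len(ncol(z_matrix)))
  idx <- which(lower.tri(z_matrix), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  setNames(z_matrix[idx],
           paste0(nets[idx[, "row"]], "-", nets[idx[, "col"]]))
}

#' FC computed for every window of a session
#'
#' @param roi_series matrix, TR by network, on the retained grid (already
#'   high-passed, and nuisance-removed if requested upstream).
#' @param windows a `window_set`.
#' @return matrix, window by pair, of Fisher z values; rownames are window
#'   ids.
#' @export
windowed_fc <- function(roi_series, windows) {
  rows <- lapply(seq_len(nrow(windows$boundaries)), function(i) {
    fc_vectorize(window_fc(roi_series[window_slice(windows, i), ,
                                      drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- as.character(windows$boundaries$window_id)
  out
}

#' Association between windowed FC and baseline vigilance
#'
#' For each network pair, the Spearman correlation between Fisher-z FC and
#' (shifted) baseline vigilance across pooled windows, with permutation
#' p-values and Benjamini-Hochberg flags across the pairs.
#'
#' @param fc_windows matrix from [windowed_fc()] (possibly row-bound across
#'   sessions; rownames are window ids).
#' @param baseline named pooled baseline vigilance.
#' @param B permutations per pair.
#' @param q false discovery rate for the flags.
#' @return data.frame: `pair`, `rho`, `p_perm`, `fdr_flag`.
#' @export
fc_vigilance_association <- function(fc_windows, baseline, B = 10000,
                                     q = 0.05) {
  common <- intersect(rownames(fc_windows), names(baseline))
  if (length(common) < 6) stop("need at least 6 matched windows")
  v <- baseline[common]
  res <- lapply(colnames(fc_windows), function(pair) {
    test <- spearman_perm_test(fc_windows[common, pair], v, B = B)
    data.frame(pair = pair, rho = test$rho, p_perm = test$p)
  })
  res <- do.call(rbind, res)
  res$fdr_flag <- bh_fdr(res$p_perm, q = q)
  res
}

#' Similarity between two FC patterns
#'
#' Pearson correlation between two 28-element FC vectors (e.g. the
#' vigilance-association patterns of rest vs task, or with vs without
#' autonomic removal), with a two-tailed permutation test shuffling one
#' vector's entries.
#'
#' @param pattern_a,pattern_b numeric vectors of equal length with matching
#'   pair ordering.
#' @param B permutations.
#' @return list: `r`, `p_perm`.
#' @export
pattern_similarity <- function(pattern_a, pattern_b, B = 10000) {
  if (length(pattern_a) != length(pattern_b)) {
    stop("pattern lengths differ: ", length(pattern_a), " vs ",
         length(pattern_b))
  }
  r <- cor(pattern_a, pattern_b)
  r_b <- vapply(seq_len(B), function(b) {
    cor(pattern_a, pattern_b[sample.int(length(pattern_b))])
  }, numeric(1))
  p <- (1 + sum(abs(r_b) >= abs(r) - 1e-12)) / (1 + B)
  list(r = r, p_perm = p)
}
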