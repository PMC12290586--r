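#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor dgamma mad median quantile rnorm runif sd var
#'   p.adjust lm.fit setNames
#' @importFrom utils head tail read.delim write.table
NULL

# Column-wise z-scoring. Constant columns are an error unless `drop_constant`,
# in which case they are removed with a warning.
zscore_columns <- function(X, drop_constant = FALSE, tol = 1e-12) {
  X <- as.matrix(X)
  s <- apply(X, 2, sd)
  bad <- !is.finite(s) | s < tol
  if (any(bad)) {
    if (!drop_constant) {
      stop("cannot z-score constant column(s): ",
           paste(colnames(X)[bad], collapse = ", "))
    }
    warning("dropping constant column(s): ", paste(colnames(X)[bad], collapse = ", "))
    X <- X[, !bad, drop = FALSE]
    s <- s[!bad]
  }
  sweep(sweep(X, 2, colMeans(X), "-"), 2, s, "/")
}

zscore_vec <- function(x, tol = 1e-12) {
  s <- sd(x)
  if (!is.finite(s) || s < tol) stop("cannot z-score a constant series")
  (x - mean(x)) / s
}

# Spearman rho with average ranks; errors when either input is constant in rank.
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("Spearman correlation undefined: all values tied in one variable")
  }
  cor(rx, ry)
}

# Two-tailed permutation p-value for a Spearman correlation, shuffling `y`.
# Uses the add-one estimator p = (1 + #{|rho_b| >= |rho|}) / (1 + B) so the
# p-value is never exactly zero and is unbiased under the null.
spearman_perm_test <- function(x, y, B = 10000) {
  rho <- spearman_rho(x, y)
  rx <- scale(rank(x))[, 1]
  ry <- rank(y)
  n <- length(ry)
  perm <- matrix(0, n, B)
  for (b in seq_len(B)) perm[, b] <- ry[sample.int(n)]
  perm <- scale(perm)              # columns: centered/unit-sd permuted ranks
  rho_b <- as.vector(crossprod(perm, rx)) / (n - 1)
  p <- (1 + sum(abs(rho_b) >= abs(rho) - 1e-12)) / (1 + B)
  list(rho = rho, p = p, n = n)
}
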