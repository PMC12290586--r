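# brute-force normal-equations oracle for R^2 (intercept included)
oracle_r2 <- function(y, X) {
  X <- scale(X)
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  res <- y - A %*% beta
  100 * (1 - sum(res^2) / sum((y - mean(y))^2))
}

test_that("window R^2 handles exact fits, orthogonal targets, and matches the oracle", {
  set.seed(10)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4)
  y_exact <- drop(scale(X[, 2]))
  expect_equal(window_r2(y_exact, X)$r2_pct, 100, tolerance = 1e-9)

  # target orthogonalized against the design and intercept -> 0%
  y <- rnorm(n)
  y_orth <- drop(qr.resid(qr(cbind(1, X)), y))
  expect_lt(window_r2(y_orth, X)$r2_pct, 1e-8)

  # oracle equivalence on 100 random windows
  for (i in 1:100) {
    Xi <- matrix(rnorm(n * 13), n, 13)
    yi <- rnorm(n)
    expect_equal(window_r2(yi, Xi)$r2_pct, oracle_r2(yi, Xi),
                 tolerance = 1e-8)
  }
})

test_that("null R^2 matches its sampling expectation and adjustment removes it", {
  set.seed(11)
  n <- 60; p <- 5
  draws <- replicate(1000, {
    fit <- window_r2(rnorm(n), matrix(rnorm(n * p), n, p), adjust = TRUE)
    c(fit$r2_pct, fit$r2_adj_pct)
  })
  expect_equal(mean(draws[1, ]), 100 * p / (n - 1), tolerance = 1)
  # adjusted values are floored at 0, so the mean sits slightly above 0
  expect_lt(mean(draws[2, ]), 5)
})

test_that("rank-deficient designs drop dependent columns", {
  set.seed(12)
  X <- matrix(rnorm(120), 60, 2)
  X3 <- cbind(X, X[, 1] + X[, 2])
  expect_warning(fit <- window_r2(rnorm(60), X3), "rank-deficient")
  expect_equal(fit$n_regressors, 2)
  expect_error(window_r2(rnorm(10), matrix(rnorm(10 * 9), 10, 9)),
               "too short")
})

test_that("stimulus residualization removes nuisance variance from the target", {
  set.seed(13)
  n <- 60
  stim <- matrix(rnorm(n * 2), n, 2)
  X <- matrix(rnorm(n * 3), n, 3)
  y <- 2 * stim[, 1] + drop(scale(X[, 1])) + rnorm(n, sd = 0.1)
  with_stim <- window_r2(y, X, nuisance = stim)
  without <- window_r2(y, X)
  # after removing the stimulus component the design explains a larger share
  expect_gt(with_stim$r2_pct, without$r2_pct)
})

test_that("vigilance association is a rank statistic with permutation inference", {
  r2 <- data.frame(window_id = as.character(1:12),
                   r2_pct = seq(60, 5, length.out = 12))
  b <- setNames(1:12, as.character(1:12))
  set.seed(14)
  res <- vigilance_association(r2, b, B = 1000)
  expect_equal(res$rho, -1)
  expect_equal(res$p_perm, 1 / 1001, tolerance = 1e-9)
  # invariance under monotone transforms of either variable
  set.seed(14)
  res2 <- vigilance_association(transform(r2, r2_pct = exp(r2_pct / 10)),
                                log(b), B = 1000)
  expect_equal(res2$rho, res$rho)
  expect_error(vigilance_association(r2[1:5, ], b, B = 10), "at least 6")
})

test_that("BH flags match an exhaustive threshold oracle", {
  oracle_bh <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    k_star <- 0
    for (k in seq_len(m)) if (ps[k] <= k * q / m) k_star <- k
    flags <- logical(m)
    if (k_star > 0) flags <- p <= ps[k_star]
    flags
  }
  expect_equal(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_equal(bh_fdr(c(0.001, 0.011, 0.02, 0.8)),
               c(TRUE, TRUE, TRUE, FALSE))
  set.seed(15)
  for (i in 1:1000) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p), oracle_bh(p, 0.05))
  }
})

test_that("bootstrap interval behaves on degenerate and regular input", {
  set.seed(16)
  x <- 1:15
  res <- bootstrap_ci(x, x + 0.0, B = 200)
  expect_equal(unname(res$ci), c(1, 1))     # perfectly monotone data
  y <- rnorm(15)
  res2 <- bootstrap_ci(x, x + y, B = 500)
  expect_true(res2$ci[1] <= res2$rho && res2$rho <= res2$ci[2])
})

test_that("partialling leaves residuals orthogonal to the nuisance set", {
  set.seed(17)
  n <- 60
  nuis <- matrix(rnorm(n * 3), n, 3)
  targ <- matrix(rnorm(n * 4), n, 4)
  res <- partial_out(targ, nuis)
  expect_lt(max(abs(crossprod(res, nuis))), 1e-8)
  expect_lt(max(abs(crossprod(res, rep(1, n)))), 1e-8)
  # target inside the nuisance span collapses
  expect_warning(out <- partial_out(cbind(nuis[, 1], targ[, 1]), nuis),
                 "constant|dropping")
  expect_equal(ncol(out), 1)
  # orthogonal target unchanged up to z-scoring
  t_orth <- qr.resid(qr(cbind(1, nuis)), targ[, 1])
  expect_equal(drop(partial_out(cbind(t_orth), nuis)),
               drop(scale(t_orth)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("autonomic removal reduces variance and zeroes exact combinations", {
  set.seed(18)
  s <- lean_session(31)
  an <- analyze_global_r2(s)
  resid <- remove_autonomic_from_fmri(an$global_hp, an$design, an$windows)
  v_in <- window_variance(an$global_hp, an$windows)
  v_out <- window_variance(drop(resid), an$windows)
  expect_true(all(v_out <= v_in + 1e-12))
  # an exact design combination residualizes to ~0
  combo <- rowSums(an$design$columns[, an$design$groups$autonomic[1:3]])
  r0 <- remove_autonomic_from_fmri(combo, an$design, an$windows)
  expect_lt(max(abs(r0[1:660])), 1e-8)
})

test_that("collinearity check returns 100% for a column inside the group", {
  s <- lean_session(32)
  an <- analyze_global_r2(s)
  stim_col <- an$design$columns[, an$design$groups$autonomic[1]]
  res <- collinearity_check(stim_col, an$design, an$windows)
  expect_equal(res$mean, 100, tolerance = 1e-6)
  expect_lt(res$sd, 1e-6)
})
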