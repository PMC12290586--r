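#' Respiratory response function
#'
#' Closed-form impulse response mapping fluctuations in respiratory volume to
#' the BOLD signal: an early positive lobe peaking a few seconds after a deep
#' breath followed by a slower, wider negative lobe,
#' \deqn{RRF(t) = 0.6\,t^{2.1} e^{-t/1.6} - 0.0023\,t^{3.54} e^{-t/4.25}.}
#'
#' @param t non-negative time grid in seconds.
#' @return kernel samples (not normalized).
#' @export
rrf <- function(t) {
  if (any(t < 0)) stop("response functions are causal: t must be >= 0")
  0.6 * t^2.1 * exp(-t / 1.6) - 0.0023 * t^3.54 * exp(-t / 4.25)
}

#' Cardiac response function
#'
#' Closed-form impulse response mapping heart-rate fluctuations to the BOLD
#' signal: a gamma-shaped positive peak near 4 s followed by a Gaussian
#' trough centred at 12 s,
#' \deqn{CRF(t) = 0.6\,t^{2.7} e^{-t/1.6}
#'   - \frac{16}{\sqrt{2\pi\cdot 9}} e^{-(t-12)^2/18}.}
#'
#' @param t non-negative time grid in seconds.
#' @return kernel samples (not normalized).
#' @export
crf <- function(t) {
  if (any(t < 0)) stop("response functions are causal: t must be >= 0")
  0.6 * t^2.7 * exp(-t / 1.6) - 16 / sqrt(2 * pi * 9) * exp(-(t - 12)^2 / 18)
}

#' Double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a response gamma with peak delay
#' `peak_s` and dispersion `disp`, minus an undershoot gamma with delay
#' `undershoot_s` and dispersion `u_disp`, scaled down by `ratio`. The
#' defaults give the canonical HRF (peak ~5 s, undershoot ~15 s).
#'
#' @param t non-negative time grid in seconds.
#' @param peak_s,undershoot_s delay parameters (s).
#' @param disp,u_disp dispersion parameters (s).
#' @param ratio response-to-undershoot amplitude ratio.
#' @return kernel samples (not normalized).
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16, disp = 1,
                          u_disp = 1, ratio = 6) {
  if (any(t < 0)) stop("response functions are causal: t must be >= 0")
  stopifnot(peak_s > 0, undershoot_s > 0, disp > 0, u_disp > 0, ratio > 0)
  dgamma(t, shape = peak_s / disp, scale = disp) -
    dgamma(t, shape = undershoot_s / u_disp, scale = u_disp) / ratio
}

#' EEG-tailored hemodynamic response function
#'
#' Double-gamma kernel parameterized for slow EEG band-power fluctuations:
#' peak delay 10 s, undershoot delay 14 s, both dispersions 2,
#' response-to-undershoot ratio 2. Compared with the canonical HRF it peaks
#' later and undershoots earlier and more strongly, matching the longer
#' apparent latency of the BOLD response to band-power changes.
#'
#' @param t non-negative time grid in seconds.
#' @return kernel samples (not normalized).
#' @export
eeg_hrf <- function(t) {
  canonical_hrf(t, peak_s = 10, undershoot_s = 14, disp = 2, u_disp = 2,
                ratio = 2)
}

#' Sampled convolution kernel with dispersion family
#'
#' Wraps a closed-form response function into a kernel object carrying its
#' lag grid at TR resolution (0 to `t_max_s`), unit-peak-normalized samples,
#' and a dispersion family `k_d(t) = k(t/d)` used to build dispersion
#' derivatives by finite differences. For the double-gamma kernels the
#' native dispersion parameter is perturbed instead of time-dilating.
#'
#' @param fun function of a single time argument (seconds).
#' @param tr_s sampling interval in seconds.
#' @param t_max_s kernel support; default 33.6 s (16 TRs at 2.1 s), always at
#'   least 32 s.
#' @param name kernel label.
#' @param disp_family optional function(t, d) giving the kernel at dispersion
#'   scale d (d = 1 is the base kernel); defaults to time dilation.
#' @return an object of class `response_kernel` with elements `lag_s`,
#'   `amplitude` (unit peak), `fun`, `disp_family`, `name`, `tr_s`.
#' @export
response_kernel <- function(fun, tr_s, t_max_s = max(32, 16 * tr_s),
                            name = "kernel", disp_family = NULL) {
  stopifnot(tr_s > 0, t_max_s >= 32)
  lag_s <- seq(0, t_max_s, by = tr_s)
  if (is.null(disp_family)) disp_family <- function(t, d) fun(t / d)
  amp <- fun(lag_s)
  peak <- max(abs(amp))
  if (peak == 0) stop("kernel is identically zero on its lag grid")
  structure(list(lag_s = lag_s, amplitude = amp / peak, fun = fun,
                 disp_family = disp_family, name = name, tr_s = tr_s,
                 norm = peak),
            class = "response_kernel")
}

# convenience constructors for the three kernel families used in the design
rrf_kernel <- function(tr_s) response_kernel(rrf, tr_s, name = "rrf")
crf_kernel <- function(tr_s) response_kernel(crf, tr_s, name = "crf")

hrf_kernel <- function(tr_s, peak_s = 6, undershoot_s = 16, disp = 1,
                       u_disp = 1, ratio = 6, name = "hrf") {
  fun <- function(t) canonical_hrf(t, peak_s, undershoot_s, disp, u_disp, ratio)
  fam <- function(t, d) canonical_hrf(t, peak_s, undershoot_s, disp * d,
                                      u_disp * d, ratio)
  response_kernel(fun, tr_s, name = name, disp_family = fam)
}

eeg_hrf_kernel <- function(tr_s) {
  fam <- function(t, d) canonical_hrf(t, 10, 14, 2 * d, 2 * d, 2)
  response_kernel(eeg_hrf, tr_s, name = "eeg_hrf", disp_family = fam)
}

#' Kernel basis with temporal and dispersion derivatives
#'
#' Expands a response kernel into a basis set: the kernel itself plus up to
#' two temporal derivatives (1st and 2nd time derivatives, evaluated by
#' central differences on the closed form) and up to two dispersion
#' derivatives (1st and 2nd central differences in the dispersion parameter,
#' step 5% of its value). Each derivative column is orthogonalized against
#' the base kernel and scaled to unit Euclidean norm; the base column keeps
#' unit peak amplitude. The autonomic response bases use 2 + 2 derivatives
#' (5 columns); the hemodynamic bases for pulse amplitude, EEG band power
#' and stimulus trains use 1 + 1 (3 columns).
#'
#' @param kernel a `response_kernel`.
#' @param n_temporal,n_dispersion number of derivatives of each kind (0-2).
#' @return object of class `kernel_basis`: list with `lag_s`, `kernels`
#'   (lag-by-column matrix), `n_columns`, `name`.
#' @export
add_derivatives <- function(kernel, n_temporal = 2, n_dispersion = 2) {
  stopifnot(inherits(kernel, "response_kernel"))
  if (n_temporal > 2 || n_dispersion > 2 || n_temporal < 0 || n_dispersion < 0) {
    stop("only 0-2 temporal and dispersion derivatives are supported")
  }
  t <- kernel$lag_s
  base <- kernel$amplitude
  cols <- list(base)
  nm <- kernel$name
  labels <- nm
  f <- function(x) kernel$fun(x) / kernel$norm
  dt <- 1e-3
  if (n_temporal >= 1) {
    tp <- pmax(t - dt, 0)
    cols <- c(cols, list((f(t + dt) - f(tp)) / (t + dt - tp)))
    labels <- c(labels, paste0(nm, "_td1"))
  }
  if (n_temporal >= 2) {
    # second derivative; clamp at t = 0 where the forms may be non-smooth
    d2 <- (f(t + dt) - 2 * f(t) + f(abs(t - dt))) / dt^2
    cols <- c(cols, list(d2))
    labels <- c(labels, paste0(nm, "_td2"))
  }
  if (n_dispersion >= 1) {
    h <- 0.05
    g <- function(d) kernel$disp_family(t, d) / kernel$norm
    cols <- c(cols, list((g(1 + h) - g(1 - h)) / (2 * h)))
    labels <- c(labels, paste0(nm, "_dd1"))
    if (n_dispersion >= 2) {
      cols <- c(cols, list((g(1 + h) - 2 * g(1) + g(1 - h)) / h^2))
      labels <- c(labels, paste0(nm, "_dd2"))
    }
  }
  K <- do.call(cbind, cols)
  colnames(K) <- labels
  # orthogonalize derivatives against the base kernel; unit-norm scale
  if (ncol(K) > 1) {
    b <- K[, 1]
    for (j in 2:ncol(K)) {
      v <- K[, j]
      v <- v - b * sum(v * b) / sum(b * b)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("degenerate derivative column ", labels[j])
      K[, j] <- v / nv
    }
  }
  structure(list(lag_s = t, kernels = K, n_columns = ncol(K),
                 name = kernel$name, tr_s = kernel$tr_s),
            class = "kernel_basis")
}
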