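---
title: "Vigilance-staged covariation of fMRI and peripheral autonomic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vigilance-staged covariation of fMRI and peripheral autonomic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigicov)
```

## The problem

As people drift between alertness and drowsiness, the brain's global
hemodynamic signal becomes increasingly entangled with peripheral
autonomic physiology: heart-rate fluctuations, breathing depth, and
peripheral vascular tone all change around sleep onset, and each has a
well-characterized hemodynamic consequence in the BOLD signal. `vigicov`
implements a windowed analysis of this entanglement: it quantifies, in
non-overlapping windows of a simultaneous EEG-fMRI-physiology session,
how much fMRI variance the autonomic signals explain, and asks whether
that fraction grows as EEG-indexed vigilance falls.

The package covers the full chain:

1. **Autonomic features** (`physio_features`): respiratory volume (RV),
   heart rate (HR) and pulse wave amplitude (PWA) extracted from raw
   respiration-belt and photoplethysmography (PPG) waveforms in 6-s
   windows centred on each fMRI volume.
2. **Vigilance indexing** (`band_rms_per_tr`, `vigilance_index`,
   `baseline_vigilance`): per-TR EEG alpha/theta amplitude ratio, averaged
   within analysis windows ("baseline vigilance"), with an
   alpha/(delta+theta) alternative.
3. **Response modeling** (`rrf`, `crf`, `canonical_hrf`, `eeg_hrf`,
   `add_derivatives`, `build_design`): convolution of RV, HR and PWA with
   respiratory, cardiac and canonical hemodynamic response functions plus
   temporal/dispersion derivative bases — 13 autonomic regressors, 9
   fast-EEG regressors, 6 stimulus covariates.
4. **Windowed covariance regression** (`windowed_r2`,
   `vigilance_association`, `bh_fdr`, `bootstrap_ci`, `partial_out`):
   per-window OLS R², Spearman correlation of R² with shifted baseline
   vigilance, 10,000-shuffle permutation tests, Benjamini-Hochberg
   correction, bootstrap intervals, and Frisch-Waugh orthogonalization.
5. **Model-free staging** (`xcov_normalized`, `stage_tertiles`,
   `staged_average`): lagged cross-correlations between fMRI and the
   unconvolved signals, averaged within pooled vigilance tertiles.
6. **Connectivity** (`windowed_fc`, `fc_vigilance_association`,
   `pattern_similarity`): windowed Fisher-z functional connectivity, its
   vigilance association, and the effect of regressing the autonomic
   design out of the fMRI series first.
7. **Synthetic sessions** (`sim_config`, `simulate_session`): a generator
   with a known latent vigilance path and a known vigilance-dependent
   coupling gain, so every stage of the pipeline has a recoverable truth.

## The core statistic

In each non-overlapping window of length 60 TRs (126 s at TR = 2.1 s),
the fMRI series \(y\) is regressed on the z-scored, convolved autonomic
design \(X\) (both high-pass filtered at 1/window-length to keep
between-window offsets out of within-window variance):

\[
R^2_w \;=\; 100 \times
  \frac{\mathrm{SS}_{\text{fit}}}{\mathrm{SS}_{\text{total}}},
\qquad
\rho \;=\; \mathrm{Spearman}\!\left(R^2_w,\; \bar v_w\right),
\]

where \(\bar v_w\) is the window-mean alpha/theta ratio advanced by 2 TRs
(4.2 s) to approximate the hemodynamic peak latency. Significance comes
from a two-tailed permutation test that shuffles \(\bar v_w\) across the
pooled windows, with the add-one estimator
\(p = (1 + \#\{|\rho_b| \ge |\rho|\})/(1 + B)\), \(B = 10{,}000\). Windows
are pooled across sessions before correlation, matching the analysis this
pipeline reproduces; a per-session correlation is also available and both
are reported by `scripts/acceptance.R`.

Groups of different size (13 autonomic vs 9 fast-EEG columns) are
compared on adjusted R², \(1 - (1 - R^2)(n-1)/(n-p-1)\), floored at 0 so
the percentage interpretation survives; flooring is logged.

### Response kernels

The three kernel families are transcriptions of the standard closed
forms: the respiratory response function
\(0.6\,t^{2.1}e^{-t/1.6} - 0.0023\,t^{3.54}e^{-t/4.25}\), the cardiac
response function \(0.6\,t^{2.7}e^{-t/1.6} -
16/\sqrt{18\pi}\,e^{-(t-12)^2/18}\), and double-gamma hemodynamic
kernels (canonical: peak 6 s, undershoot 16 s, dispersions 1, ratio 6;
EEG-tailored: peak 10 s, undershoot 14 s, dispersions 2, ratio 2). All
are sampled at TR resolution on a 0-33.6 s lag grid and unit-peak
normalized. "Two temporal and two dispersion derivatives" is implemented
as 1st/2nd-order central differences in time and in a dispersion
parameter (5% step), each orthogonalized against the base kernel and
unit-norm scaled; the derivative construction in the literature varies,
and the binding constraint adopted here is the five-column count per
autonomic basis. For the RRF and CRF, which have no free dispersion
parameter, the dispersion family is time dilation \(k_d(t) = k(t/d)\);
for the double-gamma kernels the native dispersion parameters are
perturbed.

PWA has no dedicated response function: the series is advanced 2 TRs and
convolved with the canonical three-column basis. Stimulus covariates are
built per response class (responded / unresponded) on a 1-Hz grid,
convolved there, and linearly resampled to the TR grid; convolution
always precedes the discarding of the first 7 volumes so that lagged
responses to early events bleed correctly into the first window.

## Numerical choices

- **Zero-phase filtering.** Every filter (0.15-Hz low-pass on the
  autonomic series, 0.5-2 Hz PPG band-pass, EEG band isolation,
  1/window-length high-pass) is a Butterworth applied forward and
  backward with odd-reflection end padding (`zerophase_butter`). Zero
  phase matters because a causal filter would bias the lag estimates in
  the cross-correlation analyses; the padding keeps step and trend
  transients out of the window edges.
- **Peak detection.** Local maxima with height at least 5% of the
  signal's whole-scan interquartile range and spacing at least 0.55 s
  (109.09 bpm); conflicts resolved greedily by height, earlier peak on
  ties. IBIs outside [0.33, 2] s or more than 3 scaled MADs from a
  running median are linearly interpolated, and the interpolated fraction
  is reported; above 25% the signal is rejected as unusable. Workflows of
  this kind traditionally rely on visual inspection for IBI artifacts; the
  automated rule is a deliberate, logged replacement.
- **Population vs sample moments.** RV/PWA use the population standard
  deviation (amplitude semantics); window variance uses the sample
  variance. Both choices are fixed by tests.
- **Tertile staging.** Pooled baseline-vigilance values are cut at the
  33.3%/66.7% linear-interpolation quantiles; ties at a cut fall into the
  extreme stage, matching the inclusive boundary convention of the staged
  analyses.
- **Cross-correlation normalization.** \(r(\ell)\) uses full-window
  means and sum-of-squares with overlap-only products, so
  \(r(0) = 1\) for a series against itself and attainable magnitude
  shrinks toward extreme lags; positive lags mean the physiological
  signal leads the fMRI signal. End effects are therefore visible at the
  grid edges (-5 to +15 TRs) and are not corrected.
- **Guards.** Correlations numerically at ±1 raise errors before the
  Fisher transform rather than being clipped (silent clipping would
  corrupt permutation nulls); zero denominators in the vigilance index
  raise errors rather than returning infinities; rank-deficient designs
  drop dependent columns with a warning.

## What the generator emulates

`simulate_session` draws a latent vigilance path as an exact-discretized
Ornstein-Uhlenbeck process on the TR grid (mean-reversion time 300 s,
stationary SD 0.55, reflected into [0.3, 2.2] on the alpha/theta-ratio
scale), then derives:

- **EEG band powers** whose alpha/theta ratio tracks the latent path with
  multiplicative noise;
- **autonomic ground truth**: heart rate slows (70 to 52 bpm), breathing
  deepens, and pulse amplitude grows as vigilance falls; each measure
  additionally carries an independent OU fluctuation (correlation time
  30 s; HR on the bpm scale, where heart-rate variability is
  conventionally quantified) whose innovation scale grows with
  drowsiness, so vigilance drives both the mean and the variability of
  the autonomic state without making the three measures collinear;
- **waveforms** (optional): a PPG pulse train of 0.3-s gamma-shaped
  pulses at the true beat times with the true amplitude, and a
  respiration sinusoid with slowly wandering rate — enough structure to
  exercise peak detection and windowed-SD extraction at 100 Hz;
- **fMRI series**: each ROI is gain(t) times the sum of the z-scored
  convolved autonomic drives, plus canonical-HRF responses to responded
  stimuli (task condition), plus AR(1) noise (phi = 0.4, SD 1.5% signal);
  the gain is affine in vigilance, clamped between `gain_high_vig` (0.5)
  and `gain_low_vig` (1.0). The affine form is the simplest monotone
  family consistent with the hypothesis that coupling strengthens with
  drowsiness; no quantitative law for this mapping exists to copy.
- **task events**: uniform inter-stimulus intervals on [29, 41] s,
  response probability falling and reaction time rising with drowsiness,
  responses slower than 4 s recorded as missing.

Defaults give a 24.5-min session at TR 2.1 s — 700 volumes, 693 after
discarding the first 7, hence 11 windows of 60 TRs or 6 of 115 TRs.

**What it does not emulate.** No spatial structure beyond independent
voxel noise around ROI means; no head motion, scanner drift, or EEG
artifacts (the pipeline consumes cleaned data by contract); no
respiratory-cardiac interaction (aliasing, sinus arrhythmia); a single
monotone increase of autonomic variability with drowsiness, although
empirically the HR-variability relationship can differ between task and
rest; and noise levels chosen for a clearly recoverable effect at desk
scale — windowed global R² sits near 70% here, higher than typical real
global-signal values. Passing the recovery tests therefore demonstrates
that the pipeline measures what it claims on data with known truth, not
that real data will show effects of this size.

## Validation strategy and problem sizes

The test suite checks closed-form cases (kernel shapes, filter responses,
window arithmetic), brute-force oracles (normal-equations R² to 1e-8,
loop cross-correlation to 1e-10, exhaustive-threshold BH on 1000 random
p-vectors), and Monte-Carlo properties at deliberately small sizes chosen
for a fast default run:

- recovery: 20 sessions with the low-vigilance gain twice the
  high-vigilance gain; the pooled and per-session-median Spearman
  correlations are both at or below -0.3;
- type-I calibration: 200 sessions with constant gain *and*
  vigilance-independent autonomic variability (both are required for a
  true null, since R² is monotone in drive variance), rejection rate at
  alpha = 0.05 inside the exact binomial 95% interval;
- staged cross-correlation: 24 sessions, 241.5-s windows, pooled
  tertiles — the low-vigilance peak exceeds the high-vigilance peak for
  RV, HR and PWA;
- connectivity: 20 sessions — autonomic removal shrinks the
  vigilance-FC association for the large majority of the 28 network
  pairs.

`scripts/acceptance.R` re-runs these end to end from a single seed and
writes the resulting numbers as JSON.

## Known limitations

- Permutation inference pools windows across sessions and treats them as
  exchangeable, ignoring within-session dependence, as in the analysis
  this package reproduces; a per-session stratified permutation would be
  a straightforward extension.
- The printed tertile cut points of any particular data set are
  data-dependent; only the staging *procedure* is reproducible here.
- The automated IBI artifact rule and the PWA-outlier window rule stand
  in for manual steps in the original workflow and are labelled as such.
- Voxelwise analyses reuse the ROI code path on voxel columns; no
  spatial statistics (cluster correction, smoothness estimation) are
  provided.
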