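Package: vigicov
Title: Vigilance-Dependent Covariation of fMRI and Peripheral Autonomic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the coupling between fMRI signals and
    peripheral autonomic measures (respiratory volume, heart rate, pulse wave
    amplitude) changes with EEG-indexed baseline vigilance. Includes extraction
    of per-volume autonomic features from raw respiration and
    photoplethysmography waveforms, EEG alpha/theta vigilance indexing,
    respiratory/cardiac/hemodynamic response-function convolution with
    derivative basis sets, sliding-window coefficient-of-determination
    regression with permutation inference, Benjamini-Hochberg correction and
    bootstrap confidence intervals, lagged cross-correlation staged by pooled
    vigilance tertiles, windowed functional connectivity with nuisance
    partialling, and a synthetic-session generator with known ground-truth
    vigilance trajectory and coupling gain for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
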