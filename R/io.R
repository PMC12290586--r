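#' Write a synthetic session to disk
#'
#' Serializes a simulated session in the formats the pipeline consumes:
#' 4D fMRI NIfTI (voxel grid ROI-by-voxel, TR in the header), labeled 3D
#' atlas NIfTI, physio TSV (`time_s`, `resp`, `ppg`), EEG band-power TSV
#' (`tr_index`, `alpha`, `theta`, `delta`), events TSV (`onset_s`, `rt_s`
#' with empty cells for missing), and a JSON ground-truth sidecar.
#'
#' @param session a `sim_session` from [simulate_session()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- session$config
  nx <- cfg$n_rois; ny <- cfg$n_voxels_per_roi
  n_tr <- nrow(session$fmri$voxels)
  vol <- aperm(array(t(session$fmri$voxels), c(nx * ny, 1, 1, n_tr)),
               c(1, 2, 3, 4))
  dim(vol) <- c(nx, ny, 1, n_tr)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(3, 3, 3, cfg$tr_s)
  paths <- c(fmri = file.path(dir, "fmri.nii.gz"),
             atlas = file.path(dir, "atlas.nii.gz"),
             physio = file.path(dir, "physio.tsv"),
             eeg = file.path(dir, "eeg_power.tsv"),
             events = file.path(dir, "events.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  RNifti::writeNifti(img, paths["fmri"])
  atlas <- array(session$fmri$voxel_roi, c(nx, ny, 1))
  RNifti::writeNifti(RNifti::asNifti(atlas), paths["atlas"])
  tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  }
  if (!is.null(session$physio)) tsv(session$physio, paths["physio"])
  tsv(session$eeg, paths["eeg"])
  if (!is.null(session$events)) {
    tsv(session$events[, c("onset_s", "rt_s")], paths["events"])
  }
  jsonlite::write_json(
    list(condition = session$condition, seed = cfg$seed, tr_s = cfg$tr_s,
         vigilance_latent = session$vigilance,
         coupling_gain = session$fmri$coupling_gain,
         ibi_true = session$truth$ibi_true, rv_true = session$truth$rv_true,
         pwa_true = session$truth$pwa_true),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a session bundle from disk
#'
#' Reads the fMRI and atlas NIfTI files and the physio/EEG/events TSVs,
#' validates the TR recorded in the NIfTI header against the expected value
#' (mismatch beyond 1 ms is an error) and the atlas grid against the fMRI
#' grid, discards the first `n_discard` volumes of nothing (volumes are kept
#' here; discarding happens inside the analyses so convolution can use the
#' full span), and extracts per-ROI mean series by atlas label.
#'
#' @param dir directory written by [write_session()] (or with the same
#'   layout).
#' @param tr_s expected repetition time (s).
#' @param condition `"rest"` or `"task"`.
#' @return list: `roi` (TR x ROI means, full grid), `voxels`, `voxel_roi`,
#'   `physio`, `eeg`, `events` (NULL if absent), `tr_s`, `condition`.
#' @export
load_session <- function(dir, tr_s = 2.1, condition = c("rest", "task")) {
  condition <- match.arg(condition)
  img <- RNifti::readNifti(file.path(dir, "fmri.nii.gz"))
  hdr_tr <- RNifti::pixdim(img)[4]
  if (abs(hdr_tr - tr_s) > 1e-3) {
    stop("TR in NIfTI header (", hdr_tr, " s) does not match expected ",
         tr_s, " s")
  }
  atlas <- RNifti::readNifti(file.path(dir, "atlas.nii.gz"))
  # NIfTI writers may drop trailing singleton dimensions
  adim <- c(dim(atlas), 1, 1)[1:3]
  if (!all(dim(img)[1:3] == adim)) {
    stop("atlas grid does not match fMRI grid")
  }
  d <- dim(img)
  n_tr <- d[4]
  voxels <- t(matrix(img, prod(d[1:3]), n_tr))
  labels <- as.integer(atlas)
  keep <- labels > 0
  voxels <- voxels[, keep, drop = FALSE]
  labels <- labels[keep]
  rois <- sort(unique(labels))
  roi <- sapply(rois, function(l) rowMeans(voxels[, labels == l,
                                                  drop = FALSE]))
  colnames(roi) <- paste0("roi", rois)
  physio_path <- file.path(dir, "physio.tsv")
  physio <- if (file.exists(physio_path)) read.delim(physio_path) else NULL
  eeg <- read.delim(file.path(dir, "eeg_power.tsv"))
  ev_path <- file.path(dir, "events.tsv")
  events <- if (condition == "task" && file.exists(ev_path)) {
    read.delim(ev_path)
  } else NULL
  list(roi = roi, voxels = voxels, voxel_roi = labels, physio = physio,
       eeg = eeg, events = events, tr_s = tr_s, condition = condition)
}

#' Run the windowed covariance analysis on one session
#'
#' End-to-end orchestration for a single session: extracts autonomic
#' features from the raw waveforms (or takes the provided TR-level series),
#' computes the EEG vigilance index and shifted baseline vigilance, builds
#' the convolved 13-column autonomic design (plus stimulus covariates for
#' the task condition), discards the first `n_discard` volumes, high-pass
#' filters the global fMRI signal at 1/window-length, tiles the session
#' into windows, and correlates per-window variance explained with baseline
#' vigilance using a permutation test.
#'
#' @param session a `sim_session`, or the list returned by
#'   [load_session()].
#' @param window_len_tr analysis window length in volumes (default 60).
#' @param n_discard leading volumes dropped from analysis (default 7).
#' @param B permutations for the association test.
#' @param model_stimuli include stimulus covariates as nuisance (task
#'   condition only; default TRUE when events are present).
#' @param shift_trs EEG-to-fMRI shift for baseline vigilance (default 2).
#' @param out_dir optional directory; when given, per-window results and a
#'   JSON summary (with config hash and seed) are written there.
#' @return list: `autonomic`, `baseline`, `r2` (per window), `association`
#'   (`rho`, `p_perm`, `n_windows`), `ci95`, `hr_variance_association`,
#'   `windows`.
#' @export
run_pipeline <- function(session, window_len_tr = 60, n_discard = 7,
                         B = 10000, model_stimuli = NULL, shift_trs = 2,
                         out_dir = NULL) {
  tr_s <- if (inherits(session, "sim_session")) session$config$tr_s else
    session$tr_s
  roi <- if (inherits(session, "sim_session")) session$fmri$roi else
    session$roi
  n_tr <- nrow(roi)
  events <- session$events
  if (is.null(model_stimuli)) model_stimuli <- !is.null(events)

  if (!is.null(session$physio)) {
    autonomic <- physio_features(session$physio,
                                 rate_hz = round(1 / median(diff(session$physio$time_s))),
                                 tr_s = tr_s, n_vols = n_tr)
  } else {
    autonomic <- data.frame(tr_index = seq_len(n_tr) - 1L,
                            rv = session$truth$rv_true,
                            hr = session$truth$hr_true,
                            pwa = session$truth$pwa_true)
  }

  design <- build_design(autonomic, tr_s, events = events,
                         n_discard = n_discard)
  window_len_s <- window_len_tr * tr_s
  design <- highpass_design(design, window_len_s)
  ratio <- vigilance_index(session$eeg)[-seq_len(n_discard)]
  global <- rowMeans(roi)[-seq_len(n_discard)]
  fs <- 1 / tr_s
  global_hp <- highpass_for_windows(global, fs, window_len_s)

  windows <- segment_windows(length(global_hp), window_len_tr)
  baseline <- baseline_vigilance(ratio, windows, shift_trs = shift_trs)
  r2 <- windowed_r2(global_hp, design, windows, group = "autonomic",
                    model_stimuli = model_stimuli)
  r2 <- r2[as.character(r2$window_id) %in% names(baseline), ]
  assoc <- vigilance_association(r2, baseline, B = B)
  keep <- as.character(r2$window_id)
  ci <- bootstrap_ci(r2$r2_pct, baseline[keep], B = 2000)

  hr_hp <- highpass_for_windows(autonomic$hr[-seq_len(n_discard)], fs,
                                window_len_s)
  hr_var <- window_variance(hr_hp, windows)[keep]
  hr_assoc <- spearman_perm_test(hr_var, baseline[keep], B = B)

  res <- list(autonomic = autonomic, baseline = baseline, r2 = r2,
              association = assoc, ci95 = ci$ci,
              hr_variance_association = list(rho = hr_assoc$rho,
                                             p_perm = hr_assoc$p),
              windows = windows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(cbind(r2, baseline = baseline[keep]),
                file.path(out_dir, "windowed_r2.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    prov <- list(rho = assoc$rho, p_perm = assoc$p_perm,
                 ci95 = unname(ci$ci), window_len_tr = window_len_tr,
                 n_discard = n_discard, B = B,
                 seed = if (inherits(session, "sim_session"))
                   session$config$seed else NA)
    jsonlite::write_json(prov, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
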