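#' Resample an EEG-derived series onto the fMRI time grid
#'
#' Co-registers the series to the scanner clock, applies an anti-alias
#' low-pass below the volume-rate Nyquist (0.25 Hz at TR = 2 s;
#' 4th-order Butterworth, zero-phase) when the series is faster than the
#' volume rate, and samples it at the volume acquisition times. HRF
#' convolution and standardisation happen later, in [build_design()].
#'
#' @param asym an `asymmetry_series` (or any list with `times`, `values`,
#'   `rate`).
#' @param fmri_start acquisition time of the first volume, seconds, on
#'   the EEG clock.
#' @param n_volumes number of volumes.
#' @param tr repetition time, seconds.
#' @param tolerance span tolerance at the edges, seconds (band-power
#'   windows shave half a window off each end of the EEG).
#' @return numeric regressor of length `n_volumes`.
#' @export
build_asymmetry_regressor <- function(asym, fmri_start = 0, n_volumes, tr,
                                      tolerance = 3) {
  vol_times <- fmri_start + (seq_len(n_volumes) - 1) * tr
  lo <- min(asym$times); hi <- max(asym$times)
  if (lo > vol_times[1] + tolerance || hi < vol_times[n_volumes] - tolerance) {
    stop(sprintf(paste0("asymmetry series [%.1f, %.1f] s does not span the ",
                        "fMRI acquisition [%.1f, %.1f] s"),
                 lo, hi, vol_times[1], vol_times[n_volumes]))
  }
  values <- asym$values
  target <- 1 / tr
  if (asym$rate > target * (1 + 1e-6)) {
    bf <- signal::butter(4, (target / 2) / (asym$rate / 2), type = "low")
    values <- signal::filtfilt(bf, values)
  }
  interp_series(asym$times, values, vol_times)
}

# TR-grid mean of the reported trace restricted to trials of given types;
# zero outside those trials
affect_regressor <- function(reported, schedule, types, n_volumes, tr,
                             axis = "valence") {
  t_mid <- (seq_len(n_volumes) - 0.5) * tr
  vals <- interp_series(reported$time, reported[[axis]], t_mid)
  keep <- rep(FALSE, n_volumes)
  sel <- schedule[schedule$trial_type %in% types, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    keep[t_mid >= sel$onset[i] & t_mid < sel$onset[i] + sel$duration[i]] <- TRUE
  }
  vals * keep
}

# reporting-task indicator at the TR grid
task_boxcar <- function(schedule, types, n_volumes, tr) {
  t_mid <- (seq_len(n_volumes) - 0.5) * tr
  out <- rep(0, n_volumes)
  sel <- schedule[schedule$trial_type %in% types, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    out[t_mid >= sel$onset[i] & t_mid < sel$onset[i] + sel$duration[i]] <- 1
  }
  out
}

# HRF-convolved movement confound: the reporting task (music+reporting
# and reporting-only trials) drives joystick use
movement_confound <- function(schedule, n_volumes, tr) {
  bc <- task_boxcar(schedule, c("music_reporting", "reporting_only"),
                    n_volumes, tr)
  convolve_regressor(bc, canonical_hrf(dt = tr))
}

# shared design builders for the analysis chains ------------------------

asymmetry_design <- function(dataset, band) {
  if (is.character(band)) band <- eeg_bands()[[band]]
  cfg <- dataset$config
  n_vol <- dim(dataset$bold$data)[4]
  tr <- dataset$bold$tr
  asym <- prefrontal_asymmetry(dataset$eeg, band,
                               window = cfg$power_window,
                               step = cfg$power_step)
  reg <- build_asymmetry_regressor(asym, fmri_start = 0,
                                   n_volumes = n_vol, tr = tr)
  build_design(list(asymmetry = reg),
               confounds = list(movement = movement_confound(
                 dataset$schedule, n_vol, tr)),
               drift_order = cfg$drift_order, n_volumes = n_vol, tr = tr)
}

entropy_design <- function(dataset, band, entropy_mode = "per_trial_boxcar",
                           n_bins = 16L) {
  if (is.character(band)) band <- eeg_bands()[[band]]
  cfg <- dataset$config
  n_vol <- dim(dataset$bold$data)[4]
  tr <- dataset$bold$tr
  asym <- prefrontal_asymmetry(dataset$eeg, band,
                               window = cfg$entropy_window %||% 1,
                               step = cfg$entropy_step)
  ent <- entropy_regressor_series(asym, dataset$schedule,
                                  mode = entropy_mode, n_bins = n_bins)
  reg <- build_asymmetry_regressor(ent, fmri_start = 0,
                                   n_volumes = n_vol, tr = tr)
  build_design(list(entropy = reg),
               confounds = list(movement = movement_confound(
                 dataset$schedule, n_vol, tr)),
               drift_order = cfg$drift_order, n_volumes = n_vol, tr = tr)
}

affect_design <- function(dataset, axis) {
  cfg <- dataset$config
  n_vol <- dim(dataset$bold$data)[4]
  tr <- dataset$bold$tr
  reg <- affect_regressor(dataset$reported, dataset$schedule,
                          c("music_only", "music_reporting"),
                          n_vol, tr, axis = axis)
  build_design(stats::setNames(list(reg), axis),
               confounds = list(movement = movement_confound(
                 dataset$schedule, n_vol, tr)),
               drift_order = cfg$drift_order, n_volumes = n_vol, tr = tr)
}

reporting_design <- function(dataset) {
  n_vol <- dim(dataset$bold$data)[4]
  tr <- dataset$bold$tr
  build_design(list(reporting = task_boxcar(dataset$schedule,
                                            "reporting_only", n_vol, tr)),
               confounds = list(),
               drift_order = dataset$config$drift_order,
               n_volumes = n_vol, tr = tr)
}

# set B: voxels co-varying with FEELTRACE use alone, from the
# reporting-only trials
reporting_mask <- function(dataset, alpha, correction = "bonferroni",
                           n_permutations = 200L) {
  des <- reporting_design(dataset)
  fit <- fit_glm(dataset$bold, des)
  sm <- f_contrast(fit, "reporting")
  fwe_threshold(sm, alpha, method = correction, fit = fit,
                n_permutations = n_permutations,
                seed = stage_seed(dataset$config$seed, "permute"))
}

#' Calibrate ROI coupling amplitudes to a target theoretical power
#'
#' For every coupled ROI in the dataset's ground truth, solves for the
#' amplitude at which the analysis that is meant to detect it (the
#' affect GLM for valence/arousal ROIs, the asymmetry or entropy fusion
#' GLM for EEG-driven ROIs, the reporting GLM for movement ROIs) has the
#' requested per-voxel power at the Bonferroni-corrected level, then
#' regenerates the BOLD data at those amplitudes (same seed, so the
#' noise realisation is unchanged).
#'
#' @param dataset an `affect_dataset`.
#' @param power target per-voxel power.
#' @param alpha FWE level of the detecting analyses.
#' @param exclusion_alpha FWE level of the reporting analysis (movement
#'   ROIs calibrate against it).
#' @return the dataset with recalibrated coupling amplitudes and BOLD.
#' @export
calibrate_coupling <- function(dataset, power = 0.95, alpha = 0.01,
                               exclusion_alpha = 0.05) {
  cfg <- dataset$config
  n_vox <- prod(cfg$volume_shape)
  band <- cfg$driver_band
  designs <- list()
  need <- unique(vapply(cfg$coupling$rois, function(r) r$driver, character(1)))
  if ("valence" %in% need) designs$valence <- list(affect_design(dataset, "valence"), "valence", alpha)
  if ("arousal" %in% need) designs$arousal <- list(affect_design(dataset, "arousal"), "arousal", alpha)
  if ("asymmetry" %in% need) designs$asymmetry <- list(asymmetry_design(dataset, band), "asymmetry", alpha)
  if ("entropy" %in% need) designs$entropy <- list(entropy_design(dataset, band), "entropy", alpha)
  if ("movement" %in% need) designs$movement <- list(reporting_design(dataset), "reporting", exclusion_alpha)
  for (nm in names(cfg$coupling$rois)) {
    roi <- cfg$coupling$rois[[nm]]
    if (roi$amplitude == 0) next
    d <- designs[[roi$driver]]
    cfg$coupling$rois[[nm]]$amplitude <-
      amplitude_for_power(d[[1]], d[[2]],
                          truth_column = dataset$truth$driver_series[[roi$driver]],
                          noise_sd = cfg$noise_sd_bold, power = power,
                          alpha = d[[3]], n_comparisons = n_vox)
  }
  gb <- generate_bold(dataset$latent, dataset$features, dataset$schedule, cfg)
  dataset$config <- cfg
  dataset$bold <- gb$bold
  dataset$truth <- gb$truth
  dataset
}

fusion_result <- function(measure, band, statmap, mask_A, mask_B, clusters,
                          alpha, exclusion_alpha, correction, dataset) {
  mask_C <- exclusion_contrast(mask_A, mask_B)
  structure(list(measure = measure, band = band, statmap = statmap,
                 mask_A = mask_A, mask_B = mask_B, mask_C = mask_C,
                 clusters = clusters, alpha = alpha,
                 exclusion_alpha = exclusion_alpha, correction = correction,
                 provenance = list(seed = dataset$config$seed,
                                   n_trials = dataset$config$n_trials,
                                   tr = dataset$config$tr)),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("EEG-informed fMRI fusion (%s%s): |A| = %d, |B| = %d, |C| = %d voxels\n",
              x$measure, if (nzchar(x$band)) paste0(", ", x$band) else "",
              sum(x$mask_A), sum(x$mask_B), sum(x$mask_C)))
  if (nrow(x$clusters)) {
    cat(sprintf("  %d cluster(s) in C; peak F = %.2f\n",
                nrow(x$clusters), max(x$clusters$peak_f)))
  } else cat("  no significant clusters in C\n")
  invisible(x)
}

#' EEG-asymmetry-informed fMRI analysis
#'
#' Full fusion chain for one frequency band: prefrontal Laplacian
#' asymmetry from the EEG, resampled to the volume grid, entered as the
#' effect of interest in a GLM with the movement confound and polynomial
#' drift, F-tested, FWE-thresholded (set A), stripped of the
#' reporting-related set B, and summarised as a cluster table over
#' C = A \ B.
#'
#' @param dataset an `affect_dataset` (or equivalent list with `eeg`,
#'   `bold`, `schedule`, `reported`, `config`).
#' @param band band name (`"alpha"`, `"beta"`, ...) or a
#'   `band_definition`.
#' @param alpha FWE level of the asymmetry map (set A).
#' @param exclusion_alpha FWE level of the reporting map (set B).
#' @param correction `"bonferroni"` or `"permutation_maxT"`.
#' @param n_permutations permutations for the permutation method.
#' @return a `fusion_result` with the stat map, masks A/B/C and the
#'   cluster table of C.
#' @export
run_asymmetry_fusion <- function(dataset, band = "alpha", alpha = 0.01,
                                 exclusion_alpha = 0.05,
                                 correction = "bonferroni",
                                 n_permutations = 200L) {
  if (is.character(band)) band <- eeg_bands()[[band]]
  des <- asymmetry_design(dataset, band)
  fit <- fit_glm(dataset$bold, des)
  sm <- f_contrast(fit, "asymmetry")
  mask_A <- fwe_threshold(sm, alpha, method = correction, fit = fit,
                          n_permutations = n_permutations,
                          seed = stage_seed(dataset$config$seed, "permute"))
  mask_B <- reporting_mask(dataset, exclusion_alpha, correction,
                           n_permutations)
  mask_C <- exclusion_contrast(mask_A, mask_B)
  clusters <- local_maxima_table(sm, mask_C)
  fusion_result("asymmetry", band$name, sm, mask_A, mask_B, clusters,
                alpha, exclusion_alpha, correction, dataset)
}

#' Entropy-informed fMRI analysis
#'
#' As [run_asymmetry_fusion()], with the Shannon-entropy regressor of
#' the asymmetry dynamics (per-trial boxcar by default) as the effect of
#' interest. The asymmetry is computed at the finer entropy power step
#' so each trial holds enough samples for a stable histogram.
#'
#' @inheritParams run_asymmetry_fusion
#' @param entropy_mode `"per_trial_boxcar"` or `"sliding_window"`.
#' @param n_bins histogram bins per estimation window.
#' @return a `fusion_result`.
#' @export
run_entropy_fusion <- function(dataset, band = "alpha", alpha = 0.01,
                               exclusion_alpha = 0.05,
                               correction = "bonferroni",
                               entropy_mode = "per_trial_boxcar",
                               n_bins = 16L,
                               n_permutations = 200L) {
  if (is.character(band)) band <- eeg_bands()[[band]]
  des <- entropy_design(dataset, band, entropy_mode = entropy_mode,
                        n_bins = n_bins)
  fit <- fit_glm(dataset$bold, des)
  sm <- f_contrast(fit, "entropy")
  mask_A <- fwe_threshold(sm, alpha, method = correction, fit = fit,
                          n_permutations = n_permutations,
                          seed = stage_seed(dataset$config$seed, "permute"))
  mask_B <- reporting_mask(dataset, exclusion_alpha, correction,
                           n_permutations)
  mask_C <- exclusion_contrast(mask_A, mask_B)
  clusters <- local_maxima_table(sm, mask_C)
  fusion_result("entropy", band$name, sm, mask_A, mask_B, clusters,
                alpha, exclusion_alpha, correction, dataset)
}

#' Affect-report GLM with exclusion contrast
#'
#' Set A: voxels co-varying with the reported affect trace during all
#' music-listening trials (music-only trials carry the reports copied
#' from the matching music+reporting trial, as the paradigm prescribes).
#' Set B: voxels co-varying with FEELTRACE use during reporting-only
#' trials. C = A \ B isolates affect-related from reporting-related
#' voxels.
#'
#' @param dataset an `affect_dataset`.
#' @param axis `"valence"` or `"arousal"`.
#' @param alpha FWE level of the affect map (set A).
#' @param exclusion_alpha FWE level of the reporting map (set B).
#' @param correction `"bonferroni"` or `"permutation_maxT"`.
#' @param n_permutations permutations for the permutation method.
#' @return a `fusion_result` (`measure = "affect_<axis>"`).
#' @export
run_affect_glm <- function(dataset, axis = c("valence", "arousal"),
                           alpha = 0.05, exclusion_alpha = 0.05,
                           correction = "bonferroni",
                           n_permutations = 200L) {
  axis <- match.arg(axis)
  sched <- dataset$schedule
  if (!all(c("music_only", "music_reporting", "reporting_only") %in%
           sched$trial_type)) {
    stop("schedule must contain all three trial types")
  }
  des <- affect_design(dataset, axis)
  fit <- fit_glm(dataset$bold, des)
  sm <- f_contrast(fit, axis)
  mask_A <- fwe_threshold(sm, alpha, method = correction, fit = fit,
                          n_permutations = n_permutations,
                          seed = stage_seed(dataset$config$seed, "permute"))
  mask_B <- reporting_mask(dataset, exclusion_alpha, correction,
                           n_permutations)
  mask_C <- exclusion_contrast(mask_A, mask_B)
  clusters <- local_maxima_table(sm, mask_C)
  fusion_result(paste0("affect_", axis), "", sm, mask_A, mask_B, clusters,
                alpha, exclusion_alpha, correction, dataset)
}

#' Full fusion study with data-driven band selection
#'
#' Runs the high-vs-low valence KS + Holm battery and then the
#' asymmetry- and entropy-informed fMRI analyses for every band in which
#' the battery rejects (mirroring the convention of fusing only bands
#' that show a significant asymmetry difference). Bands can be forced
#' explicitly instead.
#'
#' @param dataset an `affect_dataset`.
#' @param bands optional character vector of band names; `NULL` selects
#'   the battery's rejected bands.
#' @param alpha FWE level of the fusion maps.
#' @param exclusion_alpha FWE level of the reporting (set B) map.
#' @param correction `"bonferroni"` or `"permutation_maxT"`.
#' @param battery_alpha level of the band-selection battery.
#' @return list with `battery` (the selection table) and `fusions` (a
#'   list of `fusion_result`s named `<measure>_<band>`; empty when no
#'   band is selected).
#' @export
run_fusion_study <- function(dataset, bands = NULL, alpha = 0.01,
                             exclusion_alpha = 0.05,
                             correction = "bonferroni",
                             battery_alpha = 0.05) {
  battery <- asymmetry_battery(dataset$eeg, dataset$reported,
                               dataset$schedule, alpha = battery_alpha,
                               window = dataset$config$power_window,
                               step = dataset$config$power_step)
  if (is.null(bands)) bands <- battery$band[battery$rejected]
  fusions <- list()
  for (b in bands) {
    fusions[[paste0("asymmetry_", b)]] <-
      run_asymmetry_fusion(dataset, b, alpha = alpha,
                           exclusion_alpha = exclusion_alpha,
                           correction = correction)
    fusions[[paste0("entropy_", b)]] <-
      run_entropy_fusion(dataset, b, alpha = alpha,
                         exclusion_alpha = exclusion_alpha,
                         correction = correction)
  }
  list(battery = battery, fusions = fusions)
}
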