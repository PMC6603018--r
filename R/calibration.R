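#' Run one null study for error-rate calibration
#'
#' Simulates a dataset with every coupling switched off (all ROI
#' amplitudes 0 and zero EEG valence gain), then runs the two inferential
#' chains whose error rates the package must control: the high-vs-low
#' valence KS + Holm battery across the four bands, and the
#' asymmetry-informed fusion GLM with Bonferroni FWE thresholding of its
#' map. Under this global null any rejection is a false positive.
#'
#' @param seed simulation seed.
#' @param n_trials trials per study (15 gives a 5/5 high/low split of the
#'   music trials under a median split).
#' @param volume_shape voxel grid (small; FWE control does not depend on
#'   the voxel count).
#' @param eeg_rate EEG rate, Hz.
#' @param alpha level for both chains.
#' @return list: `battery_rejected` (any band rejected), `chain_rejected`
#'   (any voxel in the Bonferroni mask), `p_values` (per-voxel fusion GLM
#'   p-values), `battery` (the battery table).
#' @export
run_null_study <- function(seed, n_trials = 15L,
                           volume_shape = c(7L, 7L, 7L),
                           eeg_rate = 100, alpha = 0.05) {
  cs <- coupling_spec(volume_shape = volume_shape,
                      amplitudes = c(valence = 0, arousal = 0,
                                     asymmetry = 0, entropy = 0,
                                     movement = 0),
                      eeg_valence_gain = 0)
  cfg <- sim_config(seed = seed, n_trials = n_trials, eeg_rate = eeg_rate,
                    volume_shape = volume_shape, coupling = cs)
  schedule <- generate_schedule(cfg)
  aff <- generate_affect(schedule, cfg)
  eeg <- generate_eeg(aff$latent, schedule, cfg)
  gb <- generate_bold(aff$latent, NULL, schedule, cfg)
  ds <- structure(list(config = cfg, schedule = schedule,
                       latent = aff$latent, reported = aff$reported,
                       eeg = eeg, bold = gb$bold, truth = gb$truth),
                  class = "affect_dataset")
  battery <- asymmetry_battery(eeg, aff$reported, schedule, alpha = alpha)
  des <- asymmetry_design(ds, cfg$driver_band)
  fit <- fit_glm(ds$bold, des)
  sm <- f_contrast(fit, "asymmetry")
  mask <- fwe_threshold(sm, alpha, method = "bonferroni")
  list(battery_rejected = any(battery$rejected),
       chain_rejected = any(mask),
       p_values = as.numeric(sm$p_values),
       battery = battery)
}

#' Run one ground-truth recovery study
#'
#' Simulates a fully coupled dataset, calibrates every ROI amplitude to
#' the requested theoretical per-voxel power, then runs the affect GLM
#' (valence), the asymmetry fusion and the entropy fusion, and scores
#' recovery against the ground-truth masks.
#'
#' @param seed simulation seed.
#' @param n_trials trials per study.
#' @param volume_shape voxel grid.
#' @param eeg_rate EEG rate, Hz.
#' @param power target theoretical per-voxel power for the calibration.
#' @param alpha FWE level of the detecting analyses.
#' @param exclusion_alpha FWE level of the reporting (set B) analysis.
#' @return list of per-study scores: voxelwise sensitivities within the
#'   valence-, asymmetry- and entropy-coupled ROIs (fraction of coupled
#'   voxels in mask C of their own analysis), whether the movement ROI
#'   intersects set B and whether it ever reaches any mask C, the
#'   cross-detection indicators between the asymmetry and entropy
#'   analyses, whether the run is dissociated, and whether C and B are
#'   disjoint in every analysis.
#' @export
run_recovery_study <- function(seed, n_trials = 18L,
                               volume_shape = c(10L, 10L, 10L),
                               eeg_rate = 100, power = 0.95,
                               alpha = 0.01, exclusion_alpha = 0.05) {
  cfg <- sim_config(seed = seed, n_trials = n_trials, eeg_rate = eeg_rate,
                    volume_shape = volume_shape,
                    coupling = coupling_spec(volume_shape = volume_shape))
  ds <- simulate_dataset(cfg)
  ds <- calibrate_coupling(ds, power = power, alpha = alpha,
                           exclusion_alpha = exclusion_alpha)
  fa <- run_affect_glm(ds, "valence", alpha = alpha,
                       exclusion_alpha = exclusion_alpha)
  fs <- run_asymmetry_fusion(ds, cfg$driver_band, alpha = alpha,
                             exclusion_alpha = exclusion_alpha)
  fe <- run_entropy_fusion(ds, cfg$driver_band, alpha = alpha,
                           exclusion_alpha = exclusion_alpha)
  tm <- ds$truth$roi_masks
  flags_asym <- any(fs$mask_C[tm$asymmetry])
  flags_ent <- any(fe$mask_C[tm$entropy])
  cross_asym <- any(fs$mask_C[tm$entropy])
  cross_ent <- any(fe$mask_C[tm$asymmetry])
  list(sens_valence = mean(fa$mask_C[tm$valence]),
       sens_asymmetry = mean(fs$mask_C[tm$asymmetry]),
       sens_entropy = mean(fe$mask_C[tm$entropy]),
       movement_in_B = any(fs$mask_B[tm$movement]),
       movement_in_C = any(fa$mask_C[tm$movement] | fs$mask_C[tm$movement] |
                             fe$mask_C[tm$movement]),
       null_in_C = any(fa$mask_C[tm$null] | fs$mask_C[tm$null] |
                         fe$mask_C[tm$null]),
       dissociated = flags_asym && flags_ent && !cross_asym && !cross_ent,
       c_b_disjoint = !any(fa$mask_C & fa$mask_B) &&
         !any(fs$mask_C & fs$mask_B) && !any(fe$mask_C & fe$mask_B))
}

#' Directional consistency of asymmetry and its entropy with valence
#'
#' Orders the music trials by mean reported valence and pairs the k-th
#' most positive trial with the k-th most negative one. Per band, each
#' pair scores a success when the higher-valence member shows the larger
#' mean asymmetry, and (separately) when the lower-valence member shows
#' the larger asymmetry entropy. The success counts are sign tests over
#' the trials, scored against chance with a one-sided binomial test.
#'
#' @param eeg an [eeg_recording()].
#' @param reported the reported `affect_trajectory`.
#' @param schedule the `trial_schedule`.
#' @param bands band names to score (default alpha and beta).
#' @param power_window,power_step band-power parameters for trial-mean
#'   asymmetry.
#' @param entropy_window,entropy_step band-power parameters for the
#'   entropy series.
#' @return data.frame: `band`, `n_trials`, `asym_successes`, `asym_p`,
#'   `entropy_successes`, `entropy_p`.
#' @export
directional_consistency <- function(eeg, reported, schedule,
                                    bands = c("alpha", "beta"),
                                    power_window = 2, power_step = 2,
                                    entropy_window = 1,
                                    entropy_step = 0.25) {
  labels <- label_valence_trials(reported, schedule, threshold = "median")
  bdefs <- eeg_bands()[bands]
  coarse <- prefrontal_asymmetry_bands(eeg, bdefs, window = power_window,
                                       steps = power_step)
  fine <- prefrontal_asymmetry_bands(eeg, bdefs, window = entropy_window,
                                     steps = entropy_step)
  o <- order(labels$mean_valence)
  n_pairs <- length(o) %/% 2L
  lo <- o[seq_len(n_pairs)]
  hi <- rev(o)[seq_len(n_pairs)]
  rows <- lapply(seq_along(bands), function(i) {
    tm <- trial_mean_asymmetry(coarse[[i]][[1]], schedule)
    ent <- trial_entropy(fine[[i]][[1]], schedule)$entropy_bits
    s_asym <- sum(tm[hi] > tm[lo])
    s_ent <- sum(ent[lo] > ent[hi])
    data.frame(band = bands[i], n_trials = length(o), n_pairs = n_pairs,
               asym_successes = s_asym,
               asym_p = stats::binom.test(s_asym, n_pairs,
                                          alternative = "greater")$p.value,
               entropy_successes = s_ent,
               entropy_p = stats::binom.test(s_ent, n_pairs,
                                             alternative = "greater")$p.value)
  })
  do.call(rbind, rows)
}
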