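test_that("schedules honour the paradigm structure and precedence constraint", {
  cfg <- sim_config(seed = 7, n_trials = 36L, eeg_rate = 100)
  sched <- generate_schedule(cfg)
  expect_equal(nrow(sched), 36L)
  expect_true(all(sched$duration == 40))
  expect_equal(as.integer(table(sched$trial_type)), rep(12L, 3))
  expect_true(all(sched$target_region1 %in% 1:9))
  expect_true(all(sched$target_region2 %in% 1:9))
  expect_true(all(sched$target_region1 != sched$target_region2))
  expect_true(all(sched$jitter >= 0 & sched$jitter <= 2))
  expect_true(all(diff(sched$onset) > 40))  # non-overlap with breaks

  # precedence: checked across many seeds, exhaustively within each
  for (s in 1:25) {
    sc <- generate_schedule(sim_config(seed = s, n_trials = 12L,
                                       eeg_rate = 100))
    for (i in which(sc$trial_type == "reporting_only")) {
      expect_true(any(sc$trial_type[seq_len(i - 1)] == "music_reporting" &
                        sc$stimulus_id[seq_len(i - 1)] == sc$stimulus_id[i]))
    }
  }
})

test_that("three trials force music_reporting before reporting_only", {
  sc <- generate_schedule(sim_config(seed = 3, n_trials = 3L, eeg_rate = 100))
  expect_lt(which(sc$trial_type == "music_reporting"),
            which(sc$trial_type == "reporting_only"))
})

test_that("schedule generation is deterministic and rejects bad sizes", {
  cfg <- sim_config(seed = 7, n_trials = 36L, eeg_rate = 100)
  expect_identical(generate_schedule(cfg), generate_schedule(cfg))
  expect_error(generate_schedule(sim_config(seed = 1, n_trials = 10L,
                                            eeg_rate = 100)),
               "multiple of 3")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(seed = 1, trial_duration = 30), "2 \\* half")
  expect_error(sim_config(seed = 1, eeg_rate = 125, tr = 1.5), "integer")
  expect_error(sim_config(seed = 1, channel_labels = c("F3", "F4")),
               "must include")
  expect_error(sim_config(seed = 1, report_lag = -1), "non-negative")
  expect_error(coupling_spec(volume_shape = c(12L, 12L, 12L),
                             amplitudes = c(valence = Inf, arousal = 0,
                                            asymmetry = 0, entropy = 0,
                                            movement = 0)), "finite")
})

test_that("overlapping ROI masks are rejected", {
  shape <- c(8L, 8L, 8L)
  m <- roi_block(c(2L, 2L, 2L), c(2L, 2L, 2L), shape)
  rois <- list(a = list(driver = "valence", amplitude = 1, mask = m),
               b = list(driver = "arousal", amplitude = 1, mask = m),
               null = list(driver = "valence", amplitude = 0,
                           mask = roi_block(c(6L, 6L, 6L), c(2L, 2L, 2L),
                                            shape)))
  expect_error(coupling_spec(rois = rois), "disjoint")
})

test_that("affect trajectories stay in range and track targets", {
  cfg <- tiny_config(seed = 11, n_trials = 12L)
  sched <- generate_schedule(cfg)
  aff <- generate_affect(sched, cfg)
  for (tr in list(aff$latent, aff$reported)) {
    expect_true(all(abs(tr$valence) <= 1))
    expect_true(all(abs(tr$arousal) <= 1))
    expect_equal(diff(range(diff(tr$time))), 0, tolerance = 1e-9)
  }
  # latent mean differs between halves when targets differ
  music <- sched[sched$trial_type != "reporting_only", ]
  d <- vapply(seq_len(nrow(music)), function(i) {
    on <- music$onset[i]
    h1 <- aff$latent$time >= on & aff$latent$time < on + 20
    h2 <- aff$latent$time >= on + 20 & aff$latent$time < on + 40
    (mean(aff$latent$valence[h1]) - mean(aff$latent$valence[h2])) *
      sign(music$target_v1[i] - music$target_v2[i] + 1e-12)
  }, numeric(1))
  expect_gt(mean(d[music$target_v1 != music$target_v2]), 0)
})

test_that("zero noise and zero lag make the report track the latent state", {
  cfg <- tiny_config(seed = 5, n_trials = 6L, report_lag = 0,
                     report_noise_sd = 0)
  sched <- generate_schedule(cfg)
  aff <- generate_affect(sched, cfg)
  # within music+reporting trials the joystick copies the latent state
  mr <- sched[sched$trial_type == "music_reporting", ]
  for (i in seq_len(nrow(mr))) {
    sel <- aff$latent$time >= mr$onset[i] & aff$latent$time < mr$onset[i] + 40
    expect_equal(aff$reported$valence[sel], aff$latent$valence[sel],
                 tolerance = 1e-12)
  }
})

test_that("reported traces are copied into music-only and replay trials", {
  cfg <- tiny_config(seed = 9, n_trials = 9L)
  sched <- generate_schedule(cfg)
  aff <- generate_affect(sched, cfg)
  mo <- sched[sched$trial_type == "music_only", ][1, ]
  mr <- sched[sched$trial_type == "music_reporting" &
                sched$stimulus_id == mo$stimulus_id, ][1, ]
  sel_mo <- which(aff$reported$time >= mo$onset &
                    aff$reported$time < mo$onset + 40)
  src_t <- aff$reported$time[sel_mo] - mo$onset + mr$onset
  src_v <- approx(aff$reported$time, aff$reported$valence, src_t,
                  rule = 2)$y
  # interpolation at the copy boundary leaves sub-report-noise residue
  expect_equal(aff$reported$valence[sel_mo], src_v, tolerance = 0.01)
})

test_that("EEG generation enforces Nyquist and scales with the valence gain", {
  cfg <- tiny_config(seed = 2, n_trials = 6L)
  sched <- generate_schedule(cfg)
  aff <- generate_affect(sched, cfg)
  cfg_bad <- cfg
  cfg_bad$eeg_rate <- 80
  expect_error(generate_eeg(aff$latent, sched, cfg_bad), "Nyquist")
})

test_that("constant extreme valence flips asymmetry sign with equal magnitude", {
  cfg <- tiny_config(seed = 13, n_trials = 6L, noise_sd_eeg = 0,
                     eeg_shared_frac = 1, entropy_mod = 0)
  sched <- generate_schedule(cfg)
  t <- seq(0, affectfuse:::schedule_end(sched) + 16, by = 0.1)
  band <- eeg_bands()$alpha
  asym_for <- function(v) {
    latent <- affect_trajectory(t, rep(v, length(t)), rep(0, length(t)),
                                kind = "latent")
    rec <- generate_eeg(latent, sched, cfg)
    mean(prefrontal_asymmetry(rec, band)$values)
  }
  a_pos <- asym_for(1)
  a_neg <- asym_for(-1)
  expect_gt(a_pos, 0)
  expect_equal(a_pos, -a_neg, tolerance = 1e-8)
})

test_that("zero valence gain leaves trial-mean asymmetry centred on zero", {
  # pooled over replicate studies: >= 200 music trials
  tms <- unlist(lapply(1:4, function(s) {
    cfg <- sim_config(seed = 100 + s, n_trials = 75L, eeg_rate = 100,
                      coupling = coupling_spec(
                        volume_shape = c(12L, 12L, 12L),
                        eeg_valence_gain = 0))
    sched <- generate_schedule(cfg)
    aff <- generate_affect(sched, cfg)
    rec <- generate_eeg(aff$latent, sched, cfg)
    asym <- prefrontal_asymmetry(rec, eeg_bands()$alpha)
    affectfuse:::trial_mean_asymmetry(asym, sched)
  }))
  expect_gte(length(tms), 200)
  ci <- t.test(tms)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("null BOLD is drift plus noise and movement ROIs track reporting", {
  shape <- c(7L, 7L, 7L)
  cs <- coupling_spec(volume_shape = shape,
                      amplitudes = c(valence = 0, arousal = 0,
                                     asymmetry = 0, entropy = 0,
                                     movement = 1))
  cfg <- sim_config(seed = 21, n_trials = 9L, eeg_rate = 100,
                    volume_shape = shape, coupling = cs)
  sched <- generate_schedule(cfg)
  aff <- generate_affect(sched, cfg)
  gb <- generate_bold(aff$latent, NULL, sched, cfg)
  n_vol <- dim(gb$bold$data)[4]
  boxcar <- affectfuse:::task_boxcar(sched, c("music_reporting",
                                              "reporting_only"), n_vol, 2)
  Y <- affectfuse:::as_voxel_matrix(gb$bold)
  mov <- which(gb$truth$roi_masks$movement)
  nullv <- which(gb$truth$roi_masks$null)
  cor_mov <- mean(abs(cor(Y[, mov], convolve_regressor(boxcar,
                                                       canonical_hrf(2)))))
  cor_null <- mean(abs(cor(Y[, nullv], convolve_regressor(boxcar,
                                                          canonical_hrf(2)))))
  expect_gt(cor_mov, 3 * cor_null)
})

test_that("identical seed and config give bit-identical datasets", {
  cfg <- tiny_config(seed = 31, n_trials = 6L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$eeg$samples, d2$eeg$samples)
  expect_identical(d1$bold$data, d2$bold$data)
  expect_identical(d1$reported, d2$reported)
  expect_identical(d1$schedule, d2$schedule)
})
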