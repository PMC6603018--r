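#' Circumplex region targets
#'
#' The stimulus set targets 9 regions of the valence-arousal circumplex:
#' the 3 x 3 grid of {low, neutral, high} valence crossed with {low,
#' neutral, high} arousal. Region `r` (1-9) maps to a (valence, arousal)
#' pair on a grid of half-width `extent`.
#'
#' @param region integer vector of region indices in 1..9.
#' @param extent half-width of the grid in circumplex units (default 2/3,
#'   keeping targets away from the hard [-1, 1] clip).
#' @return a two-column matrix with columns `valence`, `arousal`.
#' @export
circumplex_target <- function(region, extent = 2 / 3) {
  stopifnot(all(region %in% 1:9))
  lev <- c(-1, 0, 1) * extent
  cbind(valence = lev[(region - 1L) %% 3L + 1L],
        arousal = lev[(region - 1L) %/% 3L + 1L])
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic joint EEG + BOLD generator. The
#' defaults encode the study conditions: 40-s trials split into two 20-s
#' halves targeting different circumplex regions, three trial types
#' (music only / music + reporting / reporting only) in equal numbers,
#' TR = 2 s, and a 12^3 voxel grid at 3 mm isotropic resolution.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_trials total trial count; must be a multiple of 3 (the three
#'   trial types are balanced).
#' @param trial_duration trial length in seconds (must equal
#'   `2 * half_duration`).
#' @param half_duration length of one affect-target half, seconds.
#' @param eeg_rate EEG sampling rate, Hz. Must exceed 90 Hz so the 1-45 Hz
#'   analysis band is below Nyquist.
#' @param tr fMRI repetition time, seconds; `eeg_rate * tr` must be integer.
#' @param volume_shape integer triple of voxel grid dimensions.
#' @param channel_labels EEG channel names (10/20 system); must include
#'   F3, F4, FP1, FP2, F7, F8, Fz, C3, C4 (the Laplacian montage).
#' @param noise_sd_eeg white measurement noise SD per EEG channel, microvolts.
#' @param noise_sd_bold Gaussian noise SD per voxel per volume, BOLD units.
#' @param coupling a [coupling_spec()] describing ROI drivers and the EEG
#'   valence gain.
#' @param report_lag time constant of the joystick's first-order lag,
#'   seconds (the reported trace is a low-pass follower of felt affect).
#' @param report_noise_sd SD of additive report noise, circumplex units.
#' @param drift_order Legendre polynomial order of the slow scanner drift.
#' @param affect_rate sampling rate of the affect trajectories, Hz.
#' @param affect_noise_sd marginal SD of the AR(1) wander of latent affect.
#' @param affect_tau AR(1) correlation time of latent affect, seconds.
#' @param target_gain attenuation of the targeted circumplex state in the
#'   latent trajectory (music only partially induces its target; the
#'   default is calibrated so sub-trial target/report correlation is near
#'   the weak behavioural coupling of roughly r = 0.3).
#' @param band_amplitudes RMS amplitude (microvolts) of the four canonical
#'   band oscillations mixed into every channel.
#' @param eeg_shared_frac fraction of band variance shared between
#'   homologous left/right channel pairs (bilateral correlation).
#' @param entropy_mod amplitude scale of the slow within-trial gain
#'   wander whose strength grows as trial valence falls (makes
#'   low-valence asymmetry more disordered, hence higher Shannon
#'   entropy).
#' @param valence_scale steepness scale (circumplex units) of the
#'   valence dependence of that wander.
#' @param stim_frac fraction of the affective wander variance that is
#'   stimulus-locked (reproducible whenever the same excerpt plays).
#' @param driver_band band whose asymmetry/entropy drives coupled ROIs.
#' @param power_window,power_step band-power estimation window and step,
#'   seconds (step 2 s gives one power sample per TR).
#' @param entropy_window,entropy_step band-power window and step used
#'   for entropy analyses, seconds (shorter than the fusion window so
#'   each trial holds many fast power samples).
#' @param fixation,post_break fixation minimum and inter-trial break,
#'   seconds.
#' @param drift_sd SD of random per-voxel drift coefficients.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_trials = 36L,
                       trial_duration = 40,
                       half_duration = 20,
                       eeg_rate = 250,
                       tr = 2,
                       volume_shape = c(12L, 12L, 12L),
                       channel_labels = c("F3", "F4", "FP1", "FP2",
                                          "F7", "F8", "Fz", "C3", "C4"),
                       noise_sd_eeg = 1,
                       noise_sd_bold = 1,
                       coupling = coupling_spec(volume_shape = volume_shape),
                       report_lag = 1,
                       report_noise_sd = 0.05,
                       drift_order = 3L,
                       affect_rate = 10,
                       affect_noise_sd = 0.30,
                       affect_tau = 5,
                       target_gain = 0.122,
                       band_amplitudes = c(delta = 2, theta = 1.5,
                                           alpha = 2, beta = 1.2),
                       eeg_shared_frac = 0.9,
                       entropy_mod = 3,
                       valence_scale = 0.07,
                       stim_frac = 0.95,
                       driver_band = "alpha",
                       power_window = 2,
                       power_step = 2,
                       entropy_window = 1,
                       entropy_step = 0.25,
                       fixation = 1,
                       post_break = 0.5,
                       drift_sd = 0.3) {
  required <- c("F3", "F4", "FP1", "FP2", "F7", "F8", "Fz", "C3", "C4")
  if (missing(seed)) stop("sim_config() requires an explicit seed")
  if (trial_duration != 2 * half_duration) {
    stop("trial_duration must equal 2 * half_duration")
  }
  if (abs(eeg_rate * tr - round(eeg_rate * tr)) > 1e-9) {
    stop("eeg_rate * tr must be an integer number of samples per volume")
  }
  if (!all(required %in% channel_labels)) {
    stop("channel_labels must include: ",
         paste(setdiff(required, channel_labels), collapse = ", "))
  }
  if (report_lag < 0) stop("report_lag must be non-negative")
  if (length(volume_shape) != 3L) stop("volume_shape must be a triple")
  cfg <- list(seed = as.integer(seed), n_trials = as.integer(n_trials),
              trial_duration = trial_duration, half_duration = half_duration,
              eeg_rate = eeg_rate, tr = tr,
              volume_shape = as.integer(volume_shape),
              channel_labels = channel_labels,
              noise_sd_eeg = noise_sd_eeg, noise_sd_bold = noise_sd_bold,
              coupling = coupling, report_lag = report_lag,
              report_noise_sd = report_noise_sd,
              drift_order = as.integer(drift_order),
              affect_rate = affect_rate, affect_noise_sd = affect_noise_sd,
              affect_tau = affect_tau, target_gain = target_gain,
              band_amplitudes = band_amplitudes,
              eeg_shared_frac = eeg_shared_frac, entropy_mod = entropy_mod,
              valence_scale = valence_scale, stim_frac = stim_frac,
              driver_band = driver_band,
              power_window = power_window, power_step = power_step,
              entropy_window = entropy_window, entropy_step = entropy_step,
              fixation = fixation, post_break = post_break,
              drift_sd = drift_sd)
  class(cfg) <- "sim_config"
  cfg
}

#' Rectangular ROI mask
#'
#' @param corner 1-based voxel coordinate of the low corner.
#' @param size edge lengths in voxels.
#' @param volume_shape grid dimensions.
#' @return a logical array of dimension `volume_shape`.
#' @export
roi_block <- function(corner, size, volume_shape) {
  if (any(corner < 1L) || any(corner + size - 1L > volume_shape)) {
    stop("ROI block does not fit inside the volume")
  }
  m <- array(FALSE, dim = volume_shape)
  m[corner[1]:(corner[1] + size[1] - 1L),
    corner[2]:(corner[2] + size[2] - 1L),
    corner[3]:(corner[3] + size[3] - 1L)] <- TRUE
  m
}

#' ROI coupling specification
#'
#' Declares which voxel blocks are driven by which latent signal
#' (valence, arousal, asymmetry, entropy, or the reporting-movement
#' boxcar), at what amplitude, plus the EEG valence gain. A null ROI
#' (amplitude 0) is always retained for type-I error checks. Masks must
#' be pairwise disjoint.
#'
#' @param rois optional named list; each element a list with `driver`
#'   (one of `"valence"`, `"arousal"`, `"asymmetry"`, `"entropy"`,
#'   `"movement"`), `amplitude` (BOLD units per unit standardised
#'   driver), and `mask` (logical array). If `NULL`, a default layout of
#'   disjoint 2x2x2 blocks is built.
#' @param eeg_valence_gain fractional amplitude modulation of the shared
#'   prefrontal alpha/beta oscillation per unit latent valence (+ on the
#'   left, - on the right), so left-minus-right Laplacian band power
#'   grows with valence.
#' @param volume_shape voxel grid for the default layout.
#' @param amplitudes named amplitudes for the default layout's drivers.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(rois = NULL,
                          eeg_valence_gain = 0.6,
                          volume_shape = c(12L, 12L, 12L),
                          amplitudes = c(valence = 0.4, arousal = 0.4,
                                         asymmetry = 0.4, entropy = 0.4,
                                         movement = 0.8)) {
  if (is.null(rois)) {
    drivers <- c("valence", "arousal", "asymmetry", "entropy", "movement")
    # disjoint 2^3 blocks in opposite octants of the grid, plus a null block
    if (any(volume_shape < 7L)) stop("default ROI layout needs a >= 7^3 grid")
    s <- volume_shape - 2L
    anchors <- list(c(2L, 2L, 2L), c(2L, 2L, s[3]), c(2L, s[2], 2L),
                    c(s[1], 2L, 2L), c(s[1], s[2], s[3]),
                    c(s[1], s[2], 2L))
    rois <- list()
    for (i in seq_along(drivers)) {
      rois[[drivers[i]]] <- list(driver = drivers[i],
                                 amplitude = unname(amplitudes[drivers[i]]),
                                 mask = roi_block(anchors[[i]], c(2L, 2L, 2L),
                                                  volume_shape))
    }
    rois[["null"]] <- list(driver = "valence", amplitude = 0,
                           mask = roi_block(anchors[[6]], c(2L, 2L, 2L),
                                            volume_shape))
  }
  occ <- Reduce(`+`, lapply(rois, function(r) r$mask))
  if (any(occ > 1L)) stop("ROI masks must be pairwise disjoint")
  if (!any(vapply(rois, function(r) r$amplitude == 0, logical(1)))) {
    stop("coupling_spec must retain at least one null (amplitude 0) ROI")
  }
  amps <- vapply(rois, function(r) r$amplitude, numeric(1))
  if (!all(is.finite(amps))) stop("ROI amplitudes must be finite")
  structure(list(rois = rois, eeg_valence_gain = eeg_valence_gain),
            class = "coupling_spec")
}

#' Generate a pseudo-randomised trial schedule
#'
#' Builds the ordered trial list: equal numbers of the three trial types,
#' each stimulus appearing once as music-only, once as music+reporting,
#' and once as reporting-only, with the constraint that every
#' reporting-only trial is preceded (somewhere earlier in the session) by
#' the music+reporting trial of the same stimulus. Each trial carries two
#' 20-s circumplex targets (different regions), a uniform 0-2 s onset
#' jitter, and a >= 1 s fixation gap.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `trial_schedule` with columns `trial`,
#'   `onset`, `duration`, `trial_type`, `stimulus_id`, `target_region1`,
#'   `target_region2`, `target_v1`, `target_a1`, `target_v2`, `target_a2`,
#'   `jitter`.
#' @export
generate_schedule <- function(config) {
  n <- config$n_trials
  if (n < 3L || n %% 3L != 0L) {
    stop("n_trials must be a multiple of 3 and at least 3 ",
         "(three balanced trial types)")
  }
  set.seed(stage_seed(config$seed, "schedule"))
  n_stim <- n %/% 3L
  types <- rep(c("music_only", "music_reporting", "reporting_only"),
               each = n_stim)
  stim <- rep(seq_len(n_stim), times = 3L)
  ord <- sample.int(n)
  types <- types[ord]; stim <- stim[ord]
  # repair pass: every reporting_only must come after its music_reporting
  for (s in seq_len(n_stim)) {
    i_mr <- which(types == "music_reporting" & stim == s)
    i_ro <- which(types == "reporting_only" & stim == s)
    if (i_ro < i_mr) {  # swap positions
      types[c(i_mr, i_ro)] <- types[c(i_ro, i_mr)]
    }
  }
  # per-stimulus targets: two different circumplex regions (region set is
  # shared by the three presentations of a stimulus)
  r1 <- sample(1:9, n_stim, replace = TRUE)
  r2 <- vapply(r1, function(r) sample(setdiff(1:9, r), 1L), integer(1))
  jit <- stats::runif(n, 0, 2)
  onset <- numeric(n)
  t_cur <- 0
  for (i in seq_len(n)) {
    onset[i] <- t_cur + config$fixation + jit[i]
    t_cur <- onset[i] + config$trial_duration + config$post_break
  }
  tg1 <- circumplex_target(r1[stim])
  tg2 <- circumplex_target(r2[stim])
  sched <- data.frame(trial = seq_len(n), onset = onset,
                      duration = config$trial_duration,
                      trial_type = types, stimulus_id = stim,
                      target_region1 = r1[stim], target_region2 = r2[stim],
                      target_v1 = tg1[, "valence"], target_a1 = tg1[, "arousal"],
                      target_v2 = tg2[, "valence"], target_a2 = tg2[, "arousal"],
                      jitter = jit)
  attr(sched, "half_duration") <- config$half_duration
  class(sched) <- c("trial_schedule", "data.frame")
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  if (is.unsorted(sched$onset, strictly = TRUE)) {
    stop("trial onsets must be strictly increasing")
  }
  ends <- sched$onset + sched$duration
  if (any(sched$onset[-1] < ends[-length(ends)])) stop("trials overlap")
  for (i in which(sched$trial_type == "reporting_only")) {
    prior <- sched$trial_type[seq_len(i - 1L)] == "music_reporting" &
      sched$stimulus_id[seq_len(i - 1L)] == sched$stimulus_id[i]
    if (!any(prior)) {
      stop("reporting_only trial ", sched$trial[i],
           " is not preceded by a music_reporting trial of stimulus ",
           sched$stimulus_id[i])
    }
  }
  if (any(sched$jitter < 0 | sched$jitter > 2)) {
    stop("jitter must lie in [0, 2] s")
  }
  invisible(sched)
}

schedule_end <- function(sched) {
  max(sched$onset + sched$duration)
}

music_trials <- function(sched) {
  sched[sched$trial_type %in% c("music_only", "music_reporting"), ,
        drop = FALSE]
}

#' Generate latent and reported affect trajectories
#'
#' The latent trajectory is the attenuated per-half circumplex target
#' plus a smooth AR(1) wander (felt affect only loosely follows what the
#' music targets). The reported trajectory is the joystick record: a
#' first-order lag follower of the latent state during music+reporting
#' trials, copied into the matching music-only trials (as in the analysis
#' convention for trials without reporting), a noisy re-tracking of the
#' earlier record during reporting-only replays, and a relaxation to the
#' neutral rest position between trials. Both are clipped to [-1, 1].
#'
#' @param schedule a `trial_schedule`.
#' @param config the [sim_config()].
#' @return list with elements `latent` and `reported`, each an
#'   `affect_trajectory` (data.frame: `time`, `valence`, `arousal`) with a
#'   `kind` attribute.
#' @export
generate_affect <- function(schedule, config) {
  if (config$report_lag < 0) stop("report_lag must be non-negative")
  set.seed(stage_seed(config$seed, "affect"))
  dt <- 1 / config$affect_rate
  t_end <- schedule_end(schedule) + 16  # tail for the HRF to play out
  times <- seq(0, t_end, by = dt)
  nt <- length(times)
  half <- config$half_duration

  target_series <- function(col1, col2) {
    out <- numeric(nt)
    music <- schedule[schedule$trial_type != "reporting_only", , drop = FALSE]
    for (i in seq_len(nrow(music))) {
      on <- music$onset[i]
      h1 <- times >= on & times < on + half
      h2 <- times >= on + half & times < on + 2 * half
      out[h1] <- music[[col1]][i]
      out[h2] <- music[[col2]][i]
    }
    out
  }
  ar1 <- function(n, sd_marg, tau) {
    phi <- exp(-dt / tau)
    e <- stats::rnorm(n, 0, sd_marg * sqrt(1 - phi^2))
    as.numeric(stats::filter(e, phi, method = "recursive"))
  }
  # the affective wander splits into a stimulus-locked response (the music
  # drives the same trajectory whenever the same excerpt plays, which is
  # what licenses copying reports into music-only trials) and an
  # idiosyncratic remainder
  stim_frac <- config$stim_frac %||% 0.7
  sd_stim <- config$affect_noise_sd * sqrt(stim_frac)
  sd_idio <- config$affect_noise_sd * sqrt(1 - stim_frac)
  n_trial_samp <- length(seq(0, 2 * half, by = dt))
  stim_ids <- sort(unique(schedule$stimulus_id))
  stim_resp <- lapply(stim_ids, function(s) {
    list(v = ar1(n_trial_samp, sd_stim, config$affect_tau),
         a = ar1(n_trial_samp, sd_stim, config$affect_tau))
  })
  names(stim_resp) <- as.character(stim_ids)
  lat_v <- config$target_gain * target_series("target_v1", "target_v2") +
    ar1(nt, sd_idio, config$affect_tau)
  lat_a <- config$target_gain * target_series("target_a1", "target_a2") +
    ar1(nt, sd_idio, config$affect_tau)
  for (i in which(schedule$trial_type != "reporting_only")) {
    idx <- which(times >= schedule$onset[i] &
                   times < schedule$onset[i] + 2 * half)
    k <- pmin(round((times[idx] - schedule$onset[i]) / dt) + 1L, n_trial_samp)
    resp <- stim_resp[[as.character(schedule$stimulus_id[i])]]
    lat_v[idx] <- lat_v[idx] + resp$v[k]
    lat_a[idx] <- lat_a[idx] + resp$a[k]
  }
  lat_v <- clip01(lat_v)
  lat_a <- clip01(lat_a)

  lag_filter <- function(x) {
    if (config$report_lag == 0) return(x)
    a <- exp(-dt / config$report_lag)
    as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  }
  rep_v <- lag_filter(lat_v) + stats::rnorm(nt, 0, config$report_noise_sd)
  rep_a <- lag_filter(lat_a) + stats::rnorm(nt, 0, config$report_noise_sd)

  # joystick is only live during reporting trials; fill the gaps/replays
  in_trial <- function(on) times >= on & times < on + 2 * half
  live <- rep(FALSE, nt)
  for (i in which(schedule$trial_type == "music_reporting")) {
    live <- live | in_trial(schedule$onset[i])
  }
  # music_only: copy the record from the same stimulus' music_reporting trial
  for (i in which(schedule$trial_type == "music_only")) {
    src <- which(schedule$trial_type == "music_reporting" &
                   schedule$stimulus_id == schedule$stimulus_id[i])[1]
    idx <- which(in_trial(schedule$onset[i]))
    src_t <- times[idx] - schedule$onset[i] + schedule$onset[src]
    rep_v[idx] <- interp_series(times, rep_v, src_t)
    rep_a[idx] <- interp_series(times, rep_a, src_t)
    live[idx] <- TRUE
  }
  # reporting_only: noisy re-tracking of the replayed earlier record
  for (i in which(schedule$trial_type == "reporting_only")) {
    src <- which(schedule$trial_type == "music_reporting" &
                   schedule$stimulus_id == schedule$stimulus_id[i])[1]
    idx <- which(in_trial(schedule$onset[i]))
    src_t <- times[idx] - schedule$onset[i] + schedule$onset[src]
    rep_v[idx] <- interp_series(times, rep_v, src_t) +
      stats::rnorm(length(idx), 0, config$report_noise_sd)
    rep_a[idx] <- interp_series(times, rep_a, src_t) +
      stats::rnorm(length(idx), 0, config$report_noise_sd)
    live[idx] <- TRUE
  }
  # between trials the joystick relaxes to neutral
  if (config$report_lag > 0) {
    relax <- exp(-dt / config$report_lag)
    for (k in which(!live)) {
      prev <- if (k == 1L) 0 else c(rep_v[k - 1L], rep_a[k - 1L])
      if (k == 1L) { rep_v[k] <- 0; rep_a[k] <- 0 }
      else { rep_v[k] <- prev[1] * relax; rep_a[k] <- prev[2] * relax }
    }
  } else {
    rep_v[!live] <- 0; rep_a[!live] <- 0
  }
  rep_v <- clip01(rep_v); rep_a <- clip01(rep_a)

  latent <- affect_trajectory(times, lat_v, lat_a, kind = "latent")
  reported <- affect_trajectory(times, rep_v, rep_a, kind = "reported")
  list(latent = latent, reported = reported)
}

#' Construct an affect trajectory
#'
#' @param time uniformly spaced sample times, seconds.
#' @param valence,arousal values in [-1, 1].
#' @param kind `"latent"` or `"reported"`.
#' @return an `affect_trajectory` data frame.
#' @export
affect_trajectory <- function(time, valence, arousal,
                              kind = c("latent", "reported")) {
  kind <- match.arg(kind)
  if (any(abs(valence) > 1 + 1e-9) || any(abs(arousal) > 1 + 1e-9)) {
    stop("affect values must lie in [-1, 1]")
  }
  dt <- diff(time)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("affect trajectory times must be uniformly spaced")
  }
  out <- data.frame(time = time, valence = valence, arousal = arousal)
  attr(out, "kind") <- kind
  class(out) <- c("affect_trajectory", "data.frame")
  out
}

# band-limited unit-RMS Gaussian oscillation, synthesised in the Fourier
# domain: independent complex-Gaussian coefficients on the in-band bins
# (flat spectrum inside the band, zero outside), Hermitian-symmetrised
band_noise <- function(n, rate, low, high) {
  m <- stats::nextn(n)
  half <- seq(2L, m %/% 2L)  # positive-frequency bins, DC excluded
  f <- (half - 1L) * rate / m
  lo <- max(low, 0.5)
  sel <- half[f >= lo & f <= high]
  X <- complex(m)
  X[sel] <- complex(real = stats::rnorm(length(sel)),
                    imaginary = stats::rnorm(length(sel)))
  X[m + 2L - sel] <- Conj(X[sel])
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  y / stats::sd(y)
}

#' Generate a multichannel EEG recording coupled to latent valence
#'
#' Each channel is a mixture of band-limited delta/theta/alpha/beta
#' oscillations plus white noise. Homologous left/right pairs share a
#' bilateral oscillation component. The shared prefrontal alpha and beta
#' components at F3 (left) and F4 (right) are amplitude-modulated by
#' `(1 +/- g * m(t))` where `g` is the EEG valence gain and
#' `m(t) = v(t) + s(v) eta(t)`: the modulation follows latent valence, and
#' its jitter SD `s(v)` grows as valence falls, so low-valence asymmetry
#' is more disordered (higher Shannon entropy).
#'
#' @param latent latent `affect_trajectory`.
#' @param schedule the `trial_schedule` (span checking only).
#' @param config the [sim_config()].
#' @return an [eeg_recording()].
#' @export
generate_eeg <- function(latent, schedule, config) {
  rate <- config$eeg_rate
  if (rate <= 90) {
    stop("eeg_rate must exceed 90 Hz (Nyquist for the 1-45 Hz band)")
  }
  set.seed(stage_seed(config$seed, "eeg"))
  t_end <- max(latent$time)
  times <- seq(0, t_end, by = 1 / rate)
  n <- length(times)
  v <- interp_series(latent$time, latent$valence, times)
  g <- config$coupling$eeg_valence_gain
  bands <- eeg_bands()
  amps <- config$band_amplitudes
  labels <- config$channel_labels
  pairs <- list(c("FP1", "FP2"), c("F7", "F8"), c("C3", "C4"), c("F3", "F4"))
  h <- config$eeg_shared_frac

  # within-trial instability of the asymmetry operating point: a slow
  # oscillatory gain wander (random phase and period near the trial
  # length), demeaned over each trial so it spreads the asymmetry's
  # within-trial state occupancy (raising its Shannon entropy) without
  # moving the trial mean; its amplitude s(v) grows steeply as the
  # trial's valence falls, so low-valence trials are the disordered ones
  m <- v
  vscale <- config$valence_scale %||% 0.15
  for (i in seq_len(nrow(schedule))) {
    idx <- which(times >= schedule$onset[i] &
                   times < schedule$onset[i] + schedule$duration[i])
    if (!length(idx)) next
    vbar <- mean(v[idx])
    s <- config$entropy_mod * stats::plogis(-vbar / vscale)
    # linear drift of the operating point (random direction): its state
    # occupancy is uniform, the maximally disordered histogram
    ramp <- (times[idx] - schedule$onset[i]) / schedule$duration[i] - 0.5
    sgn <- sample(c(-1, 1), 1)
    m[idx] <- m[idx] + s * sgn * (ramp - mean(ramp))
  }

  X <- matrix(0, nrow = length(labels), ncol = n,
              dimnames = list(labels, NULL))
  for (b in names(bands)) {
    band <- bands[[b]]
    shared <- list()
    for (p in seq_along(pairs)) {
      shared[[p]] <- band_noise(n, rate, band$low, band$high)
    }
    modulate <- b %in% c("alpha", "beta")
    for (ch in labels) {
      own <- band_noise(n, rate, band$low, band$high)
      p <- which(vapply(pairs, function(pp) ch %in% pp, logical(1)))
      if (length(p) == 1L) {
        base <- shared[[p]]
        if (modulate && pairs[[p]][1] == "F3") {
          side <- if (ch == "F3") 1 else -1
          base <- base * (1 + side * g * m)
        }
        comp <- sqrt(h) * base + sqrt(1 - h) * own
      } else {
        comp <- own
      }
      X[ch, ] <- X[ch, ] + amps[[b]] * comp
    }
  }
  if (config$noise_sd_eeg > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd_eeg),
                    nrow = nrow(X))
  }
  eeg_recording(X, rate, labels)
}

#' Generate coupled 4-D BOLD data with ground truth
#'
#' Each coupled ROI's time course is `amplitude` times the HRF-convolved,
#' standardised driver (latent valence, latent arousal, the band
#' asymmetry regressor, the per-trial entropy regressor, or the
#' reporting-movement boxcar that is on during music+reporting and
#' reporting-only trials), plus Legendre drift and Gaussian noise. Null
#' voxels carry drift and noise only.
#'
#' @param latent latent `affect_trajectory`.
#' @param eeg_features list with elements `asymmetry` (an
#'   `asymmetry_series` for the driver band) and `entropy_regressor`
#'   (series at the asymmetry rate), as produced inside
#'   [simulate_dataset()]; may be `NULL` when no ROI uses them.
#' @param schedule the `trial_schedule`.
#' @param config the [sim_config()].
#' @return list with `bold` (a [bold_series()]) and `truth` (ROI masks by
#'   driver, amplitudes, drivers at the TR grid, seed).
#' @export
generate_bold <- function(latent, eeg_features, schedule, config) {
  set.seed(stage_seed(config$seed, "bold"))
  tr <- config$tr
  shape <- config$volume_shape
  n_vol <- floor(max(latent$time) / tr)
  t_mid <- (seq_len(n_vol) - 0.5) * tr
  rois <- config$coupling$rois
  occ <- Reduce(`+`, lapply(rois, function(r) r$mask))
  if (any(occ > 1L)) stop("overlapping ROI masks")
  if (!all(dim(occ) == shape)) stop("ROI masks do not fit volume_shape")

  live <- vapply(rois, function(r) r$amplitude != 0, logical(1))
  drivers_needed <- unique(vapply(rois[live], function(r) r$driver,
                                  character(1)))
  driver <- list()
  if ("valence" %in% drivers_needed) {
    driver$valence <- interp_series(latent$time, latent$valence, t_mid)
  }
  if ("arousal" %in% drivers_needed) {
    driver$arousal <- interp_series(latent$time, latent$arousal, t_mid)
  }
  if ("asymmetry" %in% drivers_needed) {
    driver$asymmetry <- build_asymmetry_regressor(eeg_features$asymmetry,
                                                  fmri_start = 0,
                                                  n_volumes = n_vol, tr = tr)
  }
  if ("entropy" %in% drivers_needed) {
    er <- eeg_features$entropy_regressor
    driver$entropy <- interp_series(er$times, er$values, t_mid)
  }
  if ("movement" %in% drivers_needed) {
    mv <- rep(0, n_vol)
    rep_tr <- schedule[schedule$trial_type %in%
                         c("music_reporting", "reporting_only"), , drop = FALSE]
    for (i in seq_len(nrow(rep_tr))) {
      mv[t_mid >= rep_tr$onset[i] &
           t_mid < rep_tr$onset[i] + rep_tr$duration[i]] <- 1
    }
    driver$movement <- mv
  }
  hrf <- canonical_hrf(dt = tr)
  signal_for <- function(name) {
    x <- driver[[name]]
    s <- stats::sd(x)
    if (s > 0) x <- (x - mean(x)) / s
    convolve_regressor(x, hrf)
  }
  sig <- lapply(stats::setNames(drivers_needed, drivers_needed), signal_for)

  n_vox <- prod(shape)
  Y <- matrix(stats::rnorm(n_vol * n_vox, 0, config$noise_sd_bold),
              nrow = n_vol)
  if (config$drift_order > 0 && config$drift_sd > 0) {
    L <- legendre_basis(n_vol, config$drift_order)[, -1, drop = FALSE]
    coefs <- matrix(stats::rnorm(ncol(L) * n_vox, 0, config$drift_sd),
                    nrow = ncol(L))
    Y <- Y + L %*% coefs
  }
  Y <- Y + 100  # baseline
  for (r in rois) {
    if (r$amplitude == 0) next
    idx <- which(r$mask)
    Y[, idx] <- Y[, idx] + r$amplitude * sig[[r$driver]]
  }
  data4d <- array(t(Y), dim = c(shape, n_vol))
  bold <- bold_series(data4d, tr = tr,
                      affine = diag(c(3, 3, 3, 1)))
  truth <- list(roi_masks = lapply(rois, function(r) r$mask),
                drivers = lapply(rois, function(r) r$driver),
                amplitudes = lapply(rois, function(r) r$amplitude),
                driver_series = sig,
                eeg_valence_gain = config$coupling$eeg_valence_gain,
                latent = latent, seed = config$seed)
  list(bold = bold, truth = truth)
}

#' Simulate a complete joint EEG-fMRI dataset
#'
#' Runs the full generative chain: schedule, latent and reported affect,
#' valence-coupled EEG, driver-band asymmetry features, and coupled BOLD,
#' all from one seed. Identical `config` (including seed) gives a
#' bit-identical dataset.
#'
#' @param config a [sim_config()].
#' @return an object of class `affect_dataset`: list with `config`,
#'   `schedule`, `latent`, `reported`, `eeg`, `features` (driver-band
#'   asymmetry, entropy table, entropy regressor), `bold`, `truth`.
#' @export
simulate_dataset <- function(config) {
  schedule <- generate_schedule(config)
  aff <- generate_affect(schedule, config)
  eeg <- generate_eeg(aff$latent, schedule, config)
  feats <- dataset_features(eeg, schedule, config)
  gb <- generate_bold(aff$latent, feats, schedule, config)
  structure(list(config = config, schedule = schedule,
                 latent = aff$latent, reported = aff$reported,
                 eeg = eeg, features = feats,
                 bold = gb$bold, truth = gb$truth),
            class = "affect_dataset")
}

# driver-band features used by the generator and by fusion ground truth
dataset_features <- function(eeg, schedule, config) {
  band <- eeg_bands()[[config$driver_band]]
  asym <- prefrontal_asymmetry_bands(eeg, list(band),
                                     window = config$power_window,
                                     steps = config$power_step)[[1]][[1]]
  asym_fine <- prefrontal_asymmetry_bands(eeg, list(band),
                                          window = config$entropy_window,
                                          steps = config$entropy_step)[[1]][[1]]
  ent_tab <- trial_entropy(asym_fine, schedule)
  ent_reg <- entropy_regressor_series(asym_fine, schedule,
                                      mode = "per_trial_boxcar")
  list(asymmetry = asym, asymmetry_fine = asym_fine,
       entropy_table = ent_tab, entropy_regressor = ent_reg,
       band = band)
}

#' @export
print.affect_dataset <- function(x, ...) {
  cat("Synthetic joint EEG-fMRI dataset\n")
  cat(sprintf("  trials: %d (%s)\n", nrow(x$schedule),
              paste(names(table(x$schedule$trial_type)), collapse = "/")))
  cat(sprintf("  EEG: %d channels @ %g Hz, %.0f s\n",
              nrow(x$eeg$samples), x$eeg$rate,
              ncol(x$eeg$samples) / x$eeg$rate))
  d <- dim(x$bold$data)
  cat(sprintf("  BOLD: %dx%dx%d voxels, %d volumes, TR %g s\n",
              d[1], d[2], d[3], d[4], x$bold$tr))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}
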