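#' EEG recording container
#'
#' @param samples channel x time numeric matrix, microvolts.
#' @param rate sampling rate, Hz.
#' @param labels channel labels (10/20 names), unique, one per row.
#' @param reference `"as_recorded"` or `"CAR"`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, labels,
                          reference = c("as_recorded", "CAR")) {
  reference <- match.arg(reference)
  samples <- as.matrix(samples)
  if (nrow(samples) != length(labels)) {
    stop("one label per channel row is required")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(is.finite(samples))) stop("EEG samples must be finite")
  if (rate <= 0) stop("rate must be positive")
  rownames(samples) <- labels
  structure(list(samples = samples, rate = rate, labels = labels,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$reference))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Canonical frequency band definitions
#'
#' Delta 0-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta 13-20 Hz. The delta
#' band is effectively 1-4 Hz after the 1 Hz broadband high-pass.
#'
#' @return named list of `band_definition` objects (`name`, `low`, `high`).
#' @export
eeg_bands <- function() {
  mk <- function(name, low, high) {
    structure(list(name = name, low = low, high = high),
              class = "band_definition")
  }
  list(delta = mk("delta", 0, 4), theta = mk("theta", 4, 8),
       alpha = mk("alpha", 8, 12), beta = mk("beta", 13, 20))
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over all channels from every channel,
#' so the channel mean of the output is zero at each sample.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced recording (`reference = "CAR"`).
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2L) {
    stop("common average reference needs at least 2 channels")
  }
  mu <- colMeans(rec$samples)
  out <- sweep(rec$samples, 2L, mu)
  eeg_recording(out, rec$rate, rec$labels, reference = "CAR")
}

# zero-phase 3rd-order Butterworth helper (effective order 6 after the
# forward-backward pass)
butter_filtfilt <- function(x, rate, low, high, order = 3) {
  ny <- rate / 2
  if (high >= ny) stop("band edge ", high, " Hz is at or above Nyquist (",
                       ny, " Hz)")
  bf <- if (low <= 0) {
    signal::butter(order, high / ny, type = "low")
  } else {
    signal::butter(order, c(low, high) / ny, type = "pass")
  }
  signal::filtfilt(bf, x)
}

#' Broadband 1-45 Hz filter
#'
#' Zero-phase band-pass (3rd-order Butterworth, forward-backward) applied
#' per channel.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges, Hz.
#' @return the filtered recording.
#' @export
broadband_filter <- function(rec, low = 1, high = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * high) {
    stop("sampling rate ", rec$rate, " Hz too low for a ", high,
         " Hz band edge (Nyquist violation)")
  }
  out <- t(apply(rec$samples, 1L, butter_filtfilt,
                 rate = rec$rate, low = low, high = high))
  eeg_recording(out, rec$rate, rec$labels, reference = rec$reference)
}

#' Laplacian derivation
#'
#' Local spatial filter: the centre channel minus the mean of its
#' reference channels. The prefrontal montages used for asymmetry are F3
#' referenced to FP1, F7, Fz, C3 and F4 referenced to FP2, F8, Fz, C4.
#'
#' @param rec an [eeg_recording()].
#' @param centre centre channel label.
#' @param references reference channel labels (must not include `centre`).
#' @return numeric time series, microvolts.
#' @export
laplacian_derivation <- function(rec, centre, references) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (centre %in% references) stop("centre channel cannot be its own reference")
  missing <- setdiff(c(centre, references), rec$labels)
  if (length(missing)) {
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  }
  ref <- colMeans(rec$samples[references, , drop = FALSE])
  as.numeric(rec$samples[centre, ] - ref)
}

#' Default prefrontal Laplacian montages
#' @return list with `left` and `right` montages (`centre`, `references`).
#' @export
prefrontal_montages <- function() {
  list(left = list(centre = "F3", references = c("FP1", "F7", "Fz", "C3")),
       right = list(centre = "F4", references = c("FP2", "F8", "Fz", "C4")))
}

#' Windowed band-power time series
#'
#' Band-passes the series to `[band$low, band$high]` (3rd-order
#' Butterworth, zero-phase; a zero lower edge becomes a low-pass, the
#' broadband 1 Hz high-pass having already removed DC), then takes the
#' mean squared amplitude over sliding windows.
#'
#' @param x numeric time series (a Laplacian derivation), microvolts.
#' @param rate sampling rate of `x`, Hz.
#' @param band a `band_definition` from [eeg_bands()].
#' @param window window length, seconds.
#' @param step hop between window starts, seconds; the output rate is
#'   `1/step`.
#' @return list of class `power_series`: `times` (window centres, s),
#'   `values` (mean square, uV^2), `rate` (1/step), `band`.
#' @export
bandpower_series <- function(x, rate, band, window = 2, step = 2) {
  if (step <= 0) stop("step must be positive")
  need <- if (band$low > 0) 2 / band$low else 1
  if (window < need) {
    stop(sprintf("window must be at least %.2f s for the %s band",
                 need, band$name))
  }
  wn <- round(window * rate)
  if (wn > length(x)) stop("window longer than the series")
  xf <- butter_filtfilt(x, rate, band$low, band$high)
  windowed_power(xf, rate, band, window, step)
}

# sliding mean-square over an already band-filtered series, via a
# cumulative sum so the cost is independent of the window length
windowed_power <- function(xf, rate, band, window, step) {
  wn <- round(window * rate)
  sn <- round(step * rate)
  cs <- c(0, cumsum(xf^2))
  starts <- seq(1L, length(xf) - wn + 1L, by = sn)
  vals <- (cs[starts + wn] - cs[starts]) / wn
  structure(list(times = (starts - 1L) / rate + window / 2,
                 values = vals, rate = 1 / step, band = band),
            class = "power_series")
}

#' Left-minus-right asymmetry series
#'
#' @param left_power,right_power `power_series` of equal length and rate
#'   (left and right prefrontal Laplacian band power).
#' @return an `asymmetry_series`: `times`, `values` (uV^2), `rate`, `band`.
#' @export
asymmetry_series <- function(left_power, right_power) {
  if (length(left_power$values) != length(right_power$values)) {
    stop("left and right power series differ in length")
  }
  if (abs(left_power$rate - right_power$rate) > 1e-9) {
    stop("left and right power series differ in rate")
  }
  structure(list(times = left_power$times,
                 values = left_power$values - right_power$values,
                 rate = left_power$rate, band = left_power$band),
            class = "asymmetry_series")
}

#' Prefrontal asymmetry pipeline
#'
#' Convenience chain: common average reference, 1-45 Hz broadband filter,
#' F3/F4 Laplacian derivations, band filtering with windowed power, and
#' the left-minus-right difference. [prefrontal_asymmetry_bands()]
#' computes several bands (and optionally several power steps) from a
#' single pass through the shared reference/filter/Laplacian stages.
#'
#' @param rec an [eeg_recording()].
#' @param band a `band_definition`.
#' @param window,step band-power window and step, seconds.
#' @return an `asymmetry_series`.
#' @export
prefrontal_asymmetry <- function(rec, band, window = 2, step = 2) {
  prefrontal_asymmetry_bands(rec, list(band), window, step)[[1]][[1]]
}

#' @rdname prefrontal_asymmetry
#' @param bands list of band definitions.
#' @param steps numeric vector of power steps, seconds.
#' @param measure `"power"` (mean-squared amplitude, uV^2, the default)
#'   or `"amplitude"` (its square root, uV) before the left-right
#'   difference.
#' @return for `prefrontal_asymmetry_bands`, a nested list indexed by
#'   band then by step.
#' @export
prefrontal_asymmetry_bands <- function(rec, bands, window = 2, steps = 2,
                                       measure = c("power", "amplitude")) {
  measure <- match.arg(measure)
  rec <- common_average_reference(rec)
  rec <- broadband_filter(rec)
  m <- prefrontal_montages()
  left <- laplacian_derivation(rec, m$left$centre, m$left$references)
  right <- laplacian_derivation(rec, m$right$centre, m$right$references)
  out <- lapply(bands, function(band) {
    lf <- butter_filtfilt(left, rec$rate, band$low, band$high)
    rf <- butter_filtfilt(right, rec$rate, band$low, band$high)
    lapply(steps, function(step) {
      lp <- windowed_power(lf, rec$rate, band, window, step)
      rp <- windowed_power(rf, rec$rate, band, window, step)
      if (measure == "amplitude") {
        lp$values <- sqrt(lp$values)
        rp$values <- sqrt(rp$values)
      }
      asymmetry_series(lp, rp)
    })
  })
  names(out) <- vapply(bands, function(b) b$name, character(1))
  out
}

# mean asymmetry within each trial's span
trial_mean_asymmetry <- function(asym, schedule,
                                 types = c("music_only", "music_reporting")) {
  keep <- schedule[schedule$trial_type %in% types, , drop = FALSE]
  vapply(seq_len(nrow(keep)), function(i) {
    sel <- asym$times >= keep$onset[i] &
      asym$times < keep$onset[i] + keep$duration[i]
    if (!any(sel)) stop("trial ", keep$trial[i],
                        " has no asymmetry samples in its span")
    mean(asym$values[sel])
  }, numeric(1))
}
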