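#' Shannon entropy of a signal's state occupancy
#'
#' Discretises `values` into `n_bins` equal-width bins spanning their
#' range (or the supplied `edges`) and returns
#' `H = -sum P log2 P` in bits, with `0 * log2(0)` defined as 0. Larger
#' entropy means greater disorder of the series' states. A constant
#' series occupies a single bin and has 0 bits.
#'
#' @param values numeric samples (at least 2).
#' @param n_bins number of equal-width bins (at least 2) when `edges` is
#'   not supplied.
#' @param edges optional explicit bin edges (ascending, length >= 3).
#' @return an object of class `entropy_estimate`: `value` (bits),
#'   `n_samples`, `n_bins`, `bin_edges`, `probs`.
#' @export
shannon_entropy <- function(values, n_bins = 16L, edges = NULL) {
  if (length(values) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(values))) stop("values must be finite")
  if (is.null(edges)) {
    if (n_bins < 2L) stop("n_bins must be at least 2")
    rng <- range(values)
    if (rng[1] == rng[2]) {
      # degenerate: one occupied state, zero entropy by convention
      est <- list(value = 0, n_samples = length(values), n_bins = 1L,
                  bin_edges = c(rng[1] - 0.5, rng[1] + 0.5), probs = 1)
      class(est) <- "entropy_estimate"
      return(est)
    }
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  } else {
    if (is.unsorted(edges, strictly = TRUE)) {
      stop("edges must be strictly increasing")
    }
    n_bins <- length(edges) - 1L
  }
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  nz <- p > 0
  H <- -sum(p[nz] * log2(p[nz]))
  structure(list(value = H, n_samples = length(values),
                 n_bins = as.integer(n_bins), bin_edges = edges, probs = p),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("Shannon entropy: %.4f bits (%d samples, %d bins, max %.2f)\n",
              x$value, x$n_samples, x$n_bins, log2(max(x$n_bins, 2L))))
  invisible(x)
}

#' Per-trial Shannon entropy of the asymmetry series
#'
#' One entropy estimate per music-listening trial (music-only and
#' music+reporting). By default all trials share one state alphabet:
#' equal-width bins spanning the pooled range of asymmetry values over
#' the music trials, so that H directly measures how many asymmetry
#' states a trial visits and trials are comparable on a common scale. A
#' disordered trial that wanders across many states scores high; a trial
#' pinned near one level scores low. `edges = "per_trial"` instead bins
#' each trial over its own range (scale-free occupancy shape).
#'
#' @param asym an `asymmetry_series` (use a fine power step, e.g. 0.25 s,
#'   so each trial holds enough samples for a stable histogram).
#' @param schedule the `trial_schedule`.
#' @param n_bins number of bins (default 16).
#' @param edges `"common"` (default), `"per_trial"`, or an explicit
#'   numeric edge vector.
#' @return data.frame: `trial_id`, `band`, `entropy_bits`, `n_samples`,
#'   `n_bins`.
#' @export
trial_entropy <- function(asym, schedule, n_bins = 16L, edges = "common") {
  keep <- music_trials(schedule)
  in_trial <- lapply(seq_len(nrow(keep)), function(i) {
    which(asym$times >= keep$onset[i] &
            asym$times < keep$onset[i] + keep$duration[i])
  })
  short <- vapply(in_trial, length, integer(1)) < 2L
  if (any(short)) {
    stop("trial ", keep$trial[which(short)[1]],
         " has fewer than 2 asymmetry samples; use a finer power step")
  }
  bin_edges <- if (is.numeric(edges)) {
    edges
  } else if (identical(edges, "common")) {
    rng <- range(asym$values[unlist(in_trial)])
    if (rng[1] == rng[2]) NULL else seq(rng[1], rng[2],
                                        length.out = n_bins + 1L)
  } else if (identical(edges, "per_trial")) {
    NULL
  } else stop("edges must be 'common', 'per_trial' or a numeric vector")
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    est <- shannon_entropy(asym$values[in_trial[[i]]], n_bins = n_bins,
                           edges = bin_edges)
    data.frame(trial_id = keep$trial[i], band = asym$band$name,
               entropy_bits = est$value, n_samples = est$n_samples,
               n_bins = est$n_bins)
  })
  do.call(rbind, rows)
}

#' Entropy regressor series at the asymmetry rate
#'
#' Temporal embedding of asymmetry entropy for the fusion GLM. In
#' `per_trial_boxcar` mode each music-listening trial's span carries that
#' trial's entropy and non-trial spans carry 0 (the entropy was computed
#' per trial, and a boxcar is its faithful embedding). With `center =
#' TRUE` (the default) the embedded value is the trial entropy minus the
#' session mean across music trials: what remains encodes entropy
#' modulation, whereas a raw embedding is dominated by the music-on/off
#' structure and would alias the task boxcar. In `sliding_window` mode a
#' trailing-window entropy is computed at every power sample.
#'
#' @param asym an `asymmetry_series`.
#' @param schedule the `trial_schedule`.
#' @param mode `"per_trial_boxcar"` or `"sliding_window"`.
#' @param window trailing window length for sliding mode, seconds (must
#'   cover at least 4 power samples).
#' @param n_bins histogram bins.
#' @param center subtract the across-trial mean entropy in boxcar mode.
#' @return list: `times`, `values` (bits), `rate`.
#' @export
entropy_regressor_series <- function(asym, schedule,
                                     mode = c("per_trial_boxcar",
                                              "sliding_window"),
                                     window = 20, n_bins = 16L,
                                     center = TRUE) {
  mode <- match.arg(mode)
  values <- numeric(length(asym$times))
  if (mode == "per_trial_boxcar") {
    tab <- trial_entropy(asym, schedule, n_bins = n_bins)
    ent <- tab$entropy_bits
    if (center) ent <- ent - mean(ent)
    keep <- music_trials(schedule)
    for (i in seq_len(nrow(keep))) {
      sel <- asym$times >= keep$onset[i] &
        asym$times < keep$onset[i] + keep$duration[i]
      values[sel] <- ent[tab$trial_id == keep$trial[i]]
    }
  } else {
    wn <- round(window * asym$rate)
    if (wn < 4L) stop("sliding window must cover at least 4 power samples")
    for (k in seq_along(values)) {
      lo <- max(1L, k - wn + 1L)
      if (k - lo + 1L >= 2L) {
        values[k] <- shannon_entropy(asym$values[lo:k], n_bins = n_bins)$value
      }
    }
  }
  list(times = asym$times, values = values, rate = asym$rate)
}
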