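# Shared fixtures, built in code. Heavy simulated objects are memoised
# for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

required_channels <- function() {
  c("F3", "F4", "FP1", "FP2", "F7", "F8", "Fz", "C3", "C4")
}

# small fast study configuration used across unit tests
tiny_config <- function(seed = 7L, n_trials = 9L, ...) {
  sim_config(seed = seed, n_trials = n_trials, eeg_rate = 100,
             volume_shape = c(7L, 7L, 7L),
             coupling = coupling_spec(volume_shape = c(7L, 7L, 7L)), ...)
}

tiny_dataset <- function() {
  memo("tiny_dataset", simulate_dataset(tiny_config()))
}

# a deterministic multichannel recording with known content
sine_recording <- function(rate = 100, dur = 20, freqs = NULL) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  labels <- required_channels()
  freqs <- freqs %||% seq(2, 18, length.out = length(labels))
  samples <- t(vapply(freqs, function(f) sin(2 * pi * f * t), numeric(length(t))))
  eeg_recording(samples, rate, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-sample KS statistic: scan every pooled sample point
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# independent histogram-entropy oracle (explicit loops, no tabulate)
entropy_oracle <- function(x, edges) {
  k <- length(edges) - 1L
  counts <- numeric(k)
  for (v in x) {
    for (j in seq_len(k)) {
      hi <- if (j == k) edges[j + 1] + 1e-300 else edges[j + 1]
      if (v >= edges[j] && (v < hi || (j == k && v <= edges[j + 1]))) {
        counts[j] <- counts[j] + 1
        break
      }
    }
  }
  p <- counts / sum(counts)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# position-sensitive checksum for round-trip comparisons
digest_array <- function(a) {
  v <- as.numeric(a)
  c(n = length(v), s1 = sum(v), s2 = sum(v * seq_along(v)))
}
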