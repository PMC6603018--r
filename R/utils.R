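#' @keywords internal
"_PACKAGE"

# Deterministic per-stage sub-seed from a single top-level seed, so every
# generator stage draws from its own stream and stages can be re-run in
# isolation. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(schedule = 1L, affect = 2L, eeg = 3L, bold = 4L,
              permute = 5L, misc = 6L)
  k <- stages[[stage]]
  (as.integer(seed) %% 20000003L) * 97L + k * 1009L
}

# Legendre polynomials P_0..P_order evaluated on n points over [-1, 1],
# by the Bonnet recurrence. Columns are drift regressors.
legendre_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  colnames(P) <- paste0("drift", 0:order)
  P
}

# zero-mean / unit-SD scaling; errors on (near-)constant input
standardize <- function(x, label = "regressor") {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps^0.5 * (abs(mean(x)) + 1)) {
    stop(sprintf("column '%s' is constant (zero variance) after processing", label))
  }
  (x - mean(x)) / s
}

clip01 <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

# linear interpolation with flat extrapolation at the ends
interp_series <- function(times, values, at) {
  stats::approx(times, values, xout = at, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
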