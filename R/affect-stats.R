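#' Segment reported affect into 20-s sub-trials
#'
#' Each music-listening trial splits into two sub-trials, one per
#' targeted circumplex half, carrying the mean reported valence/arousal
#' over that window alongside the targeted values.
#'
#' @param reported the reported `affect_trajectory`.
#' @param schedule the `trial_schedule`.
#' @return data.frame: `trial_id`, `half`, `start`, `end`,
#'   `mean_valence`, `mean_arousal`, `target_valence`, `target_arousal`.
#' @export
segment_subtrials <- function(reported, schedule) {
  half <- attr(schedule, "half_duration") %||% (schedule$duration[1] / 2)
  keep <- music_trials(schedule)
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    out <- lapply(1:2, function(h) {
      s <- keep$onset[i] + (h - 1) * half
      e <- s + half
      sel <- reported$time >= s & reported$time < e
      if (!any(sel)) {
        stop("reports do not cover trial ", keep$trial[i], " half ", h)
      }
      data.frame(trial_id = keep$trial[i], half = h, start = s, end = e,
                 mean_valence = mean(reported$valence[sel]),
                 mean_arousal = mean(reported$arousal[sel]),
                 target_valence = keep[[paste0("target_v", h)]][i],
                 target_arousal = keep[[paste0("target_a", h)]][i])
    })
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Correlation between targeted and reported affect
#'
#' Pearson correlation across sub-trials of the mean reported value
#' against the targeted circumplex value, on one axis.
#'
#' @param subtrials output of [segment_subtrials()].
#' @param axis `"valence"` or `"arousal"`.
#' @return a `test_result` list: `statistic` (r), `p_raw`, `p_adjusted`
#'   (= raw; single test), `rejected` at alpha, `method`, `n`.
#' @param alpha significance level (default 0.05).
#' @export
target_report_correlation <- function(subtrials,
                                      axis = c("valence", "arousal"),
                                      alpha = 0.05) {
  axis <- match.arg(axis)
  x <- subtrials[[paste0("target_", axis)]]
  y <- subtrials[[paste0("mean_", axis)]]
  if (length(x) < 3L) stop("need at least 3 sub-trials")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in targeted or reported ", axis)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(statistic = unname(ct$estimate), p_raw = ct$p.value,
              p_adjusted = ct$p.value, alpha = alpha, method = "pearson",
              n = length(x))
}

test_result <- function(statistic, p_raw, p_adjusted, alpha, method, n = NA) {
  structure(list(statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, rejected = p_adjusted < alpha,
                 alpha = alpha, method = method, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (adjusted %.4g), %s at alpha = %g\n",
              x$method, x$statistic, x$p_raw, x$p_adjusted,
              if (x$rejected) "rejected" else "not rejected", x$alpha))
  invisible(x)
}

#' Label music trials as high or low valence
#'
#' A trial is labelled `"high"` when its mean reported valence exceeds
#' the threshold, else `"low"` (ties go to `"low"`). The threshold is 0
#' by default, or the median across trials with `threshold = "median"`.
#'
#' @param reported the reported `affect_trajectory`.
#' @param schedule the `trial_schedule`.
#' @param threshold numeric cut, or `"median"` for a median split.
#' @return data.frame: `trial_id`, `mean_valence`, `label`.
#' @export
label_valence_trials <- function(reported, schedule, threshold = 0) {
  keep <- music_trials(schedule)
  mv <- vapply(seq_len(nrow(keep)), function(i) {
    sel <- reported$time >= keep$onset[i] &
      reported$time < keep$onset[i] + keep$duration[i]
    if (!any(sel)) stop("reports do not cover trial ", keep$trial[i])
    mean(reported$valence[sel])
  }, numeric(1))
  thr <- if (identical(threshold, "median")) stats::median(mv) else threshold
  data.frame(trial_id = keep$trial,
             mean_valence = mv,
             label = ifelse(mv > thr, "high", "low"))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value, used to
#' compare per-trial asymmetry (or entropy) values between high and low
#' valence conditions.
#'
#' @param values_a,values_b numeric samples, at least 5 each.
#' @param alpha significance level.
#' @return a `test_result` (`method = "ks_two_sample"`).
#' @export
ks_compare <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 5L || length(values_b) < 5L) {
    stop("each group needs at least 5 values for the KS comparison")
  }
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  test_result(statistic = unname(kt$statistic), p_raw = kt$p.value,
              p_adjusted = kt$p.value, alpha = alpha,
              method = "ks_two_sample")
}

#' Holm-Bonferroni step-down correction
#'
#' @param p_values raw p-values in [0, 1].
#' @param alpha family-wise significance level.
#' @return list: `p_adjusted` (input order), `rejected` (logical).
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = FALSE) ||
      any(!is.finite(p_values))) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "holm")
  list(p_adjusted = adj, rejected = adj < alpha)
}

#' High-vs-low valence asymmetry battery across bands
#'
#' For each frequency band: per-trial mean asymmetry of the
#' music-listening trials, split by valence label, compared with a
#' two-sample KS test; Holm-Bonferroni corrected across bands.
#'
#' @param eeg an [eeg_recording()].
#' @param reported the reported `affect_trajectory`.
#' @param schedule the `trial_schedule`.
#' @param bands list of band definitions (default all four).
#' @param alpha family-wise level.
#' @param threshold valence split rule as in [label_valence_trials()].
#' @param window,step band-power window and step, seconds.
#' @return data.frame: `band`, `statistic`, `p_raw`, `p_adjusted`,
#'   `rejected`, `n_high`, `n_low`.
#' @export
asymmetry_battery <- function(eeg, reported, schedule,
                              bands = eeg_bands(), alpha = 0.05,
                              threshold = "median",
                              window = 2, step = 2) {
  labels <- label_valence_trials(reported, schedule, threshold = threshold)
  asyms <- prefrontal_asymmetry_bands(eeg, bands, window = window,
                                      steps = step)
  rows <- lapply(seq_along(bands), function(bi) {
    band <- bands[[bi]]
    tm <- trial_mean_asymmetry(asyms[[bi]][[1]], schedule)
    hi <- tm[labels$label == "high"]
    lo <- tm[labels$label == "low"]
    res <- ks_compare(hi, lo, alpha = alpha)
    data.frame(band = band$name, statistic = res$statistic,
               p_raw = res$p_raw, n_high = length(hi), n_low = length(lo))
  })
  out <- do.call(rbind, rows)
  hb <- holm_bonferroni(out$p_raw, alpha = alpha)
  out$p_adjusted <- hb$p_adjusted
  out$rejected <- hb$rejected
  rownames(out) <- NULL
  out[, c("band", "statistic", "p_raw", "p_adjusted", "rejected",
          "n_high", "n_low")]
}
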