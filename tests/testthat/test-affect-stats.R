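make_reported <- function(times, valence, arousal = NULL) {
  affect_trajectory(times, valence, arousal %||% rep(0, length(times)),
                    kind = "reported")
}

test_that("sub-trial segmentation recovers targets and window means", {
  cfg <- tiny_config(seed = 3, n_trials = 9L)
  sched <- generate_schedule(cfg)
  t_end <- affectfuse:::schedule_end(sched) + 5
  times <- seq(0, t_end, by = 0.1)
  # constant report equal to a known value
  rep_const <- make_reported(times, rep(0.4, length(times)))
  st <- segment_subtrials(rep_const, sched)
  expect_equal(nrow(st), 2 * sum(sched$trial_type != "reporting_only"))
  expect_true(all(st$mean_valence == 0.4))
  expect_true(all(st$half %in% 1:2))
  expect_equal(st$end - st$start, rep(20, nrow(st)))
  # a linear ramp averages to its midpoint value
  ramp <- make_reported(times, clip01(times / t_end * 2 - 1))
  str <- segment_subtrials(ramp, sched)
  mid_vals <- (str$start + str$end) / 2 / t_end * 2 - 1
  expect_equal(str$mean_valence, mid_vals, tolerance = 1e-3)
  # coverage gap is an explicit error
  short <- make_reported(times[times < sched$onset[2]],
                         rep(0, sum(times < sched$onset[2])))
  expect_error(segment_subtrials(short, sched), "cover")
})

test_that("target-report correlation behaves at the identity and the null", {
  cfg <- sim_config(seed = 8, n_trials = 36L, eeg_rate = 100)
  sched <- generate_schedule(cfg)
  t_end <- affectfuse:::schedule_end(sched) + 5
  times <- seq(0, t_end, by = 0.1)
  # report that equals the targeted value inside each half
  v <- numeric(length(times))
  music <- sched[sched$trial_type != "reporting_only", ]
  for (i in seq_len(nrow(music))) {
    v[times >= music$onset[i] & times < music$onset[i] + 20] <- music$target_v1[i]
    v[times >= music$onset[i] + 20 & times < music$onset[i] + 40] <- music$target_v2[i]
  }
  st <- segment_subtrials(make_reported(times, v), sched)
  res <- target_report_correlation(st, "valence")
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_true(res$rejected)
  # independent reports: |r| small over 1000 synthetic sub-trials
  set.seed(2)
  fake <- data.frame(target_valence = sample(c(-2, 0, 2) / 3, 1000, TRUE),
                     mean_valence = rnorm(1000, 0, 0.3))
  r0 <- target_report_correlation(fake, "valence")
  expect_lt(abs(r0$statistic), 0.1)
  # degenerate variance errors
  allsame <- data.frame(target_valence = rep(0.5, 10),
                        mean_valence = rnorm(10))
  expect_error(target_report_correlation(allsame, "valence"), "variance")
  expect_error(target_report_correlation(fake[1:2, ], "valence"), "3 sub")
})

test_that("valence labelling applies the documented tie rule", {
  cfg <- tiny_config(seed = 4, n_trials = 6L)
  sched <- generate_schedule(cfg)
  t_end <- affectfuse:::schedule_end(sched) + 5
  times <- seq(0, t_end, by = 0.1)
  lab_hi <- label_valence_trials(make_reported(times,
                                               rep(0.5, length(times))),
                                 sched)
  expect_true(all(lab_hi$label == "high"))
  # exactly at the threshold: labelled low
  lab_tie <- label_valence_trials(make_reported(times,
                                                rep(0, length(times))),
                                  sched)
  expect_true(all(lab_tie$label == "low"))
  # median split halves the trials
  cfg2 <- sim_config(seed = 17, n_trials = 30L, eeg_rate = 100)
  sched2 <- generate_schedule(cfg2)
  aff <- generate_affect(sched2, cfg2)
  lab <- label_valence_trials(aff$reported, sched2, threshold = "median")
  expect_equal(sum(lab$label == "high"), sum(lab$label == "low"))
})

test_that("symmetric valence yields label proportions near 50/50", {
  labs <- unlist(lapply(1:6, function(s) {
    cfg <- sim_config(seed = 300 + s, n_trials = 30L, eeg_rate = 100,
                      target_gain = 0)
    sched <- generate_schedule(cfg)
    aff <- generate_affect(sched, cfg)
    label_valence_trials(aff$reported, sched)$label
  }))
  p <- binom.test(sum(labs == "high"), length(labs))$p.value
  expect_gt(p, 0.001)
})

test_that("KS statistic equals the brute-force ECDF scan exactly", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(50)
    b <- rnorm(50, mean = 0.3)
    res <- ks_compare(a, b)
    expect_equal(res$statistic, ks_oracle(a, b), tolerance = 1e-12)
  }
  expect_equal(suppressWarnings(ks_compare(1:10, 1:10))$statistic, 0)
  disjoint <- ks_compare(1:10, 21:30)
  expect_equal(disjoint$statistic, 1)
  expect_lt(disjoint$p_raw, 0.01)
  expect_error(ks_compare(1:3, 1:10), "at least 5")
})

test_that("KS null rejection rate is close to nominal", {
  # the asymptotic p-value is mildly conservative at small n, so the
  # calibration is checked at n = 200 per group
  set.seed(12)
  rej <- mean(replicate(1500, {
    suppressWarnings(ks_compare(rnorm(200), rnorm(200)))$p_raw < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Holm-Bonferroni step-down matches hand execution and dominance", {
  expect_equal(holm_bonferroni(0.03)$p_adjusted, 0.03)
  hb <- holm_bonferroni(c(0.01, 0.04), alpha = 0.05)
  expect_equal(hb$p_adjusted, c(0.02, 0.04))
  expect_true(all(hb$rejected))
  # monotone in sorted order; rejects between Bonferroni and raw
  set.seed(13)
  for (i in 1:20) {
    p <- runif(6)^2
    hb <- holm_bonferroni(p, alpha = 0.05)
    expect_true(!is.unsorted(hb$p_adjusted[order(p)]))
    bonf <- p < 0.05 / length(p)
    raw <- p < 0.05
    expect_true(all(hb$rejected[bonf]))
    expect_true(all(!hb$rejected[!raw]))
  }
  expect_error(holm_bonferroni(c(0.1, 1.2)), "0, 1")
})

test_that("the band battery reports alpha and beta coupling at default gain", {
  ds <- memo("sim75", {
    cfg <- sim_config(seed = 42, n_trials = 75L, eeg_rate = 100)
    sched <- generate_schedule(cfg)
    aff <- generate_affect(sched, cfg)
    eeg <- generate_eeg(aff$latent, sched, cfg)
    list(cfg = cfg, sched = sched, aff = aff, eeg = eeg)
  })
  bat <- asymmetry_battery(ds$eeg, ds$aff$reported, ds$sched)
  expect_equal(bat$band, c("delta", "theta", "alpha", "beta"))
  expect_true(all(bat$p_adjusted >= bat$p_raw))
  expect_true(bat$rejected[bat$band == "alpha"] ||
                bat$rejected[bat$band == "beta"])
})
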