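rate <- 256

test_that("zero crossings of pure sinusoids produce the expected half-waves", {
  t <- seq(0, 61, by = 1 / rate)
  w1 <- detect_slow_waves(sin(2 * pi * 1 * t), rate)
  n_pos <- sum(w1$peak_amp > 0); n_neg <- sum(w1$peak_amp <= 0)
  expect_true(abs(n_pos - 60) <= 1 && abs(n_neg - 60) <= 1)
  expect_equal(unname(quantile(w1$zc_end_s - w1$zc_start_s, 0.5)), 0.5,
               tolerance = 0.02)

  # 0.2 Hz: half-period 2.5 s retained; 0.1 Hz: 5 s rejected by the 3 s cap
  t2 <- seq(0, 120, by = 1 / rate)
  w2 <- detect_slow_waves(sin(2 * pi * 0.2 * t2), rate)
  expect_gt(nrow(w2), 10)
  expect_equal(unname(quantile(w2$zc_end_s - w2$zc_start_s, 0.5)), 2.5,
               tolerance = 0.1)
  w3 <- detect_slow_waves(sin(2 * pi * 0.1 * t2) +
                            1e-8 * sin(2 * pi * 2 * t2), rate)
  expect_equal(nrow(w3), 0)

  expect_equal(nrow(detect_slow_waves(numeric(rate * 30), rate)), 0)
  expect_error(detect_slow_waves(numeric(10), rate), "shorter")
})

test_that("extreme-peak selection keeps the configured fractions with ties broken early", {
  set.seed(4)
  amps <- -(1:100)                       # 100 negative waves, ranked
  waves <- data.frame(zc_start_s = 1:100, zc_end_s = 1:100 + 0.5,
                      peak_s = 1:100 + 0.25, peak_amp = sample(amps))
  kept <- select_extreme_peaks(waves, 0.40)
  expect_equal(nrow(kept), 40)
  expect_true(all(kept$peak_amp <= -61))  # the 40 most negative of -1..-100

  w10 <- waves[1:10, ]
  expect_equal(nrow(select_extreme_peaks(w10, 0.40)), 4)

  ties <- data.frame(zc_start_s = 1:10, zc_end_s = 1:10 + 0.5,
                     peak_s = 1:10 + 0.25, peak_amp = rep(-5, 10))
  kt <- select_extreme_peaks(ties, 0.40)
  expect_equal(kt$peak_s, ties$peak_s[1:4])   # earliest first

  expect_error(select_extreme_peaks(waves, 0.6), "keep_fraction")
  expect_error(select_extreme_peaks(waves, 0), "keep_fraction")
})

test_that("extreme-peak selection is invariant to input order", {
  set.seed(5)
  waves <- data.frame(zc_start_s = 1:50, zc_end_s = 1:50 + 0.5,
                      peak_s = 1:50 + 0.25, peak_amp = rnorm(50) * 10)
  a <- select_extreme_peaks(waves, 0.4)
  b <- select_extreme_peaks(waves[sample(50), ], 0.4)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("polarity assignment follows the gamma signature and flips with the sign", {
  sim <- small_sim()
  rec <- sim$recording
  p <- ds_params()
  x <- rec$data[, "C1"]
  waves <- detect_slow_waves(x, rec$rate_hz, p)
  waves <- ctcoord:::mask_waves(waves, rec$stages, rec$exclusions)
  sel <- select_extreme_peaks(waves, 0.4)
  res <- assign_polarity(sel, x, rec$rate_hz, "cortex", p)
  expect_equal(res$ds_sign, -1)

  # negating the samples flips the assigned polarity
  waves_n <- detect_slow_waves(-x, rec$rate_hz, p)
  waves_n <- ctcoord:::mask_waves(waves_n, rec$stages, rec$exclusions)
  sel_n <- select_extreme_peaks(waves_n, 0.4)
  res_n <- assign_polarity(sel_n, -x, rec$rate_hz, "cortex", p)
  expect_equal(res_n$ds_sign, 1)

  # thalamic assignment on the synthetic thalamic channel
  xt <- rec$data[, "T1"]
  wt <- select_extreme_peaks(
    ctcoord:::mask_waves(detect_slow_waves(xt, rec$rate_hz, p),
                         rec$stages, rec$exclusions), 0.4)
  rt <- assign_polarity(wt, xt, rec$rate_hz, "thalamus", p)
  expect_equal(rt$ds_sign, -1)
})

test_that("absent gamma modulation yields a polarity-undetermined error", {
  cfg <- sim_config(duration_s = 400, n_cortical = 1, n_thalamic = 0,
                    gamma_amp = 0, seed = 13)
  sim <- simulate_recording(cfg)
  p <- ds_params()
  x <- sim$recording$data[, 1]
  waves <- detect_slow_waves(x, cfg$rate_hz, p)
  sel <- select_extreme_peaks(waves, 0.4)
  expect_error(assign_polarity(sel, x, cfg$rate_hz, "cortex", p),
               "polarity undetermined")
})

test_that("artifact rejection removes step-contaminated epochs and nothing else", {
  t <- seq(0, 120, by = 1 / rate)
  x <- 10 * sin(2 * pi * 1 * t)                   # clean oscillation
  ev <- data.frame(peak_s = seq(10, 110, by = 10))
  clean <- reject_artifact_events(ev, x, rate, c(-3, 3))
  expect_equal(nrow(clean), nrow(ev))              # clean signal: none removed

  xs <- x; xs[round(55 * rate):length(xs)] <- xs[round(55 * rate):length(xs)] +
    20 * sd(x)                                    # 20-SD step at t = 55
  rej <- reject_artifact_events(ev, xs, rate, c(-3, 3))
  covered <- abs(ev$peak_s - 55) <= 3
  expect_equal(sort(rej$peak_s), ev$peak_s[!covered])

  # infinite thresholds: identity
  keep_all <- reject_artifact_events(ev, xs, rate, c(-3, 3),
                                     diff_threshold = Inf, sd_mult = Inf)
  expect_equal(keep_all$peak_s, ev$peak_s)

  # events too close to the recording edge are dropped with a warning
  ev_edge <- rbind(data.frame(peak_s = 1), ev)
  expect_warning(reject_artifact_events(ev_edge, x, rate, c(-3, 3)),
                 "epoch outside")
})

test_that("strict mode detects a near-subset of the default-mode downstates", {
  sim <- small_sim()
  ds_def <- suppressWarnings(detect_downstates(sim$recording, ds_params()))
  ds_str <- suppressWarnings(detect_downstates(sim$recording,
                                               ds_params(mode = "strict")))
  expect_true(all(ds_str$mode == "strict"))
  for (ch in unique(ds_str$channel)) {
    s <- ds_str$peak_s[ds_str$channel == ch & ds_str$type == "ds"]
    d <- ds_def$peak_s[ds_def$channel == ch & ds_def$type == "ds"]
    if (!length(s) || !length(d)) next
    covered <- vapply(s, function(t0) any(abs(d - t0) <= 0.05), logical(1))
    expect_gt(mean(covered), 0.9)
  }
})
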