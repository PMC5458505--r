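test_that("peri-event histograms count pairwise lags into 50 ms bins", {
  refs <- seq(10, 100, by = 10)
  h0 <- event_histogram(refs, refs, window_s = 0.5)
  expect_equal(sum(h0$counts), length(refs))
  expect_equal(histogram_peak_latency(h0), 0.025)   # zero lags in the 0-bin

  h1 <- event_histogram(refs, refs + 0.12, window_s = 0.5)
  bin <- which(h1$breaks[-length(h1$breaks)] == 0.10)
  expect_equal(h1$counts[bin], 10L)
  expect_equal(sum(h1$counts), 10L)

  expect_equal(sum(event_histogram(refs, numeric(0))$counts), 0L)
  expect_warning(event_histogram(numeric(0), refs), "no reference")
})

test_that("histograms are invariant under a global time shift", {
  set.seed(60)
  a <- sort(runif(40, 0, 100)); b <- sort(runif(40, 0, 100))
  h1 <- event_histogram(a, b)
  h2 <- event_histogram(a + 1234.5, b + 1234.5)
  expect_equal(h1$counts, h2$counts)
})

test_that("the binomial order test reproduces exact tail probabilities", {
  # 10 before / 0 after: p = 2 * 0.5^10
  ot <- binomial_order_test(0, seq(-0.45, -0.05, length.out = 10))
  expect_equal(ot$n_before, 10L)
  expect_equal(ot$p_two_sided, 2 * 0.5^10)
  expect_true(ot$significant && ot$direction == "target-leads")

  # balanced counts: p capped at 1
  ot2 <- binomial_order_test(0, c(seq(-0.4, -0.1, length.out = 5),
                                  seq(0.1, 0.4, length.out = 5)))
  expect_equal(ot2$p_two_sided, 1)
  expect_equal(ot2$direction, "none")

  # 7 before / 3 after: exact two-sided binomial sum
  ot3 <- binomial_order_test(0, c(seq(-0.45, -0.05, length.out = 7),
                                  c(0.1, 0.2, 0.3)))
  p_manual <- sum(dbinom(c(0:3, 7:10), 10, 0.5))
  expect_equal(ot3$p_two_sided, p_manual)
  expect_equal(ot3$p_two_sided, 0.34375)

  # zero lags are excluded; empty window errors
  expect_error(binomial_order_test(5, 5), "no counted pairs")
  # nearest-only counts one pair per reference
  otn <- binomial_order_test(0, c(-0.1, -0.2, 0.3), nearest_only = TRUE)
  expect_equal(otn$n_before + otn$n_after, 1L)
})

test_that("Bonferroni levels divide the family-wise alpha", {
  expect_equal(bonferroni_level(0.05, 64), 0.00078125)
  expect_equal(signif(bonferroni_level(0.05, 64), 2), 0.00078)
  expect_equal(bonferroni_level(0.05, 1), 0.05)
  expect_equal(bonferroni_level(0.05, 20), 0.0025)
  expect_error(bonferroni_level(0.05, 0), "n_tests")
})

test_that("conditional DS probability rises with multi-channel participation", {
  # schedule-level check on a long simulated night (event times only)
  cfg <- sim_config(duration_s = 3600, seed = 14)
  gt <- build_event_schedule(cfg)
  ce <- lapply(stats::setNames(nm = c("C1", "C2", "C3", "C4")), function(ch)
    gt$peak_s[gt$channel == ch & gt$type == "ds"])
  th <- gt$peak_s[gt$channel == "T1" & gt$type == "ds"]
  res <- conditional_ds_probability(ce, th)
  off <- res$prob[row(res$prob) != col(res$prob)]
  expect_gt(mean(off, na.rm = TRUE), mean(diag(res$prob)))
  pv <- res$p_value[!is.na(res$p_value)]
  expect_gt(mean(pv < 0.05), 0.5)        # conditioning raises the probability
  expect_gt(sum(res$significant), 0)     # survives Bonferroni somewhere

  # single cortical channel: a 1x1 matrix without tests
  r1 <- conditional_ds_probability(ce[1], th)
  expect_equal(dim(r1$prob), c(1L, 1L))
  expect_true(all(is.na(r1$p_value)))
})

test_that("polynomial inflection recovers analytic and near-symmetric onsets", {
  rate <- 256
  t <- seq(-1, 1, by = 1 / rate)
  y <- (t + 0.3)^3
  expect_lt(abs(ds_onset_latency(y, rate, -1, guess_s = -0.25) + 0.3), 0.001)

  # even waveform: inflections come in symmetric pairs; the one nearer the
  # guess is returned
  y2 <- cos(pi * t)
  lat <- ds_onset_latency(y2, rate, -1, guess_s = -0.4)
  expect_lt(abs(lat + 0.5), 0.02)
  lat2 <- ds_onset_latency(y2, rate, -1, guess_s = 0.4)
  expect_lt(abs(lat2 - 0.5), 0.02)

  expect_error(ds_onset_latency(t^2, rate, -1, 0), "no real inflection")
})

test_that("the histogram peak latency uses bin midpoints with documented ties", {
  h <- event_histogram(rep(0, 10), rep(0.22, 10), window_s = 0.5)
  expect_equal(histogram_peak_latency(h), 0.225)

  h2 <- event_histogram(0, 0.31, window_s = 0.5)
  expect_equal(histogram_peak_latency(h2), 0.325)

  # two tied bins: nearest zero wins
  h3 <- event_histogram(rep(0, 3), c(0.01, 0.02, 0.31, 0.32, 0.33)[c(1, 2, 4)],
                        window_s = 0.5)
  h3$counts[h3$mids == 0.325] <- h3$counts[h3$mids == 0.025]
  expect_equal(histogram_peak_latency(h3), 0.025)
  expect_error(histogram_peak_latency(event_histogram(1, numeric(0))),
               "all-zero")
})

test_that("the gamma delay estimator recovers a constructed lag", {
  # carrier noise with amplitude bumps at known trough times, +20 ms apart
  rate <- 256
  set.seed(61)
  dur <- 400
  n <- dur * rate
  troughs <- seq(5, dur - 5, by = 0.6)
  t <- (seq_len(n) - 1) / rate
  bump <- function(times, lag) {
    g <- rep(0.3, n)
    for (t0 in times + lag) {
      i <- which(abs(t - t0) < 0.03)
      g[i] <- g[i] + cos(pi * (t[i] - t0) / 0.06)^2
    }
    g
  }
  carrier <- function(seed) {
    set.seed(seed)
    b <- bandpass_filter(rnorm(n), rate, 60, 100)
    b / sd(b)
  }
  x_thal <- 5 * bump(troughs, 0) * carrier(1)
  x_cort <- 5 * bump(troughs, 0.02) * carrier(2)
  gd <- gamma_trough_delay(x_thal, x_cort, rate, troughs, subset_size = 300)
  expect_lt(abs(gd$value_s - 0.02), 0.004)
  expect_lt(gd$p_value, 0.05)

  # zero lag: delay near zero
  x_c0 <- 5 * bump(troughs, 0) * carrier(3)
  gd0 <- gamma_trough_delay(x_thal, x_c0, rate, troughs, subset_size = 300)
  expect_lt(abs(gd0$value_s), 0.004)

  # too few troughs: single-group estimate with a warning
  expect_warning(
    gs <- gamma_trough_delay(x_thal, x_cort, rate, troughs[1:50],
                             subset_size = 500), "single-group")
  expect_true(is.na(gs$p_value))
})

test_that("enrichment follows the printed density formula", {
  # tallest bin 5, 100 DSs, 300 spindles in 60 minutes -> factor 12
  ds <- seq(30, 3000, length.out = 100)
  sp <- c(ds[1:5] + 0.21, seq(3100, 3590, length.out = 295))
  ef <- enrichment_factor(sp, ds, total_minutes = 60)
  expect_equal(ef$peak_density_per_min, 20 * 60 * 5 / 100)
  expect_equal(ef$overall_density_per_min, 5)
  expect_equal(ef$factor, 12)

  expect_equal(enrichment_factor(numeric(0), ds, 60)$factor, 0)
  expect_error(enrichment_factor(sp, numeric(0), 60), "no downstates")
  expect_error(enrichment_factor(sp, ds, 0), "total_minutes")
})

test_that("the normalised coupling proportion matches the printed formula", {
  ds <- seq(10, 2000, by = 10)                       # 200 DSs
  coupled <- ds[1:40] + 0.3                          # inside [0, 0.75]
  uncoupled <- ds[81:140] + 5                        # mid-gap, uncoupled
  sp <- c(coupled, uncoupled)
  pr <- proportion_spindles_with_ds(sp, ds, "cortex",
                                    ds_counts_in_subject = c(200, 400))
  expect_equal(pr$raw_proportion, 0.4)
  expect_equal(pr$normalized, 0.4 / (200 / 400))

  # channel holding the subject maximum: normalised equals raw
  pr2 <- proportion_spindles_with_ds(sp, ds, "cortex",
                                     ds_counts_in_subject = c(200, 120))
  expect_equal(pr2$normalized, pr2$raw_proportion)

  # thalamic window [-0.5, 0.25]
  pr3 <- proportion_spindles_with_ds(ds[1] - 0.4, ds, "thalamus", 200)
  expect_equal(pr3$n_coupled, 1L)
  pr4 <- proportion_spindles_with_ds(ds[1] + 0.4, ds, "thalamus", 200)
  expect_equal(pr4$raw_proportion, 0)
})

test_that("overlap fractions use any-intersection with touching boundaries", {
  a <- data.frame(onset_s = 0, offset_s = 1)
  b <- data.frame(onset_s = c(0.9, 3), offset_s = c(1.5, 4))
  expect_equal(overlap_fraction(a, b)$fraction, 1)
  expect_equal(overlap_fraction(b, a)$fraction, 0.5)
  expect_equal(overlap_fraction(a, a)$fraction, 1)
  disj <- data.frame(onset_s = 5, offset_s = 6)
  expect_equal(overlap_fraction(a, disj)$fraction, 0)
  # touching boundary counts
  touch <- data.frame(onset_s = 1, offset_s = 2)
  expect_equal(overlap_fraction(a, touch)$fraction, 1)
})
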