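rate <- 256

# a quiet channel with oscillatory bursts at known places
burst_signal <- function(dur, bursts, noise_sd = 0.3, freq = 12, seed = 40) {
  set.seed(seed)
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- rnorm(length(t), 0, noise_sd)
  for (b in seq_len(nrow(bursts))) {
    i <- which(t >= bursts$onset_s[b] & t <= bursts$offset_s[b])
    x[i] <- x[i] + bursts$amp[b] * sin(2 * pi * freq * (t[i] - t[i][1]))
  }
  x
}

test_that("the envelope-threshold detector finds bursts with +1 SD boundaries", {
  bursts <- data.frame(onset_s = c(20, 50), offset_s = c(21, 51.2),
                       amp = c(8, 10))
  x <- burst_signal(80, bursts)
  ev <- previous_method_detect(x, rate, "cortex")
  expect_equal(nrow(ev), 2)
  expect_lt(abs(ev$onset_s[1] - 20), 0.25)
  expect_lt(abs(ev$offset_s[1] - 21), 0.3)
  expect_true(all(ev$offset_s - ev$onset_s >= 0.3 &
                    ev$offset_s - ev$onset_s <= 2))

  # a very short burst: its above-threshold crossing stays under the
  # 0.3 s duration floor, so no event is emitted
  short <- data.frame(onset_s = 20, offset_s = 20.1, amp = 4)
  long_ref <- data.frame(onset_s = 40, offset_s = 41, amp = 8)
  ev2 <- previous_method_detect(burst_signal(60, rbind(short, long_ref)),
                                rate, "cortex")
  expect_false(any(ev2$onset_s > 19 & ev2$onset_s < 21))
  expect_true(any(ev2$onset_s > 39 & ev2$onset_s < 41))

  expect_equal(nrow(previous_method_detect(numeric(rate * 30), rate,
                                           "cortex")), 0)
})

test_that("edge and amplitude envelopes approach 2A/pi on steady tones", {
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  A <- 6
  env <- compute_envelopes(A * sin(2 * pi * 12 * t), rate)
  mid <- (2 * rate):(18 * rate)
  expect_lt(abs(mean(env$edge[mid]) - 2 * A / pi) / (2 * A / pi), 0.02)
  expect_lt(abs(mean(env$amplitude[mid]) - 2 * A / pi) / (2 * A / pi), 0.02)

  z <- compute_envelopes(numeric(rate * 10), rate)
  expect_equal(z$edge, numeric(rate * 10))

  # double smoothing: lower, wider amplitude envelope for an isolated burst
  b <- burst_signal(30, data.frame(onset_s = 15, offset_s = 15.8, amp = 8),
                    noise_sd = 0)
  e <- compute_envelopes(b, rate)
  expect_lte(max(e$amplitude), max(e$edge))
  expect_gt(sum(e$amplitude > 0.25 * max(e$amplitude)),
            sum(e$edge > 0.25 * max(e$edge)))
})

test_that("the candidate threshold is the smallest manual amplitude", {
  # envelope with three isolated triangular peaks of heights 3.0, 5.1, 7.2
  env <- numeric(3000)
  peak_at <- function(i, h) {
    env[(i - 50):(i + 50)] <<- pmax(env[(i - 50):(i + 50)],
                                    h * (1 - abs(-50:50) / 50))
  }
  peak_at(500, 3.0); peak_at(1500, 5.1); peak_at(2500, 7.2)
  marks <- data.frame(onset_s = c(400, 1400, 2400) / rate,
                      offset_s = c(600, 1600, 2600) / rate)
  expect_equal(candidate_threshold_from_marks(env, rate, marks), 3.0)
  expect_equal(candidate_threshold_from_marks(env, rate, marks[2, ]), 5.1)

  # a mark over flat envelope is skipped with a warning; all-flat errors
  flat_marks <- rbind(marks, data.frame(onset_s = 3.2, offset_s = 3.5))
  expect_warning(th <- candidate_threshold_from_marks(env, rate, flat_marks),
                 "no amplitude-envelope maximum")
  expect_equal(th, 3.0)
  expect_error(suppressWarnings(
    candidate_threshold_from_marks(env, rate,
                                   data.frame(onset_s = 3.2, offset_s = 3.5))),
    "no usable marks")
  expect_error(candidate_threshold_from_marks(env, rate, NULL), "no marks")
})

test_that("candidate epochs bracket bursts, enforce 300 ms, and merge overlaps", {
  bursts <- data.frame(onset_s = c(10, 14), offset_s = c(11, 15.1),
                       amp = c(8, 8))
  x <- burst_signal(25, bursts, noise_sd = 0.2)
  env <- compute_envelopes(x, rate)
  cands <- find_candidate_epochs(env$edge, env$amplitude, rate, 1.5)
  expect_equal(nrow(cands), 2)
  expect_true(cands$onset_s[1] < 10.3 && cands$offset_s[1] > 10.7)
  expect_true(all(cands$offset_s - cands$onset_s >= 0.3))
  expect_true(all(cands$edge_amp >= cands$amp_env_peak * 0.5))

  # a synthetic envelope whose 45% interval is shorter than 300 ms is dropped
  edge <- numeric(2000); amp_env <- numeric(2000)
  edge[990:1010] <- 5 * (1 - abs(-10:10) / 10)     # ~80 ms above 45%
  amp_env[990:1010] <- edge[990:1010]
  expect_equal(nrow(find_candidate_epochs(edge, amp_env, rate, 2)), 0)

  expect_error(find_candidate_epochs(env$edge, env$amplitude, rate, 0),
               "threshold > 0")
})

test_that("candidate epochs ignore constant offsets in the raw signal", {
  bursts <- data.frame(onset_s = 10, offset_s = 11, amp = 8)
  x <- burst_signal(20, bursts, noise_sd = 0.2)
  e1 <- compute_envelopes(x, rate)
  e2 <- compute_envelopes(x + 100, rate)
  c1 <- find_candidate_epochs(e1$edge, e1$amplitude, rate, 1.5)
  c2 <- find_candidate_epochs(e2$edge, e2$amplitude, rate, 1.5)
  expect_equal(c1$onset_s, c2$onset_s, tolerance = 0.02)
})

test_that("feature extraction matches spectral and cycle-counting expectations", {
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  set.seed(41)
  x <- rnorm(length(t), 0, 0.3)
  i12 <- which(t >= 10 & t <= 11)
  x[i12] <- x[i12] + 8 * sin(2 * pi * 12 * (t[i12] - 10))
  i6 <- which(t >= 20 & t <= 21)
  x[i6] <- x[i6] + 8 * sin(2 * pi * 6 * (t[i6] - 20))
  cands <- data.frame(onset_s = c(10, 20), offset_s = c(11, 21),
                      peak_s = c(10.5, 20.5), amp_env_peak = NA,
                      edge_amp = NA)
  stages <- data.frame(onset_s = c(0, 20), offset_s = c(20, 40),
                       stage = c("N2", "N3"))
  f <- extract_features(cands, x, rate, stages)
  expect_lt(abs(f$spindle_freq[1] - 12), 0.3)
  expect_true(abs(f$npeaks[1] - 12) <= 1)
  expect_equal(f$pr[1], 1L)
  expect_gt(f$f_ratio[1], 1)
  expect_lt(f$f_ratio[2], 1)            # 6 Hz tone: nonspindle band dominates
  expect_equal(f$stage, c(0L, 1L))
  expect_equal(f$peakrate, f$npeaks / f$dur)
})

test_that("candidate labelling follows the mark-overlap rules", {
  cands <- data.frame(onset_s = c(1, 5, 20), offset_s = c(2, 6, 21),
                      peak_s = c(1.5, 5.5, 20.5))
  marks <- data.frame(onset_s = 1.9, offset_s = 3)
  periods <- data.frame(onset_s = 0, offset_s = 10)
  lab <- label_candidates(cands, marks, periods)
  expect_equal(lab, c(1L, 0L, NA))      # overlap -> 1; in period -> 0; out -> NA
})
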