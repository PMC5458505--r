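local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Envelope-threshold spindle detection (previous method)
#'
#' Detects spindles on the gaussian-smoothed (300 ms window, 40 ms sigma)
#' Hilbert envelope of the 10-16 Hz bandpassed signal. Events must exceed
#' mean + 3 SD of the smoothed envelope for cortical channels (lowered to
#' mean + 1.5 SD for the lower-amplitude thalamic channels); start and stop
#' are the surrounding mean + 1 SD crossings; events must last 0.3-2 s.
#'
#' @param x Raw signal (N2/N3).
#' @param rate_hz Sampling rate.
#' @param region \code{"cortex"} or \code{"thalamus"}.
#' @param t0_s Time of the first sample.
#' @return Data frame of events: onset_s, offset_s, peak_s, peak_amp
#'   (smoothed envelope peak), spindle_freq (NA), method.
#' @export
previous_method_detect <- function(x, rate_hz, region = c("cortex", "thalamus"),
                                   t0_s = 0) {
  region <- match.arg(region)
  env <- analytic_envelope(bandpass_filter(x, rate_hz, 10, 16))
  env <- smooth_signal(env, rate_hz,
                       kernel_spec("gaussian", window_s = 0.3, sigma_s = 0.04))
  mu <- mean(env); s <- stats::sd(env)
  det_thr <- mu + (if (region == "cortex") 3 else 1.5) * s
  edge_thr <- mu + 1 * s
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_s = numeric(0), peak_amp = numeric(0),
                      spindle_freq = numeric(0), method = character(0))
  if (s == 0 || !any(env > det_thr)) return(empty)
  above <- env > edge_thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    if (max(env[seg]) < det_thr) next
    dur <- length(seg) / rate_hz
    if (dur < 0.3 || dur > 2) next
    pk <- seg[which.max(env[seg])]
    out[[length(out) + 1L]] <-
      data.frame(onset_s = t0_s + (seg[1] - 1) / rate_hz,
                 offset_s = t0_s + (seg[length(seg)] - 1) / rate_hz,
                 peak_s = t0_s + (pk - 1) / rate_hz,
                 peak_amp = env[pk], spindle_freq = NA_real_,
                 method = "previous")
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Edge and amplitude envelopes for candidate-epoch spindle detection
#'
#' The edge envelope is the absolute value of the 10-16 Hz bandpassed
#' signal convolved with a unit-sum 400 ms Tukey moving average; it defines
#' candidate onsets/offsets. The amplitude envelope is the edge envelope
#' convolved again with a 600 ms Tukey moving average; its peaks locate
#' candidates. For a constant-amplitude sinusoid of amplitude A both
#' envelopes tend to 2A/pi.
#'
#' @param x Raw signal (> 1 s).
#' @param rate_hz Sampling rate.
#' @return List with numeric vectors \code{edge} and \code{amplitude}.
#' @export
compute_envelopes <- function(x, rate_hz) {
  if (length(x) <= rate_hz) stop("signal must be longer than 1 s")
  bp <- bandpass_filter(x, rate_hz, 10, 16)
  edge <- smooth_signal(abs(bp), rate_hz, kernel_spec("tukey_avg", 0.4))
  amplitude <- smooth_signal(edge, rate_hz, kernel_spec("tukey_avg", 0.6))
  list(edge = edge, amplitude = amplitude)
}

#' Candidate-epoch threshold from manual marks
#'
#' For each manually marked spindle, the largest local maximum of the
#' amplitude envelope inside the mark is its manual amplitude; the channel
#' threshold is the smallest manual amplitude. Marks containing no local
#' maximum are skipped with a warning.
#'
#' @param amplitude_env Amplitude envelope (from
#'   \code{\link{compute_envelopes}}).
#' @param rate_hz Sampling rate.
#' @param marks Data frame with onset_s, offset_s of manual spindle marks.
#' @param t0_s Time of the first envelope sample.
#' @return The threshold (smallest manual amplitude).
#' @export
candidate_threshold_from_marks <- function(amplitude_env, rate_hz, marks,
                                           t0_s = 0) {
  if (is.null(marks) || !nrow(marks)) stop("no marks: classifier cannot be trained")
  pk <- local_maxima(amplitude_env)
  pk_t <- t0_s + (pk - 1) / rate_hz
  amps <- rep(NA_real_, nrow(marks))
  for (i in seq_len(nrow(marks))) {
    inside <- pk[pk_t >= marks$onset_s[i] & pk_t <= marks$offset_s[i]]
    if (!length(inside)) {
      warning("mark ", i, " contains no amplitude-envelope maximum; skipped")
      next
    }
    amps[i] <- max(amplitude_env[inside])
  }
  if (all(is.na(amps))) stop("no usable marks: classifier cannot be trained")
  min(amps, na.rm = TRUE)
}

#' Locate candidate epochs
#'
#' A candidate epoch is built around every local maximum of the amplitude
#' envelope at or above \code{threshold}: its edge amplitude is the nearest
#' local maximum of the edge envelope, and its onset/offset are the bounds
#' of the contiguous interval around that edge peak where the edge envelope
#' is >= 0.45 x the edge amplitude. Epochs shorter than 300 ms are
#' discarded; overlapping epochs from distinct peaks are merged.
#'
#' @param edge_env,amplitude_env Envelopes from
#'   \code{\link{compute_envelopes}}.
#' @param rate_hz Sampling rate.
#' @param threshold Candidate threshold (> 0).
#' @param t0_s Time of the first envelope sample.
#' @return Data frame: onset_s, offset_s, peak_s, amp_env_peak, edge_amp.
#' @export
find_candidate_epochs <- function(edge_env, amplitude_env, rate_hz, threshold,
                                  t0_s = 0) {
  stopifnot(threshold > 0)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_s = numeric(0), amp_env_peak = numeric(0),
                      edge_amp = numeric(0))
  apk <- local_maxima(amplitude_env)
  apk <- apk[amplitude_env[apk] >= threshold]
  if (!length(apk)) return(empty)
  epk <- local_maxima(edge_env)
  if (!length(epk)) return(empty)
  n <- length(edge_env)
  rows <- lapply(apk, function(i) {
    ep <- epk[which.min(abs(epk - i))]
    ea <- edge_env[ep]
    lim <- 0.45 * ea
    a <- ep; while (a > 1L && edge_env[a - 1L] >= lim) a <- a - 1L
    b <- ep; while (b < n && edge_env[b + 1L] >= lim) b <- b + 1L
    c(a, b, i, amplitude_env[i], ea)
  })
  m <- do.call(rbind, rows)
  m <- m[(m[, 2] - m[, 1]) / rate_hz >= 0.3, , drop = FALSE]
  if (!nrow(m)) return(empty)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    last <- merged[[length(merged)]]
    if (m[i, 1] <= last[2]) {            # overlap: merge, keep larger peak
      last[2] <- max(last[2], m[i, 2])
      if (m[i, 4] > last[4]) { last[3] <- m[i, 3]; last[4] <- m[i, 4]
                               last[5] <- m[i, 5] }
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- m[i, ]
  }
  m <- do.call(rbind, merged)
  data.frame(onset_s = t0_s + (m[, 1] - 1) / rate_hz,
             offset_s = t0_s + (m[, 2] - 1) / rate_hz,
             peak_s = t0_s + (m[, 3] - 1) / rate_hz,
             amp_env_peak = m[, 4], edge_amp = m[, 5])
}

band_envelope <- function(x, rate_hz, low, high) {
  smooth_signal(abs(bandpass_filter(x, rate_hz, low, high)), rate_hz,
                kernel_spec("tukey_avg", 0.4))
}

#' Per-candidate spindle feature vectors
#'
#' Computes the 15 classifier metrics for each candidate epoch: amp (maximum
#' of the amplitude envelope), dur, FFT amplitude-spectrum features of the
#' mean-removed raw segment zero-padded to 4 s (spindle_power = max in
#' 10-16 Hz, nonspindle_power = max in 5-8 Hz, their ratio f_ratio,
#' spindle_freq = argmax in 10-16 Hz), band-envelope maxima over the epoch
#' (sband 10-16, lband 4-8, hband 18-25 Hz; 400 ms Tukey moving averages),
#' the sleep stage indicator (N3 = 1), and oscillation-peak statistics of
#' the 10-16 Hz bandpassed segment (npeaks with prominence >= 10% of the
#' segment envelope peak, peakrate = npeaks/dur, mean and SD of the
#' inter-peak intervals, and pr = 1 if peakrate lies within 10-16 /s).
#'
#' @param cands Candidate data frame from \code{\link{find_candidate_epochs}}.
#' @param x Raw signal.
#' @param rate_hz Sampling rate.
#' @param stages Stage interval data frame (onset_s, offset_s, stage).
#' @param envs Optional precomputed \code{\link{compute_envelopes}} result.
#' @param t0_s Time of the first sample.
#' @return Data frame with one row per candidate and 15 feature columns.
#' @export
extract_features <- function(cands, x, rate_hz, stages = NULL, envs = NULL,
                             t0_s = 0) {
  if (is.null(envs)) envs <- compute_envelopes(x, rate_hz)
  bp <- bandpass_filter(x, rate_hz, 10, 16)
  lenv <- band_envelope(x, rate_hz, 4, 8)
  henv <- band_envelope(x, rate_hz, 18, 25)
  n_fft <- as.integer(4 * rate_hz)   # >= 4 s for 0.25 Hz resolution
  max_len <- vapply(seq_len(nrow(cands)), function(k)
    as.integer(round((cands$offset_s[k] - cands$onset_s[k]) * rate_hz)) + 1L,
    integer(1))
  if (length(max_len) && max(max_len) > n_fft) n_fft <- max(max_len)
  freqs <- (seq_len(n_fft %/% 2) - 1) * rate_hz / n_fft
  i_sp <- which(freqs >= 10 & freqs <= 16)
  i_ns <- which(freqs >= 5 & freqs <= 8)
  n <- length(x)
  out <- lapply(seq_len(nrow(cands)), function(k) {
    i0 <- max(1L, round((cands$onset_s[k] - t0_s) * rate_hz) + 1L)
    i1 <- min(n, round((cands$offset_s[k] - t0_s) * rate_hz) + 1L)
    if (i1 - i0 + 1L < 2 * rate_hz / 10) {
      stop("epoch shorter than two cycles at 10 Hz")
    }
    seg <- x[i0:i1] - mean(x[i0:i1])
    dur <- (i1 - i0) / rate_hz
    sp <- Mod(stats::fft(c(seg, numeric(n_fft - length(seg)))))[seq_len(n_fft %/% 2)]
    spindle_power <- max(sp[i_sp])
    nonspindle_power <- max(sp[i_ns])
    spindle_freq <- freqs[i_sp][which.max(sp[i_sp])]
    bseg <- bp[i0:i1]
    pk <- local_maxima(bseg)
    pk <- pk[bseg[pk] >= 0.1 * max(envs$edge[i0:i1])]
    npeaks <- length(pk)
    intv <- diff(pk) / rate_hz
    peakrate <- npeaks / dur
    data.frame(
      amp = max(envs$amplitude[i0:i1]), dur = dur,
      spindle_power = spindle_power, nonspindle_power = nonspindle_power,
      f_ratio = spindle_power / nonspindle_power,
      spindle_freq = spindle_freq,
      sband_amp = max(envs$edge[i0:i1]),
      lband_amp = max(lenv[i0:i1]), hband_amp = max(henv[i0:i1]),
      stage = as.integer(!is.null(stages) &&
                           identical(stage_of_time(cands$onset_s[k],
                                                   stages), "N3")),
      npeaks = npeaks, peakrate = peakrate,
      peak_intv_mean = if (length(intv)) mean(intv) else NA_real_,
      peak_intv_std = if (length(intv) > 1) stats::sd(intv) else 0,
      pr = as.integer(peakrate >= 10 & peakrate <= 16))
  })
  out <- do.call(rbind, out)
  # single-peak epochs: no interval statistics; use the duration as a
  # neutral stand-in so the design matrix stays complete
  out$peak_intv_mean[is.na(out$peak_intv_mean)] <- out$dur[is.na(out$peak_intv_mean)]
  out
}

#' Label candidate epochs against manual marks
#'
#' Candidates overlapping a manual mark by any amount are spindles (1);
#' candidates inside the marked periods but matching no mark are
#' non-spindles (0); candidates outside the marked periods are unlabelled
#' (NA, scored only).
#'
#' @param cands Candidate data frame.
#' @param marks Manual spindle marks (onset_s, offset_s).
#' @param mark_periods Intervals of exhaustively marked time.
#' @return Integer vector of labels (1/0/NA).
#' @export
label_candidates <- function(cands, marks, mark_periods) {
  lab <- rep(NA_integer_, nrow(cands))
  if (!nrow(cands)) return(lab)
  inside <- rep(FALSE, nrow(cands))
  for (i in seq_len(nrow(mark_periods))) {
    inside <- inside | (cands$onset_s >= mark_periods$onset_s[i] &
                          cands$offset_s <= mark_periods$offset_s[i])
  }
  lab[inside] <- 0L
  for (i in seq_len(nrow(marks))) {
    hit <- cands$offset_s >= marks$onset_s[i] &
      cands$onset_s <= marks$offset_s[i]
    lab[hit & inside] <- 1L
  }
  lab
}
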