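#' Downstate detection parameters
#'
#' @param band_hz Slow-wave filter band (default 0.1-4 Hz).
#' @param zc_dur_s Admissible time between consecutive zero crossings in
#'   seconds; default \code{c(0.25, 3)}, strict mode \code{c(0.25, 1)}.
#' @param keep_fraction Fraction of most extreme peaks retained per sign;
#'   default 0.40, strict mode 0.20.
#' @param gamma_band_hz High-gamma band used for polarity assignment
#'   (default 60-100 Hz).
#' @param artifact_sd_mult Amplitude rejection threshold in SDs of the
#'   epoched absolute raw signal (default 7).
#' @param epoch_s Epoch around DS peaks for artifact screening
#'   (default \code{c(-3, 3)}).
#' @param mode \code{"default"} or \code{"strict"}; strict sets
#'   \code{zc_dur_s = c(0.25, 1)} and \code{keep_fraction = 0.20}.
#' @return An object of class \code{ds_params}.
#' @export
ds_params <- function(band_hz = c(0.1, 4), zc_dur_s = c(0.25, 3),
                      keep_fraction = 0.40, gamma_band_hz = c(60, 100),
                      artifact_sd_mult = 7, epoch_s = c(-3, 3),
                      mode = c("default", "strict")) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    zc_dur_s <- c(0.25, 1)
    keep_fraction <- 0.20
  }
  if (keep_fraction <= 0 || keep_fraction > 0.5) {
    stop("keep_fraction must lie in (0, 0.5]")
  }
  if (diff(zc_dur_s) <= 0) stop("zc_dur_s must be an increasing pair")
  structure(list(band_hz = band_hz, zc_dur_s = zc_dur_s,
                 keep_fraction = keep_fraction, gamma_band_hz = gamma_band_hz,
                 artifact_sd_mult = artifact_sd_mult, epoch_s = epoch_s,
                 mode = mode),
            class = "ds_params")
}

#' Detect slow waves from zero crossings
#'
#' Filters the signal to the slow-wave band and returns one wave per pair of
#' consecutive zero crossings whose separation lies within
#' \code{p$zc_dur_s}. The peak is the extremum of the filtered signal
#' between the crossings; its signed amplitude is in filtered units.
#'
#' @param x Numeric vector of raw samples (already restricted to sleep;
#'   stage masking is handled by \code{\link{detect_downstates}}).
#' @param rate_hz Sampling rate in Hz.
#' @param p A \code{\link{ds_params}}.
#' @param t0_s Time of the first sample (default 0).
#' @return Data frame with columns channel-free wave geometry:
#'   \code{zc_start_s}, \code{zc_end_s}, \code{peak_s}, \code{peak_amp}.
#' @export
detect_slow_waves <- function(x, rate_hz, p = ds_params(), t0_s = 0) {
  if (length(x) < 2 * rate_hz / p$band_hz[1]) {
    stop("signal shorter than two periods of the lower band edge")
  }
  xf <- bandpass_filter(x, rate_hz, p$band_hz[1], p$band_hz[2])
  s <- sign(xf)
  s[s == 0] <- 1
  zc <- which(diff(s) != 0)            # last sample before each crossing
  out <- list()
  if (length(zc) >= 2) {
    # linear interpolation of crossing times
    tz <- (zc - 1 + xf[zc] / (xf[zc] - xf[zc + 1])) / rate_hz
    dur <- diff(tz)
    ok <- which(dur >= p$zc_dur_s[1] & dur <= p$zc_dur_s[2])
    if (length(ok)) {
      pk_i <- vapply(ok, function(i) {
        seg <- (zc[i] + 1L):zc[i + 1L]
        seg[which.max(abs(xf[seg]))]
      }, integer(1))
      out <- data.frame(zc_start_s = t0_s + tz[ok],
                        zc_end_s = t0_s + tz[ok + 1L],
                        peak_s = t0_s + (pk_i - 1) / rate_hz,
                        peak_amp = xf[pk_i])
    }
  }
  if (!length(out)) {
    out <- data.frame(zc_start_s = numeric(0), zc_end_s = numeric(0),
                      peak_s = numeric(0), peak_amp = numeric(0))
  }
  out
}

#' Retain the most extreme slow-wave peaks
#'
#' Keeps the \code{keep_fraction} of positive-peak waves with the largest
#' amplitudes and the \code{keep_fraction} of negative-peak waves with the
#' most negative amplitudes; counts are \code{floor(n_sign * keep_fraction)}
#' per sign. Amplitude ties are broken in favour of the earlier peak. The
#' result is sorted by peak time and therefore invariant to input order.
#'
#' @param waves Data frame from \code{\link{detect_slow_waves}}.
#' @param keep_fraction Proportion in (0, 0.5].
#' @return Subset of \code{waves}.
#' @export
select_extreme_peaks <- function(waves, keep_fraction = 0.40) {
  if (keep_fraction <= 0 || keep_fraction > 0.5) {
    stop("keep_fraction must lie in (0, 0.5]")
  }
  if (!nrow(waves)) stop("no waves supplied")
  pick <- function(w, sgn) {
    n_keep <- floor(nrow(w) * keep_fraction)
    if (n_keep < 1) return(w[0, ])
    o <- order(sgn * w$peak_amp, w$peak_s, decreasing = c(TRUE, FALSE),
               method = "radix")
    w[o[seq_len(n_keep)], ]
  }
  pos <- pick(waves[waves$peak_amp > 0, , drop = FALSE], 1)
  neg <- pick(waves[waves$peak_amp <= 0, , drop = FALSE], -1)
  out <- rbind(pos, neg)
  out[order(out$peak_s), , drop = FALSE]
}

# mean envelope in [win] s around each event peak, relative to the epoch mean
peak_locked_modulation <- function(env, rate_hz, peaks_s, win, epoch_s) {
  n <- length(env)
  vapply(peaks_s, function(t0) {
    iw <- round((t0 + win) * rate_hz) + 1L
    ie <- round((t0 + epoch_s) * rate_hz) + 1L
    iw <- pmax(1L, pmin(n, iw)); ie <- pmax(1L, pmin(n, ie))
    mean(env[iw[1]:iw[2]]) / mean(env[ie[1]:ie[2]])
  }, numeric(1))
}

#' Assign downstate polarity from high-gamma behaviour
#'
#' For cortical channels, the wave sign whose peak-locked mean high-gamma
#' envelope (within +/- 250 ms of the peak) is reduced relative to the
#' epoch-wide baseline is labelled the downstate. For thalamic channels
#' (which lack baseline high gamma), the tentative downstate sign is the one
#' whose peaks are followed by both higher spindle-band (10-16 Hz) peak
#' amplitude within 0-500 ms and a high-gamma increase at the
#' down-to-upstate transition (100-400 ms after the peak); this is validated
#' by splitting the downstates into the top and bottom 10% of spindle-band
#' amplitudes and requiring the transition gamma increase (relative to the
#' immediately pre-peak gamma) in both strata.
#'
#' A two-sample t-test (p < 0.05) between the per-event gamma modulation of
#' the two signs guards against assigning polarity from chance asymmetry;
#' without a significant asymmetry the channel is rejected with a
#' "polarity undetermined" error.
#'
#' @param waves Data frame of selected waves (both signs present;
#'   >= 20 per sign).
#' @param x Raw signal of the channel.
#' @param rate_hz Sampling rate.
#' @param region \code{"cortex"} or \code{"thalamus"}.
#' @param p A \code{\link{ds_params}}.
#' @return List with \code{ds_sign} (+1 or -1), \code{waves} (with added
#'   logical \code{is_downstate}), and the diagnostic statistics.
#' @export
assign_polarity <- function(waves, x, rate_hz, region = c("cortex", "thalamus"),
                            p = ds_params()) {
  region <- match.arg(region)
  pos <- waves[waves$peak_amp > 0, ]
  neg <- waves[waves$peak_amp <= 0, ]
  if (nrow(pos) < 20 || nrow(neg) < 20) {
    stop("need at least 20 candidate waves per sign")
  }
  hi <- min(p$gamma_band_hz[2], rate_hz / 2 - 1)
  genv <- analytic_envelope(bandpass_filter(x, rate_hz, p$gamma_band_hz[1], hi))
  if (region == "cortex") {
    m_pos <- peak_locked_modulation(genv, rate_hz, pos$peak_s,
                                    c(-0.25, 0.25), p$epoch_s)
    m_neg <- peak_locked_modulation(genv, rate_hz, neg$peak_s,
                                    c(-0.25, 0.25), p$epoch_s)
    tt <- stats::t.test(m_pos, m_neg)
    if (tt$p.value >= 0.05) {
      stop("polarity undetermined: no significant high-gamma asymmetry")
    }
    ds_sign <- if (mean(m_neg) < mean(m_pos)) -1 else 1
    stats_out <- list(gamma_mod_pos = mean(m_pos), gamma_mod_neg = mean(m_neg),
                      p_value = tt$p.value)
  } else {
    senv <- analytic_envelope(bandpass_filter(x, rate_hz, 10, 16))
    sp_amp <- function(w) vapply(w$peak_s, function(t0) {
      i <- round((t0 + c(0, 0.5)) * rate_hz) + 1L
      i <- pmax(1L, pmin(length(senv), i))
      max(senv[i[1]:i[2]])
    }, numeric(1))
    # transition increase judged against the immediately pre-peak gamma
    # (thalamic baseline gamma is near-absent; the wide epoch mean would be
    # inflated by neighbouring transitions)
    trans_mod <- function(w) peak_locked_modulation(genv, rate_hz, w$peak_s,
                                                    c(0.1, 0.4), c(-0.6, -0.1))
    sp_pos <- sp_amp(pos); sp_neg <- sp_amp(neg)
    g_pos <- trans_mod(pos); g_neg <- trans_mod(neg)
    score <- function(sp, g) mean(log(sp)) + mean(log(g))
    tt <- stats::t.test(log(g_pos), log(g_neg))
    if (tt$p.value >= 0.05) {
      stop("polarity undetermined: no significant high-gamma asymmetry")
    }
    ds_sign <- if (score(sp_neg, g_neg) > score(sp_pos, g_pos)) -1 else 1
    ds_w <- if (ds_sign < 0) neg else pos
    sp_ds <- if (ds_sign < 0) sp_neg else sp_pos
    g_ds <- if (ds_sign < 0) g_neg else g_pos
    q <- stats::quantile(sp_ds, c(0.1, 0.9))
    top <- g_ds[sp_ds >= q[2]]
    bot <- g_ds[sp_ds <= q[1]]
    ok_top <- length(top) >= 2 && mean(top) > 1 &&
      stats::t.test(log(top), alternative = "greater")$p.value < 0.05
    ok_bot <- length(bot) >= 2 && mean(bot) > 1 &&
      stats::t.test(log(bot), alternative = "greater")$p.value < 0.05
    if (!(ok_top && ok_bot)) {
      stop("polarity undetermined: transition gamma increase not present in ",
           "both spindle-amplitude strata")
    }
    stats_out <- list(spindle_amp_ds = mean(sp_ds),
                      gamma_mod_top = mean(top), gamma_mod_bot = mean(bot),
                      p_value = tt$p.value)
  }
  waves$is_downstate <- if (ds_sign < 0) waves$peak_amp <= 0 else
    waves$peak_amp > 0
  c(list(ds_sign = ds_sign, waves = waves), stats_out)
}

#' Reject artifact-contaminated events
#'
#' An event is removed if, within its epoch, the raw signal contains a
#' sample-to-sample difference larger than \code{diff_threshold}, or an
#' absolute value larger than \code{sd_mult} times the SD of the absolute
#' raw signal pooled over all epochs of the channel. Events whose epoch does
#' not fit in the recording are dropped with a warning. The default
#' difference threshold is 10 times the channel's median absolute first
#' difference (an automated surrogate for a per-channel visual threshold;
#' flagged in the result's \code{diff_threshold} attribute).
#'
#' @param events Data frame with a \code{peak_s} (or \code{onset_s}) column.
#' @param x Raw signal.
#' @param rate_hz Sampling rate.
#' @param epoch_s Epoch around the anchor time, e.g. \code{c(-3, 3)} for
#'   downstates, \code{c(-2, 4)} around spindle starts.
#' @param diff_threshold Sharp-transient threshold in units/sample;
#'   \code{NULL} for the automated default.
#' @param sd_mult Amplitude threshold multiplier (default 7).
#' @param anchor Column anchoring the epoch (default \code{"peak_s"}).
#' @param pool_anchors Optional anchor times whose epochs define the pooled
#'   SD of the absolute signal (defaults to the events themselves); passing
#'   the pre-exclusion event set reproduces the pooling of the original
#'   procedure, in which artifact-contaminated epochs contribute to the
#'   threshold before being rejected.
#' @return Filtered events, with attributes \code{diff_threshold} and
#'   \code{n_rejected}.
#' @export
reject_artifact_events <- function(events, x, rate_hz, epoch_s = c(-3, 3),
                                   diff_threshold = NULL, sd_mult = 7,
                                   anchor = "peak_s", pool_anchors = NULL) {
  if (!nrow(events)) return(events)
  if (is.null(diff_threshold)) {
    diff_threshold <- 10 * stats::median(abs(diff(x)))
  }
  n <- length(x)
  t_anchor <- events[[anchor]]
  i0 <- round((t_anchor + epoch_s[1]) * rate_hz) + 1L
  i1 <- round((t_anchor + epoch_s[2]) * rate_hz) + 1L
  fits <- i0 >= 1L & i1 <= n
  if (any(!fits)) {
    warning(sum(!fits), " events dropped: epoch outside recording")
  }
  events <- events[fits, , drop = FALSE]
  i0 <- i0[fits]; i1 <- i1[fits]
  if (!nrow(events)) return(events)
  if (is.null(pool_anchors)) pool_anchors <- t_anchor[fits]
  p0 <- pmax(1L, round((pool_anchors + epoch_s[1]) * rate_hz) + 1L)
  p1 <- pmin(n, round((pool_anchors + epoch_s[2]) * rate_hz) + 1L)
  pooled <- unlist(lapply(seq_along(p0), function(k) abs(x[p0[k]:p1[k]])))
  amp_thr <- sd_mult * stats::sd(pooled)
  keep <- vapply(seq_along(i0), function(k) {
    seg <- x[i0[k]:i1[k]]
    !(any(abs(diff(seg)) > diff_threshold) || any(abs(seg) > amp_thr))
  }, logical(1))
  out <- events[keep, , drop = FALSE]
  attr(out, "diff_threshold") <- diff_threshold
  attr(out, "n_rejected") <- sum(!keep)
  out
}

# waves fully inside a stage interval and not touching an exclusion
mask_waves <- function(waves, stages, exclusions) {
  if (!nrow(waves)) return(waves)
  keep <- rep(FALSE, nrow(waves))
  for (i in seq_len(nrow(stages))) {
    keep <- keep | (waves$zc_start_s >= stages$onset_s[i] &
                      waves$zc_end_s <= stages$offset_s[i])
  }
  if (nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      keep <- keep & !(waves$zc_start_s <= exclusions$offset_s[i] &
                         waves$zc_end_s >= exclusions$onset_s[i])
    }
  }
  waves[keep, , drop = FALSE]
}

#' Detect downstates on every channel of a recording
#'
#' Runs the full per-channel chain: slow-wave detection from zero crossings
#' within N2/N3 (excluding marked intervals), percentile retention of
#' extreme peaks, high-gamma polarity assignment, and artifact rejection.
#' Channels whose polarity cannot be determined are skipped with a warning.
#'
#' @param rec A \code{\link{recording}}.
#' @param p A \code{\link{ds_params}}.
#' @return Data frame of events with columns channel, type
#'   (\code{"ds"}/\code{"upstate"}), zc_start_s, peak_s, zc_end_s, peak_amp,
#'   mode; attribute \code{polarity} holds the per-channel DS sign.
#' @export
detect_downstates <- function(rec, p = ds_params()) {
  stopifnot(inherits(rec, "ctc_recording"))
  out <- list()
  polarity <- list()
  for (j in seq_along(rec$channels)) {
    ch <- rec$channels[j]
    x <- rec$data[, j]
    waves <- detect_slow_waves(x, rec$rate_hz, p, t0_s = rec$t0_s)
    all_peaks <- waves$peak_s
    waves <- mask_waves(waves, rec$stages, rec$exclusions)
    if (nrow(waves) < 40) {
      warning("channel ", ch, ": too few slow waves; skipped")
      next
    }
    waves <- select_extreme_peaks(waves, p$keep_fraction)
    res <- tryCatch(assign_polarity(waves, x, rec$rate_hz, rec$regions[j], p),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("channel ", ch, ": ", conditionMessage(res), "; skipped")
      next
    }
    w <- res$waves
    w$type <- ifelse(w$is_downstate, "ds", "upstate")
    w <- reject_artifact_events(w, x, rec$rate_hz, p$epoch_s,
                                sd_mult = p$artifact_sd_mult,
                                pool_anchors = all_peaks)
    w$channel <- ch
    w$mode <- p$mode
    polarity[[ch]] <- res$ds_sign
    out[[ch]] <- w[, c("channel", "type", "zc_start_s", "peak_s", "zc_end_s",
                       "peak_amp", "mode")]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(channel = character(0), type = character(0),
               zc_start_s = numeric(0), peak_s = numeric(0),
               zc_end_s = numeric(0), peak_amp = numeric(0),
               mode = character(0))
  rownames(res) <- NULL
  attr(res, "polarity") <- polarity
  res
}
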