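#' Peri-event histogram of event lags
#'
#' Counts target events in fixed-width lag bins relative to each reference
#' event; every (reference, target) pair whose lag falls inside the window
#' is counted. Bin edges sit at integer multiples of \code{bin_s}.
#'
#' @param ref_times,target_times Sorted event times in seconds.
#' @param bin_s Bin width (default 0.05).
#' @param window_s Half-width of the lag window in seconds (default 2).
#' @return List of class \code{event_histogram} with \code{breaks},
#'   \code{mids}, \code{counts}.
#' @export
event_histogram <- function(ref_times, target_times, bin_s = 0.05,
                            window_s = 2) {
  nb <- ceiling(window_s / bin_s)
  breaks <- seq(-nb, nb) * bin_s
  counts <- integer(2 * nb)
  if (!length(ref_times)) {
    warning("no reference events: returning an all-zero histogram")
  } else if (length(target_times)) {
    for (t0 in ref_times) {
      lag <- target_times - t0
      lag <- lag[lag >= breaks[1] & lag < breaks[length(breaks)]]
      if (length(lag)) {
        idx <- floor(lag / bin_s) + nb + 1L
        for (i in idx) counts[i] <- counts[i] + 1L
      }
    }
  }
  structure(list(breaks = breaks, mids = breaks[-1] - bin_s / 2,
                 counts = counts, bin_s = bin_s, window_s = window_s),
            class = "event_histogram")
}

#' @export
print.event_histogram <- function(x, ...) {
  cat(sprintf("<event_histogram> %d pairs in +/- %g s (%g ms bins)\n",
              sum(x$counts), x$window_s, 1000 * x$bin_s))
  invisible(x)
}

#' Plot method for peri-event histograms
#' @param x An \code{event_histogram}.
#' @param ... Passed to \code{barplot}.
#' @export
plot.event_histogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = round(x$mids, 3), space = 0,
                    xlab = "lag (s)", ylab = "count", ...)
  invisible(x)
}

#' Binomial test of temporal order
#'
#' Tests the null hypothesis of random temporal order: counts target events
#' falling before versus after a reference event within \code{window_s}
#' (every pair counted by default; \code{nearest_only} counts each
#' reference's nearest target once), excludes exact zero lags, and applies
#' a two-sided exact binomial test with success probability 1/2.
#'
#' @param ref_times,target_times Event times in seconds.
#' @param window_s Half-window (default 0.5).
#' @param alpha_adjusted Per-test significance level (after any multiple
#'   comparison correction; default 0.05).
#' @param nearest_only Count only each reference's nearest target.
#' @return List of class \code{order_test}: n_before, n_after, p_two_sided,
#'   alpha_adjusted, significant, direction.
#' @export
binomial_order_test <- function(ref_times, target_times, window_s = 0.5,
                                alpha_adjusted = 0.05, nearest_only = FALSE) {
  n_before <- 0L; n_after <- 0L
  for (t0 in ref_times) {
    lag <- target_times - t0
    lag <- lag[abs(lag) < window_s & lag != 0]
    if (nearest_only && length(lag)) lag <- lag[which.min(abs(lag))]
    n_before <- n_before + sum(lag < 0)
    n_after <- n_after + sum(lag > 0)
  }
  n <- n_before + n_after
  if (n == 0) stop("no counted pairs: order test undefined")
  p <- stats::binom.test(n_before, n, 0.5)$p.value
  sig <- p < alpha_adjusted
  structure(list(n_before = n_before, n_after = n_after, p_two_sided = p,
                 alpha_adjusted = alpha_adjusted, significant = sig,
                 direction = if (!sig) "none" else
                   if (n_before > n_after) "target-leads" else "ref-leads"),
            class = "order_test")
}

#' @export
print.order_test <- function(x, ...) {
  cat(sprintf("<order_test> before %d / after %d, p = %.3g (%s at %.2g)\n",
              x$n_before, x$n_after, x$p_two_sided,
              if (x$significant) x$direction else "not significant",
              x$alpha_adjusted))
  invisible(x)
}

#' Bonferroni-adjusted per-test level
#'
#' @param alpha Family-wise level.
#' @param n_tests Number of tests (>= 1).
#' @return alpha / n_tests.
#' @examples
#' bonferroni_level(0.05, 64)  # 0.00078125
#' @export
bonferroni_level <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Conditional thalamic downstate probability matrix
#'
#' Diagonal cell (i, i): probability of a thalamic DS peak within
#' \code{window_s} after a DS peak on cortical channel i. Off-diagonal cell
#' (i, j): the same probability conditioned on channel j also producing a
#' DS within \code{window_s} after channel i's DS. Each off-diagonal cell
#' is tested by a two-sample chi-square comparing the conditioned events
#' against their complement (channel-i DSs without a channel-j DS) -
#' disjoint groups, so the test is calibrated - Bonferroni corrected over
#' the off-diagonal cells.
#'
#' @param cortical_events Named list of cortical DS peak time vectors.
#' @param thalamic_events Thalamic DS peak times (one channel).
#' @param window_s Coupling window (default 0.5).
#' @param alpha Family-wise level for the chi-square tests (default 0.05).
#' @return List with \code{prob} (matrix), \code{n} (conditioning counts),
#'   \code{p_value} (off-diagonal, NA on diagonal), \code{significant},
#'   \code{alpha_adjusted}.
#' @export
conditional_ds_probability <- function(cortical_events, thalamic_events,
                                       window_s = 0.5, alpha = 0.05) {
  nc <- length(cortical_events)
  chs <- names(cortical_events)
  if (is.null(chs)) chs <- paste0("c", seq_len(nc))
  prob <- matrix(NA_real_, nc, nc, dimnames = list(chs, chs))
  nmat <- matrix(0L, nc, nc, dimnames = list(chs, chs))
  succ <- matrix(0L, nc, nc)
  has_thal_after <- function(t) {
    vapply(t, function(t0) any(thalamic_events > t0 &
                                 thalamic_events <= t0 + window_s),
           logical(1))
  }
  succ_c <- matrix(0L, nc, nc)
  nmat_c <- matrix(0L, nc, nc)
  for (i in seq_len(nc)) {
    ti <- cortical_events[[i]]
    if (!length(ti)) next
    hit <- has_thal_after(ti)
    for (j in seq_len(nc)) {
      cond <- if (i == j) rep(TRUE, length(ti)) else
        vapply(ti, function(t0) any(cortical_events[[j]] > t0 &
                                      cortical_events[[j]] <= t0 + window_s),
               logical(1))
      nmat[i, j] <- sum(cond)
      succ[i, j] <- sum(hit & cond)
      prob[i, j] <- if (sum(cond)) mean(hit[cond]) else NA_real_
      nmat_c[i, j] <- sum(!cond)
      succ_c[i, j] <- sum(hit & !cond)
    }
  }
  n_tests <- nc * (nc - 1)
  alpha_adj <- if (n_tests >= 1) bonferroni_level(alpha, max(1, n_tests)) else
    alpha
  pmat <- matrix(NA_real_, nc, nc, dimnames = list(chs, chs))
  if (nc > 1) {
    for (i in seq_len(nc)) for (j in seq_len(nc)) {
      if (i == j || nmat[i, j] == 0 || nmat_c[i, j] == 0) next
      pmat[i, j] <- suppressWarnings(
        stats::prop.test(c(succ[i, j], succ_c[i, j]),
                         c(nmat[i, j], nmat_c[i, j]),
                         correct = FALSE)$p.value)
    }
  }
  list(prob = prob, n = nmat, p_value = pmat,
       significant = !is.na(pmat) & pmat < alpha_adj,
       alpha_adjusted = alpha_adj)
}

#' Cortico-thalamic downstate delay
#'
#' For each significant cortex-to-thalamus pair, averages the 0.1-4 Hz
#' filtered cortical signal locked to thalamic DS peaks over events in
#' which a cortical DS occurred within \code{window_s} before the thalamic
#' DS; the pair latency is the time of the waveform minimum in
#' [-window_s, 0] s. The overall delay is the mean over pairs.
#'
#' @param pairs Data frame with columns \code{cortical}, \code{thalamic}
#'   (channel names of the qualifying pairs).
#' @param rec A \code{\link{recording}}.
#' @param ds_events DS event data frame (from
#'   \code{\link{detect_downstates}}; rows with type "ds").
#' @param window_s Qualifying window (default 0.5).
#' @param min_events Minimum qualifying events per pair (default 10).
#' @return List of class \code{delay_estimate}: value_s (mean over pairs,
#'   negative = cortex leads), per_pair, n_events.
#' @export
corticothalamic_ds_delay <- function(pairs, rec, ds_events, window_s = 0.5,
                                     min_events = 10) {
  per_pair <- numeric(0)
  n_events <- integer(0)
  labels <- character(0)
  for (k in seq_len(nrow(pairs))) {
    cch <- pairs$cortical[k]; tch <- pairs$thalamic[k]
    ct <- ds_events$peak_s[ds_events$channel == cch & ds_events$type == "ds"]
    tt <- ds_events$peak_s[ds_events$channel == tch & ds_events$type == "ds"]
    qual <- tt[vapply(tt, function(t0) any(ct >= t0 - window_s & ct < t0),
                      logical(1))]
    if (length(qual) < min_events) next
    xf <- bandpass_filter(rec$data[, cch], rec$rate_hz, 0.1, 4)
    half <- round(window_s * rec$rate_hz)
    n <- length(xf)
    acc <- numeric(half + 1)
    used <- 0L
    for (t0 in qual) {
      i0 <- round((t0 - rec$t0_s) * rec$rate_hz) + 1L
      if (i0 - half < 1 || i0 > n) next
      acc <- acc + xf[(i0 - half):i0]
      used <- used + 1L
    }
    if (used < min_events) next
    lat <- (which.min(acc) - 1L - half) / rec$rate_hz
    per_pair <- c(per_pair, lat)
    n_events <- c(n_events, used)
    labels <- c(labels, paste(cch, tch, sep = "->"))
  }
  if (!length(per_pair)) stop("no pair had enough qualifying events")
  structure(list(kind = "ct_ds_delay", value_s = mean(per_pair),
                 per_pair = stats::setNames(per_pair, labels),
                 n_events = stats::setNames(n_events, labels)),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("<delay_estimate> %s: %.1f ms", x$kind, 1000 * x$value_s))
  if (!is.null(x$p_value)) cat(sprintf(" (paired t-test p = %.3g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Downstate onset from polynomial inflection
#'
#' Fits a degree-20 polynomial to an averaged DS waveform (on a time axis
#' normalised to [-1, 1] for conditioning) and returns the real root of its
#' second derivative closest to \code{guess_s}.
#'
#' @param waveform Averaged waveform samples.
#' @param rate_hz Sampling rate.
#' @param t_start_s Time of the first waveform sample relative to the DS
#'   peak (e.g. -1 for a [-1, 1] s epoch).
#' @param guess_s Approximate (visually determined) onset time.
#' @param degree Polynomial degree (default 20).
#' @return Inflection time in seconds.
#' @export
ds_onset_latency <- function(waveform, rate_hz, t_start_s, guess_s,
                             degree = 20) {
  n <- length(waveform)
  t <- t_start_s + (seq_len(n) - 1) / rate_hz
  ctr <- mean(range(t)); scl <- diff(range(t)) / 2
  u <- (t - ctr) / scl
  fit <- stats::lm(waveform ~ stats::poly(u, degree, raw = TRUE))
  beta <- stats::coef(fit)                      # beta0 + beta1 u + ...
  beta[is.na(beta)] <- 0
  # second derivative coefficients in u
  d2 <- beta[-(1:2)] * (2:degree) * (1:(degree - 1))
  rts <- polyroot(d2)
  re <- Re(rts[abs(Im(rts)) < 1e-6])
  re <- re[re >= -1 & re <= 1]
  if (!length(re)) stop("no real inflection point in range")
  cand <- re * scl + ctr
  cand[which.min(abs(cand - guess_s))]
}

#' Latency of the histogram peak
#'
#' Centre of the maximal bin; ties are broken toward the bin nearest zero
#' lag, then toward the earlier bin.
#'
#' @param h An \code{\link{event_histogram}}.
#' @return Latency in seconds.
#' @export
histogram_peak_latency <- function(h) {
  if (all(h$counts == 0)) stop("all-zero histogram: no peak")
  mx <- which(h$counts == max(h$counts))
  if (length(mx) > 1) {
    d0 <- abs(h$mids[mx])
    mx <- mx[d0 == min(d0)]
    mx <- mx[which.min(h$mids[mx])]
  }
  h$mids[mx]
}

#' High-gamma peak delay between thalamus and cortex at spindle troughs
#'
#' Computes the 55-100 Hz analytic amplitude in both structures, averages
#' it locked to thalamic spindle troughs over consecutive subsets of
#' \code{subset_size} troughs, spline interpolates each subset's average
#' waveform, and takes the time of its maximum within +/- \code{radius_s}
#' of the trough. The delay is the cortical minus the thalamic peak time,
#' averaged over subsets; a two-tailed paired t-test compares the
#' per-subset cortical and thalamic peak times.
#'
#' @param x_thal,x_cort Raw signals.
#' @param rate_hz Sampling rate.
#' @param trough_times_s Thalamic spindle trough times.
#' @param subset_size Troughs per subset (default 500).
#' @param radius_s Peak search radius (default 0.035).
#' @param t0_s Time of the first sample.
#' @return \code{delay_estimate} with value_s (mean delay over subsets),
#'   per-subset delays, and p_value (NA with a warning if fewer than
#'   \code{subset_size} troughs: single-group estimate).
#' @export
gamma_trough_delay <- function(x_thal, x_cort, rate_hz, trough_times_s,
                               subset_size = 500, radius_s = 0.035,
                               t0_s = 0) {
  hi <- min(100, rate_hz / 2 - 1)
  et <- analytic_envelope(bandpass_filter(x_thal, rate_hz, 55, hi))
  ec <- analytic_envelope(bandpass_filter(x_cort, rate_hz, 55, hi))
  half <- round(0.2 * rate_hz)
  n <- length(et)
  idx <- round((trough_times_s - t0_s) * rate_hz) + 1L
  idx <- idx[idx - half >= 1 & idx + half <= n]
  if (!length(idx)) stop("no troughs inside the recording")
  rel <- (-half):half
  peak_time <- function(avg) {
    # dense spline interpolation of the averaged waveform
    f <- stats::splinefun(rel / rate_hz, avg)
    tt <- seq(-radius_s, radius_s, by = 1e-4)
    tt[which.max(f(tt))]
  }
  avg_over <- function(env, ii) {
    acc <- numeric(length(rel))
    for (i in ii) acc <- acc + env[(i - half):(i + half)]
    acc / length(ii)
  }
  n_sub <- length(idx) %/% subset_size
  if (n_sub < 1) {
    warning("fewer than subset_size troughs: single-group estimate, no test")
    pt <- peak_time(avg_over(et, idx))
    pc <- peak_time(avg_over(ec, idx))
    return(structure(list(kind = "gamma_trough", value_s = pc - pt,
                          per_subset = pc - pt, p_value = NA_real_,
                          n_troughs = length(idx)),
                     class = "delay_estimate"))
  }
  lat_t <- numeric(n_sub); lat_c <- numeric(n_sub)
  for (g in seq_len(n_sub)) {
    ii <- idx[((g - 1) * subset_size + 1):(g * subset_size)]
    lat_t[g] <- peak_time(avg_over(et, ii))
    lat_c[g] <- peak_time(avg_over(ec, ii))
  }
  p <- if (n_sub >= 2) stats::t.test(lat_c, lat_t, paired = TRUE)$p.value else
    NA_real_
  structure(list(kind = "gamma_trough", value_s = mean(lat_c - lat_t),
                 per_subset = lat_c - lat_t,
                 thal_peak_s = lat_t, cort_peak_s = lat_c,
                 p_value = p, n_troughs = n_sub * subset_size),
            class = "delay_estimate")
}

#' Spindle enrichment around downstates
#'
#' The peak spindle-DS density per minute is
#' 20 * 60 * (count in the tallest 50 ms bin within +/- 500 ms of the DS
#' peaks) / n_DS; the overall density is n_spindles / total_minutes; the
#' enrichment factor is their ratio.
#'
#' @param spindle_onsets Spindle onset times.
#' @param ds_peaks DS peak times (>= 1).
#' @param total_minutes Minutes of N2/N3 over which spindles were detected.
#' @return List: peak_density_per_min, overall_density_per_min, factor.
#' @export
enrichment_factor <- function(spindle_onsets, ds_peaks, total_minutes) {
  if (total_minutes <= 0) stop("total_minutes must be > 0")
  if (!length(ds_peaks)) stop("no downstates")
  if (!length(spindle_onsets)) {
    return(list(peak_density_per_min = 0,
                overall_density_per_min = 0, factor = 0))
  }
  h <- event_histogram(ds_peaks, spindle_onsets, bin_s = 0.05, window_s = 0.5)
  peak <- 20 * 60 * max(h$counts) / length(ds_peaks)
  overall <- length(spindle_onsets) / total_minutes
  list(peak_density_per_min = peak, overall_density_per_min = overall,
       factor = peak / overall)
}

#' Normalised proportion of spindles coupled to downstates
#'
#' A spindle is coupled if its onset falls within [0, +0.75] s after any DS
#' peak (cortex) or within [-0.5, +0.25] s of any DS peak (thalamus). The
#' returned value is (coupled spindles / total spindles) /
#' (channel DS count / largest DS count within the subject).
#'
#' @param spindle_onsets Spindle onset times (>= 1).
#' @param ds_peaks DS peak times on the channel.
#' @param region \code{"cortex"} or \code{"thalamus"}.
#' @param ds_counts_in_subject DS counts of all the subject's channels.
#' @return List: raw_proportion, normalized, n_coupled.
#' @export
proportion_spindles_with_ds <- function(spindle_onsets, ds_peaks,
                                        region = c("cortex", "thalamus"),
                                        ds_counts_in_subject) {
  region <- match.arg(region)
  if (!length(spindle_onsets)) stop("no spindles")
  if (!length(ds_counts_in_subject)) stop("ds_counts_in_subject is empty")
  if (!length(ds_peaks)) {
    return(list(raw_proportion = NA_real_, normalized = NA_real_,
                n_coupled = NA_integer_))
  }
  win <- if (region == "cortex") c(0, 0.75) else c(-0.5, 0.25)
  coupled <- vapply(spindle_onsets, function(t0)
    any(t0 - ds_peaks >= win[1] & t0 - ds_peaks <= win[2]), logical(1))
  raw <- mean(coupled)
  norm <- raw / (length(ds_peaks) / max(ds_counts_in_subject))
  list(raw_proportion = raw, normalized = norm, n_coupled = sum(coupled))
}

#' Fraction of events overlapping events in another channel
#'
#' An event of list A overlaps if any part of it intersects any event of
#' list B; touching boundaries count as overlap.
#'
#' @param events_a,events_b Data frames with onset_s, offset_s.
#' @return List: fraction (of A overlapping B), n_overlap, matches (indices
#'   into B of the first overlapping event per A event, NA if none).
#' @export
overlap_fraction <- function(events_a, events_b) {
  na <- nrow(events_a)
  if (!na) return(list(fraction = NA_real_, n_overlap = 0L,
                       matches = integer(0)))
  matches <- rep(NA_integer_, na)
  for (i in seq_len(na)) {
    hit <- which(events_b$onset_s <= events_a$offset_s[i] &
                   events_b$offset_s >= events_a$onset_s[i])
    if (length(hit)) matches[i] <- hit[1]
  }
  list(fraction = mean(!is.na(matches)), n_overlap = sum(!is.na(matches)),
       matches = matches)
}

#' Spindle trough times from the bandpassed signal
#'
#' Local minima of the 10-16 Hz bandpassed signal within each spindle
#' event, used to anchor the high-gamma delay analysis.
#'
#' @param x Raw signal.
#' @param rate_hz Sampling rate.
#' @param events Spindle event data frame (onset_s, offset_s).
#' @param t0_s Time of the first sample.
#' @return Numeric vector of trough times.
#' @export
spindle_troughs <- function(x, rate_hz, events, t0_s = 0) {
  bp <- bandpass_filter(x, rate_hz, 10, 16)
  n <- length(bp)
  out <- lapply(seq_len(nrow(events)), function(k) {
    i0 <- max(1L, round((events$onset_s[k] - t0_s) * rate_hz) + 1L)
    i1 <- min(n, round((events$offset_s[k] - t0_s) * rate_hz) + 1L)
    seg <- -bp[i0:i1]
    pk <- local_maxima(seg)
    pk <- pk[seg[pk] > 0]
    t0_s + (i0 - 1L + pk - 1L) / rate_hz
  })
  sort(unlist(out))
}
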