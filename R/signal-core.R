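#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass filter to a signal. With
#' \code{zero_phase = TRUE} (the default) the filter is applied forward and
#' backward, so the magnitude response is squared and the phase response
#' cancels (no group delay). Edge transients are suppressed by reflecting the
#' signal at both ends before filtering.
#'
#' @param x Numeric vector of samples.
#' @param rate_hz Sampling rate in Hz.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   \code{0 < low_hz < high_hz < rate_hz/2}.
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward filtering (default \code{TRUE}).
#' @return Numeric vector of the same length as \code{x}.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 30, by = 1/256))
#' y <- bandpass_filter(x, 256, 0.1, 4)
#' @export
bandpass_filter <- function(x, rate_hz, low_hz, high_hz, order = 4L,
                            zero_phase = TRUE) {
  stopifnot(is.numeric(x), rate_hz > 0, order >= 1)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate_hz / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < rate_hz/2")
  }
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  n <- length(x)
  if (n < 4L) stop("signal too short to filter")
  # reflect enough samples to let the slowest passband component settle
  pad <- min(n - 1L, ceiling(3 * rate_hz / low_hz))
  lpad <- x[(pad + 1L):2L]
  rpad <- x[(n - 1L):(n - pad)]
  # taper the pads to zero at their outer ends so the circular junction of
  # the frequency-domain filter sees no discontinuity
  ramp <- 0.5 * (1 - cos(pi * (seq_len(pad) - 1) / pad))
  xp <- c(lpad * ramp, x, rpad * rev(ramp))
  if (zero_phase) {
    # forward-backward filtering has the squared Butterworth magnitude and
    # zero phase; apply it exactly in the frequency domain (time-domain
    # recursion of the 2*order-coefficient band filter is numerically
    # unstable for narrow normalized bands such as 0.1-4 Hz at 256 Hz)
    m <- stats::nextn(length(xp), c(2, 3, 5))  # fast mixed-radix FFT size
    xp <- c(xp, numeric(m - length(xp)))
    f <- (seq_len(m) - 1) * rate_hz / m
    f <- pmin(f, rate_hz - f)
    om <- rep(Inf, m)
    nz <- f > 0
    om[nz] <- abs((f[nz]^2 - low_hz * high_hz) /
                    (f[nz] * (high_hz - low_hz)))
    h2 <- 1 / (1 + om^(2 * order))       # |H|^2 of the analog prototype
    yp <- Re(stats::fft(stats::fft(xp) * h2, inverse = TRUE)) / m
  } else {
    bf <- signal::butter(order, c(low_hz, high_hz) / (rate_hz / 2),
                         type = "pass")
    yp <- as.numeric(signal::filter(bf, xp))
  }
  as.numeric(yp[(pad + 1L):(pad + n)])
}

#' Analytic amplitude (Hilbert envelope)
#'
#' Instantaneous amplitude of a signal, computed as the modulus of the
#' analytic signal. The analytic signal is built in the frequency domain by
#' zeroing negative frequencies and doubling positive ones.
#'
#' @param x Numeric vector, length >= 4; the mean is removed before the
#'   transform.
#' @return Non-negative numeric vector of the same length.
#' @export
analytic_envelope <- function(x) {
  if (length(x) < 4L) stop("signal too short for an analytic envelope")
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x - mean(x)) * h, inverse = TRUE) / n
  Mod(z)
}

#' Smoothing kernel specification
#'
#' Describes a unit-sum (moving-average) smoothing kernel: either a truncated
#' gaussian or a Tukey-tapered moving average.
#'
#' @param kind \code{"gaussian"} or \code{"tukey_avg"}.
#' @param window_s Kernel support in seconds (> 0).
#' @param sigma_s Gaussian width in seconds (gaussian only).
#' @param taper Tukey taper fraction in [0, 1] (tukey_avg only; default 0.5).
#' @return An object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(kind = c("gaussian", "tukey_avg"), window_s,
                        sigma_s = NULL, taper = 0.5) {
  kind <- match.arg(kind)
  if (!is.numeric(window_s) || window_s <= 0) stop("window_s must be > 0")
  if (kind == "gaussian") {
    if (is.null(sigma_s) || sigma_s <= 0) stop("gaussian kernel needs sigma_s > 0")
  } else if (taper < 0 || taper > 1) {
    stop("taper must lie in [0, 1]")
  }
  structure(list(kind = kind, window_s = window_s, sigma_s = sigma_s,
                 taper = taper), class = "kernel_spec")
}

#' Tukey (cosine-tapered) window
#'
#' @param n Window length in samples.
#' @param taper Fraction of the window inside the cosine taper (0 =
#'   rectangular, 1 = Hann).
#' @return Numeric vector of length \code{n} with values in [0, 1].
#' @export
tukey_window <- function(n, taper = 0.5) {
  stopifnot(n >= 1, taper >= 0, taper <= 1)
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (taper > 0) {
    lo <- t < taper / 2
    hi <- t > 1 - taper / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / taper - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / taper - 2 / taper + 1)))
  }
  w
}

kernel_weights <- function(k, rate_hz) {
  m <- max(1L, round(k$window_s * rate_hz))
  if (m %% 2 == 0) m <- m + 1L  # odd length => centred kernel
  if (k$kind == "gaussian") {
    t <- (seq_len(m) - (m + 1) / 2) / rate_hz
    w <- exp(-0.5 * (t / k$sigma_s)^2)
  } else {
    w <- tukey_window(m, k$taper)
  }
  w / sum(w)
}

#' Smooth a signal with a unit-sum kernel
#'
#' Centred convolution with a unit-sum kernel; a constant input maps to the
#' same constant. Edges are handled by reflection padding of one kernel
#' length, and the output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param rate_hz Sampling rate in Hz.
#' @param k A \code{\link{kernel_spec}}.
#' @return Smoothed numeric vector, same length as \code{x}.
#' @export
smooth_signal <- function(x, rate_hz, k) {
  stopifnot(inherits(k, "kernel_spec"), rate_hz > 0)
  w <- kernel_weights(k, rate_hz)
  m <- length(w)
  n <- length(x)
  if (m >= n) stop("kernel support must be shorter than the signal")
  half <- (m - 1L) / 2L
  if (half > 0) {
    xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  } else {
    xp <- x
  }
  y <- stats::filter(xp, w, sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Event-locked spectrogram with permutation significance
#'
#' Averages short-time Fourier power around a set of event times, corrects
#' each frequency row by its epoch-wide mean (log ratio), and marks cells
#' whose deviation is significant against a surrogate distribution obtained
#' by circularly shifting the event times.
#'
#' @param x Numeric vector of samples.
#' @param rate_hz Sampling rate in Hz.
#' @param event_times_s Event times in seconds (>= 10 events).
#' @param window_s Length-2 epoch window around each event, e.g.
#'   \code{c(-1, 1)}.
#' @param f_range_hz Length-2 frequency range of interest.
#' @param alpha Two-sided significance level for the mask (uncorrected).
#' @param stft_window_s Length of the Hann analysis window in seconds.
#' @param step_s Hop between analysis windows in seconds.
#' @param n_surrogate Number of circularly shifted surrogate event sets.
#' @return List with \code{time_s}, \code{freq_hz}, \code{power} (baseline
#'   corrected, dB), and logical \code{significant} of the same dimension.
#' @export
event_locked_spectrogram <- function(x, rate_hz, event_times_s, window_s,
                                     f_range_hz, alpha = 0.01,
                                     stft_window_s = 0.5, step_s = 0.025,
                                     n_surrogate = 200L) {
  if (length(event_times_s) < 10L) stop("need at least 10 events")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  n <- length(x)
  dur <- n / rate_hz
  win <- round(stft_window_s * rate_hz)
  half_win <- win %/% 2
  lo <- min(window_s); hi <- max(window_s)
  if (any(event_times_s + lo - stft_window_s / 2 < 0) ||
      any(event_times_s + hi + stft_window_s / 2 > dur)) {
    stop("epochs (plus analysis window) must fit within the recording")
  }
  taper <- tukey_window(win, 1)          # Hann
  freq <- (seq_len(win %/% 2 + 1L) - 1L) * rate_hz / win
  fi <- which(freq >= min(f_range_hz) & freq <= max(f_range_hz))
  centers <- seq(lo, hi, by = step_s)

  grid_power <- function(ev) {
    acc <- matrix(0, length(fi), length(centers))
    for (t0 in ev) {
      idx0 <- round((t0 + centers) * rate_hz) + 1L
      for (j in seq_along(centers)) {
        seg <- x[(idx0[j] - half_win):(idx0[j] - half_win + win - 1L)]
        sp <- Mod(stats::fft(taper * (seg - mean(seg))))^2
        acc[, j] <- acc[, j] + sp[fi]
      }
    }
    acc / length(ev)
  }

  p0 <- grid_power(event_times_s)
  base <- rowMeans(p0)
  obs <- 10 * log10(p0 / base)

  margin <- max(abs(lo), abs(hi)) + stft_window_s
  null_vals <- array(NA_real_, c(length(fi), length(centers), n_surrogate))
  for (s in seq_len(n_surrogate)) {
    shift <- stats::runif(1, margin, dur - margin)
    ev <- (event_times_s + shift) %% (dur - 2 * margin) + margin
    ps <- grid_power(ev)
    null_vals[, , s] <- 10 * log10(ps / rowMeans(ps))
  }
  pvals <- matrix(1, length(fi), length(centers))
  for (i in seq_along(fi)) {
    for (j in seq_along(centers)) {
      nv <- null_vals[i, j, ]
      p_hi <- (1 + sum(nv >= obs[i, j])) / (n_surrogate + 1)
      p_lo <- (1 + sum(nv <= obs[i, j])) / (n_surrogate + 1)
      pvals[i, j] <- min(1, 2 * min(p_hi, p_lo))
    }
  }
  list(time_s = centers, freq_hz = freq[fi], power = obs,
       significant = if (alpha >= 1) matrix(TRUE, length(fi), length(centers))
                     else pvals < alpha,
       p_value = pvals)
}
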