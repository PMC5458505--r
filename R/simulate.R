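#' Simulation configuration
#'
#' Parameters of the synthetic cortico-thalamic NREM recording generator.
#' The generator encodes the cortico-thalamo-cortical event sequence:
#' cortical downstates (DSs) arise as renewal processes per channel;
#' clusters of near-simultaneous cortical DSs induce thalamic DSs with a
#' probability increasing in the number of participating cortical channels
#' and a lag of ~218 ms; thalamic spindles start at the thalamic DS peak;
#' and thalamic spindles are projected to cortical channels with a ~15 ms
#' lag. Background is 1/f noise plus ongoing spindle-band (sigma) noise and
#' amplitude-modulated high-gamma band noise.
#'
#' @param rate_hz Sampling rate (256 or 1024; default 256).
#' @param duration_s Recording duration in seconds (default 1800).
#' @param n_cortical,n_thalamic Number of channels per region (default 4, 2).
#' @param ds_rate_per_min Cortical DS rate per channel per minute
#'   (default 16.3). The thalamic DS rate is emergent from the coupling;
#'   with the default coupling probabilities it is ~11.5 per minute.
#' @param spindle_rate_per_min Named vector with elements \code{thalamus}
#'   (default 7.1) and \code{cortex} (default 5); target event rates used to
#'   derive the spindle-release and projection probabilities.
#' @param ct_ds_delay_s Mean and SD of the cortical-to-thalamic DS peak lag
#'   in seconds (default \code{c(0.218, 0.066)}).
#' @param p_thal_ds_given_k Probability that a thalamic channel produces a DS
#'   given a cluster of k simultaneous cortical DSs; indexed by k, last value
#'   reused for larger k. Must be non-decreasing.
#' @param thal_spindle_onset_rel_ds_s Offset of thalamic spindle onset from
#'   the thalamic DS peak (default 0).
#' @param tc_spindle_lag_s Thalamic-to-cortical spindle lag (default 0.015).
#' @param cortical_spindle_rel_ds_s Nominal cortical spindle onset after the
#'   cortical DS peak implied by the coupling chain (default 0.25;
#'   informational, not separately enforced).
#' @param spindle_dur_s Range of spindle durations, within (0.3, 2]
#'   (default \code{c(0.9, 1.8)}).
#' @param spindle_freq_hz Range of spindle frequencies (default
#'   \code{c(10, 16)}).
#' @param ds_amp DS trough amplitude in uV, named per region (default
#'   cortex 50, thalamus 34; thalamic potentials are smaller).
#' @param spindle_amp Median spindle amplitude in uV, named per region
#'   (default cortex 18, thalamus 22 - thalamic recordings are dominated
#'   by clear spindles); per-event
#'   amplitudes are spindle_amp * (0.7 + 0.3 * lognormal(0,
#'   spindle_amp_sdlog)): a skewed distribution with a visibility floor at
#'   0.7 * spindle_amp, emulating that spindles distinguishable from the
#'   sigma background have a minimum discernible amplitude.
#' @param spindle_amp_sdlog Lognormal spread of spindle amplitudes, named
#'   per region (default cortex 0.55, thalamus 0.4).
#' @param spindle_amp_floor Visibility floor as a fraction of the median
#'   amplitude, named per region (default cortex 0.7, thalamus 0.6).
#' @param gamma_amp High-gamma carrier amplitude in uV (default 8).
#' @param sigma_amp RMS of the ongoing 6-22 Hz background in uV (default 2).
#' @param burst_rate_per_min Rate of non-spindle sigma-band distractor
#'   bursts per channel, named per region (default cortex 12, thalamus 4
#'   - the thalamus is dominated by clear spindles with little other
#'   transient activity); these brief, weak,
#'   broad-frequency (6-22 Hz) transients emulate the spindle-like
#'   background activity that produces non-spindle candidate epochs.
#' @param burst_amp Median distractor burst amplitude in uV (default 5).
#' @param white_amp RMS of broadband instrument noise in uV (default 12).
#' @param artifact_rate_per_min Rate of sharp high-amplitude artifact
#'   transients per channel (default 0.3); brief rectangular pulses of
#'   around \code{artifact_amp} uV emulating movement/electrical glitches,
#'   the target of the artifact-rejection stage.
#' @param artifact_amp Artifact pulse amplitude in uV (default 400).
#' @param delta_amp RMS of the ongoing 0.5-2 Hz (delta) background in uV,
#'   named per region; controls the rate of spontaneous slow half-waves
#'   against which the percentile retention operates (see vignette).
#' @param noise_amp RMS of the 1/f background in uV (default 10).
#' @param noise_exponent Power-spectral 1/f^a exponent, named per region
#'   (see the methods vignette for the calibration rationale).
#' @param noise_hp_hz Low-frequency roll-off corner of the background in Hz,
#'   named per region, emulating the acquisition high-pass; together with
#'   the exponent it sets the spontaneous slow-half-wave rate against which
#'   the percentile retention operates.
#' @param cluster_gap_s Maximum gap linking pooled cortical DS peaks into one
#'   cluster (default 0.25).
#' @param p_primary_projection Probability that a thalamic spindle is
#'   projected to its primary (directly connected) cortical channel
#'   (default 0.9); other channels receive diffuse projections at a rate
#'   derived from the target cortical spindle rate.
#' @param seed Integer RNG seed.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(rate_hz = 256, duration_s = 1800,
                       n_cortical = 4, n_thalamic = 2,
                       ds_rate_per_min = 16.3,
                       spindle_rate_per_min = c(thalamus = 7.1, cortex = 5),
                       ct_ds_delay_s = c(0.218, 0.066),
                       p_thal_ds_given_k = c(0.25, 0.46, 0.62, 0.72),
                       thal_spindle_onset_rel_ds_s = 0,
                       tc_spindle_lag_s = 0.015,
                       cortical_spindle_rel_ds_s = 0.25,
                       spindle_dur_s = c(0.9, 1.8),
                       spindle_freq_hz = c(10, 16),
                       ds_amp = c(cortex = 50, thalamus = 34),
                       spindle_amp = c(cortex = 18, thalamus = 18),
                       spindle_amp_sdlog = c(cortex = 0.55, thalamus = 0.4),
                       spindle_amp_floor = c(cortex = 0.7, thalamus = 0.6),
                       gamma_amp = 8, sigma_amp = 2,
                       burst_rate_per_min = c(cortex = 12, thalamus = 8),
                       burst_amp = 9,
                       white_amp = c(cortex = 12, thalamus = 16),
                       delta_amp = c(cortex = 5, thalamus = 1),
                       noise_amp = 6,
                       artifact_rate_per_min = 0.3, artifact_amp = 400,
                       noise_exponent = c(cortex = 2.5, thalamus = 2.8),
                       noise_hp_hz = c(cortex = 0.33, thalamus = 0.28),
                       cluster_gap_s = 0.25, p_primary_projection = 0.9,
                       seed = 1L) {
  stopifnot(rate_hz > 0, duration_s > 0, n_cortical >= 0, n_thalamic >= 0,
            ds_rate_per_min >= 0, all(spindle_rate_per_min >= 0),
            length(ct_ds_delay_s) == 2, ct_ds_delay_s[2] >= 0,
            all(is.finite(ct_ds_delay_s)))
  if (any(p_thal_ds_given_k < 0 | p_thal_ds_given_k > 1)) {
    stop("p_thal_ds_given_k must lie in [0, 1]")
  }
  if (any(diff(p_thal_ds_given_k) < 0)) {
    stop("p_thal_ds_given_k must be non-decreasing in k")
  }
  if (spindle_dur_s[1] <= 0.3 - 1e-9 || spindle_dur_s[2] > 2 + 1e-9 ||
      diff(spindle_dur_s) < 0) {
    stop("spindle_dur_s must be an increasing range within (0.3, 2]")
  }
  channels <- c(if (n_cortical) paste0("C", seq_len(n_cortical)),
                if (n_thalamic) paste0("T", seq_len(n_thalamic)))
  regions <- c(rep("cortex", n_cortical), rep("thalamus", n_thalamic))
  structure(list(rate_hz = rate_hz, duration_s = duration_s,
                 channels = channels, regions = regions,
                 ds_rate_per_min = ds_rate_per_min,
                 spindle_rate_per_min = spindle_rate_per_min,
                 ct_ds_delay_s = ct_ds_delay_s,
                 p_thal_ds_given_k = p_thal_ds_given_k,
                 thal_spindle_onset_rel_ds_s = thal_spindle_onset_rel_ds_s,
                 tc_spindle_lag_s = tc_spindle_lag_s,
                 cortical_spindle_rel_ds_s = cortical_spindle_rel_ds_s,
                 spindle_dur_s = spindle_dur_s,
                 spindle_freq_hz = spindle_freq_hz,
                 ds_amp = ds_amp, spindle_amp = spindle_amp,
                 spindle_amp_sdlog = spindle_amp_sdlog,
                 spindle_amp_floor = spindle_amp_floor,
                 gamma_amp = gamma_amp, sigma_amp = sigma_amp,
                 burst_rate_per_min = burst_rate_per_min,
                 burst_amp = burst_amp, white_amp = white_amp,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_amp = artifact_amp,
                 delta_amp = delta_amp,
                 noise_amp = noise_amp, noise_exponent = noise_exponent,
                 noise_hp_hz = noise_hp_hz,
                 cluster_gap_s = cluster_gap_s,
                 p_primary_projection = p_primary_projection, seed = seed),
            class = "sim_config")
}

rspindle_amp <- function(n, cfg, region) {
  fl <- region_param(cfg$spindle_amp_floor, region)
  sdl <- region_param(cfg$spindle_amp_sdlog, region)
  region_param(cfg$spindle_amp, region) *
    (fl + (1 - fl) * exp(stats::rnorm(n, 0, sdl)))
}

region_param <- function(p, region) {
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (!is.null(names(p)) && region %in% names(p)) return(unname(p[region]))
  unname(p[1])
}

empty_truth <- function() {
  data.frame(id = integer(0), channel = character(0), region = character(0),
             type = character(0), onset_s = numeric(0), offset_s = numeric(0),
             peak_s = numeric(0), amplitude = numeric(0),
             freq_hz = numeric(0), parent_id = integer(0))
}

#' Build the ground-truth event schedule
#'
#' Draws cortical DS times as independent renewal processes (gamma-shaped
#' inter-event intervals, shape 2), pools them into clusters of simultaneous
#' DSs, induces thalamic DSs from clusters with probability
#' \code{p_thal_ds_given_k[k]} and lag ~ Normal(ct_ds_delay_s), releases a
#' thalamic spindle at the thalamic DS peak with a probability derived from
#' the target thalamic spindle rate, and projects each thalamic spindle to
#' cortical channels with a probability derived from the target cortical
#' spindle rate, lagged by \code{tc_spindle_lag_s}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A data frame of scheduled events (the ground truth), one row per
#'   DS or spindle, with columns id, channel, region, type
#'   (\code{"ds"}/\code{"spindle"}), onset_s, offset_s, peak_s, amplitude,
#'   freq_hz (spindles), parent_id (coupling graph; NA for root events), and
#'   attribute \code{config}.
#' @export
build_event_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  margin <- 3
  dur <- cfg$duration_s
  ds_half_s <- 0.25
  cortical <- cfg$channels[cfg$regions == "cortex"]
  thalamic <- cfg$channels[cfg$regions == "thalamus"]
  ev <- list()
  next_id <- 1L
  add <- function(channel, region, type, onset, offset, peak, amp,
                  freq = NA_real_, parent = NA_integer_) {
    ids <- next_id - 1L + seq_along(onset)
    next_id <<- next_id + length(onset)
    data.frame(id = ids, channel = channel, region = region, type = type,
               onset_s = onset, offset_s = offset, peak_s = peak,
               amplitude = amp, freq_hz = freq, parent_id = parent)
  }

  # cortical DSs: shifted-gamma(2) renewal process per channel; the shift
  # enforces the minimum slow-oscillation period (trough + rebound) so
  # consecutive DS waveforms do not cancel
  cds <- list()
  rate_s <- cfg$ds_rate_per_min / 60
  ds_gap_s <- 1.1
  for (ch in cortical) {
    if (rate_s <= 0) next
    n_max <- ceiling(dur * rate_s * 2 + 20)
    mu_res <- max(0.1, 1 / rate_s - ds_gap_s)
    iei <- ds_gap_s + stats::rgamma(n_max, shape = 2, rate = 2 / mu_res)
    t <- margin + cumsum(iei)
    t <- t[t < dur - margin]
    if (!length(t)) next
    amp <- region_param(cfg$ds_amp, "cortex") * exp(stats::rnorm(length(t), 0, 0.1))
    cds[[ch]] <- add(ch, "cortex", "ds", t - ds_half_s, t + ds_half_s, t, amp)
  }
  cds_all <- if (length(cds)) do.call(rbind, cds) else empty_truth()
  ev <- c(ev, cds)

  # cluster pooled cortical DS peaks (gap-linkage)
  thal_ds <- list()
  if (nrow(cds_all) && length(thalamic) &&
      length(cfg$p_thal_ds_given_k)) {
    o <- order(cds_all$peak_s)
    pk <- cds_all$peak_s[o]
    cl <- cumsum(c(1, diff(pk) > cfg$cluster_gap_s))
    for (ch in thalamic) {
      t_list <- c(); p_list <- c()
      for (g in unique(cl)) {
        idx <- which(cl == g)
        k <- length(unique(cds_all$channel[o[idx]]))
        p_k <- cfg$p_thal_ds_given_k[min(k, length(cfg$p_thal_ds_given_k))]
        if (stats::runif(1) < p_k) {
          lag <- stats::rnorm(1, cfg$ct_ds_delay_s[1], cfg$ct_ds_delay_s[2])
          tt <- mean(pk[idx]) + lag
          if (tt > margin && tt < dur - margin) {
            t_list <- c(t_list, tt)
            # parent: cluster member closest to the cluster mean
            p_list <- c(p_list, cds_all$id[o[idx[which.min(abs(pk[idx] - mean(pk[idx])))]]])
          }
        }
      }
      if (length(t_list)) {
        # refractory: a thalamic channel cannot restart a DS mid-DS
        o <- order(t_list)
        t_list <- t_list[o]; p_list <- p_list[o]
        ok <- c(TRUE, diff(t_list) > 1.1)
        t_list <- t_list[ok]; p_list <- p_list[ok]
        amp <- region_param(cfg$ds_amp, "thalamus") * exp(stats::rnorm(length(t_list), 0, 0.1))
        thal_ds[[ch]] <- add(ch, "thalamus", "ds", t_list - ds_half_s,
                             t_list + ds_half_s, t_list, amp,
                             parent = p_list)
      }
    }
  }
  ev <- c(ev, thal_ds)
  thal_ds_all <- if (length(thal_ds)) do.call(rbind, thal_ds) else empty_truth()

  # thalamic spindles released at thalamic DS peaks
  thal_sp <- list()
  sp_rate_thal <- region_param(cfg$spindle_rate_per_min, "thalamus")
  if (nrow(thal_ds_all) && sp_rate_thal > 0) {
    for (ch in thalamic) {
      dsc <- thal_ds_all[thal_ds_all$channel == ch, ]
      if (!nrow(dsc)) next
      p_sp <- min(1, sp_rate_thal * (dur / 60) / nrow(dsc))
      sel <- stats::runif(nrow(dsc)) < p_sp
      if (!any(sel)) next
      n <- sum(sel)
      d <- stats::runif(n, cfg$spindle_dur_s[1], cfg$spindle_dur_s[2])
      f <- stats::runif(n, cfg$spindle_freq_hz[1], cfg$spindle_freq_hz[2])
      a <- rspindle_amp(n, cfg, "thalamus")
      on <- dsc$peak_s[sel] + cfg$thal_spindle_onset_rel_ds_s
      keep <- on > margin & on + d < dur - margin
      thal_sp[[ch]] <- add(ch, "thalamus", "spindle", on[keep],
                           (on + d)[keep], (on + d / 2)[keep], a[keep],
                           f[keep], dsc$id[sel][keep])
    }
  }
  ev <- c(ev, thal_sp)
  thal_sp_all <- if (length(thal_sp)) do.call(rbind, thal_sp) else empty_truth()

  # cortical spindles projected from thalamic spindles: each thalamic
  # channel projects focally to one primary cortical channel (near-total
  # overlap, as in directly connected TC pairs) and diffusely to the rest
  sp_rate_cort <- region_param(cfg$spindle_rate_per_min, "cortex")
  if (nrow(thal_sp_all) && length(cortical) && sp_rate_cort > 0) {
    primary_of <- stats::setNames(rep(NA_character_, length(cortical)),
                                  cortical)
    for (k in seq_along(thalamic)) {
      tgt <- cortical[1 + (2 * (k - 1)) %% length(cortical)]
      primary_of[tgt] <- thalamic[k]
    }
    p_diffuse <- min(1, sp_rate_cort * (dur / 60) / nrow(thal_sp_all))
    for (ch in cortical) {
      p_row <- rep(p_diffuse, nrow(thal_sp_all))
      if (!is.na(primary_of[ch])) {
        # primary input dominates; diffuse input only from other channels
        pri <- thal_sp_all$channel == primary_of[ch]
        p_row[pri] <- cfg$p_primary_projection
        p_row[!pri] <- p_diffuse / 2
      }
      sel <- stats::runif(nrow(thal_sp_all)) < p_row
      if (!any(sel)) next
      src <- thal_sp_all[sel, ]
      on <- src$onset_s + cfg$tc_spindle_lag_s
      d <- src$offset_s - src$onset_s
      a <- rspindle_amp(nrow(src), cfg, "cortex")
      keep <- on + d < dur - margin
      ev[[paste0("sp_", ch)]] <- add(ch, "cortex", "spindle", on[keep],
                                     (on + d)[keep], (on + d / 2)[keep],
                                     a[keep], src$freq_hz[keep],
                                     src$id[keep])
    }
  }

  # sharp artifact transients (every channel)
  if (cfg$artifact_rate_per_min > 0) {
    for (j in seq_along(cfg$channels)) {
      ch <- cfg$channels[j]
      n_a <- stats::rpois(1, cfg$artifact_rate_per_min * dur / 60)
      if (!n_a) next
      on <- stats::runif(n_a, margin, dur - margin - 0.2)
      d <- stats::runif(n_a, 0.05, 0.2)
      a <- cfg$artifact_amp * stats::runif(n_a, 0.7, 1.3) *
        sample(c(-1, 1), n_a, replace = TRUE)
      ev[[paste0("art_", ch)]] <- add(ch, cfg$regions[j], "artifact",
                                      on, on + d, on + d / 2, a)
    }
  }

  # non-spindle sigma-band distractor bursts (every channel)
  if (any(cfg$burst_rate_per_min > 0)) {
    for (j in seq_along(cfg$channels)) {
      ch <- cfg$channels[j]
      br <- region_param(cfg$burst_rate_per_min, cfg$regions[j])
      n_b <- stats::rpois(1, br * dur / 60)
      if (!n_b) next
      on <- sort(stats::runif(n_b, margin, dur - margin - 0.5))
      # refractory spacing: isolated fluctuations, no merged double-bursts
      keep <- c(TRUE, diff(on) > 2)
      on <- on[keep]; n_b <- length(on)
      d <- stats::runif(n_b, 0.25, 0.5)
      a <- region_param(cfg$burst_amp, cfg$regions[j]) *
        exp(stats::rnorm(n_b, 0, 0.3))
      ev[[paste0("burst_", ch)]] <- add(ch, cfg$regions[j], "burst",
                                        on, on + d, on + d / 2, a)
    }
  }

  gt <- if (length(ev)) do.call(rbind, ev) else empty_truth()
  rownames(gt) <- NULL
  gt <- gt[order(gt$channel, gt$onset_s), ]
  attr(gt, "config") <- cfg
  gt
}

# 1/f^a coloured noise via spectral shaping, unit variance then scaled;
# rolled off below f_hp to emulate the acquisition high-pass of clinical
# SEEG amplifiers (~0.33 Hz)
colored_noise <- function(n, rate_hz, exponent, rms, f_hp = 0.33) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * rate_hz / n
  f <- pmin(f, rate_hz - f)             # two-sided frequency axis
  gain <- pmax(f, f_hp)^(-exponent / 2)
  gain[f < f_hp] <- gain[f < f_hp] * (f[f < f_hp] / f_hp)^2
  gain[1] <- 0
  x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
  x / stats::sd(x) * rms
}

# spindle envelope: rapid waxing (~120 ms, the abrupt onset of rebound
# bursting) followed by a flat core and a slower waning tail
spindle_env <- function(n, rate_hz) {
  rise <- min(round(0.12 * rate_hz), n %/% 3)
  decay <- min(round(0.4 * n), n - rise)
  w <- rep(1, n)
  if (rise > 0) w[1:rise] <- 0.5 * (1 - cos(pi * (1:rise) / rise))
  if (decay > 0) {
    k <- (n - decay + 1):n
    w[k] <- pmin(w[k], 0.5 * (1 + cos(pi * (k - (n - decay)) / decay)))
  }
  w
}

render_spindle <- function(t_axis, onset, offset, amp, freq) {
  i0 <- which(t_axis >= onset & t_axis <= offset)
  if (!length(i0)) return(list(idx = integer(0), wave = numeric(0),
                               burst = numeric(0)))
  tt <- t_axis[i0]
  w <- spindle_env(length(i0), 1 / (t_axis[2] - t_axis[1]))
  ph <- sin(2 * pi * freq * (tt - onset))
  list(idx = i0, wave = amp * w * ph,
       burst = w * ((1 - ph) / 2)^4)    # sharp bumps at spindle troughs
}

#' Synthesize the multichannel signals for a schedule
#'
#' Renders each channel as 1/f background plus sigma-band background noise,
#' a 500 ms negative half-sine with a positive rebound for each DS, a
#' Tukey-windowed sinusoid for each spindle, and a 60-100 Hz noise carrier
#' whose amplitude is suppressed during cortical DS troughs, raised at
#' thalamic down-to-upstate transitions, and burst-modulated at spindle
#' troughs (emulating spindle-locked population firing).
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param gt Schedule from \code{\link{build_event_schedule}}.
#' @return A \code{\link{recording}}; sleep stages alternate N2/N3 in 5 min
#'   blocks.
#' @export
synthesize_signals <- function(cfg, gt) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  n <- round(cfg$duration_s * cfg$rate_hz)
  t_axis <- (seq_len(n) - 1) / cfg$rate_hz
  data <- matrix(0, n, length(cfg$channels))
  for (j in seq_along(cfg$channels)) {
    ch <- cfg$channels[j]
    region <- cfg$regions[j]
    x <- colored_noise(n, cfg$rate_hz, region_param(cfg$noise_exponent, region),
                       cfg$noise_amp,
                       f_hp = region_param(cfg$noise_hp_hz, region))
    da <- region_param(cfg$delta_amp, region)
    if (da > 0) {
      d <- stats::rnorm(n)
      d <- bandpass_filter(d, cfg$rate_hz, 0.5, 2, zero_phase = TRUE)
      x <- x + d / stats::sd(d) * da
    }
    if (cfg$sigma_amp > 0) {
      s <- stats::rnorm(n)
      s <- bandpass_filter(s, cfg$rate_hz, 6,
                           min(22, cfg$rate_hz / 2 - 1), zero_phase = TRUE)
      s <- s / stats::sd(s)
      # distractor bursts: irregular narrowband-noise envelope bumps on
      # the sigma background (not coherent oscillations, so they differ
      # from spindles in peak regularity and spectral concentration)
      smod <- rep(1, n)
      bu <- gt[gt$channel == cfg$channels[j] & gt$type == "burst", ,
               drop = FALSE]
      for (i in seq_len(nrow(bu))) {
        i0 <- which(t_axis >= bu$onset_s[i] & t_axis <= bu$offset_s[i])
        if (!length(i0)) next
        smod[i0] <- smod[i0] +
          (bu$amplitude[i] / cfg$sigma_amp) * tukey_window(length(i0), 0.5)
      }
      x <- x + s * cfg$sigma_amp * smod
    }
    gmod <- rep(if (region == "thalamus") 0.3 else 1, n)  # gamma envelope
    evc <- gt[gt$channel == ch, , drop = FALSE]
    for (i in seq_len(nrow(evc))) {
      if (evc$type[i] == "ds") {
        pk <- evc$peak_s[i]
        i0 <- which(t_axis >= pk - 0.25 & t_axis <= pk + 0.25)
        x[i0] <- x[i0] - evc$amplitude[i] *
          sin(pi * (t_axis[i0] - pk + 0.25) / 0.5)
        i1 <- which(t_axis >= pk + 0.25 & t_axis <= pk + 0.75)
        x[i1] <- x[i1] + 0.4 * evc$amplitude[i] *
          sin(pi * (t_axis[i1] - pk - 0.25) / 0.5)
        if (region == "cortex") {
          gmod[i0] <- gmod[i0] * (1 - 0.8 * sin(pi * (t_axis[i0] - pk + 0.25) / 0.5))
        } else {
          i2 <- which(t_axis >= pk + 0.1 & t_axis <= pk + 0.4)
          gmod[i2] <- gmod[i2] + 1.7 * sin(pi * (t_axis[i2] - pk - 0.1) / 0.3)
        }
      } else if (evc$type[i] == "artifact") {
        i0 <- which(t_axis >= evc$onset_s[i] & t_axis <= evc$offset_s[i])
        x[i0] <- x[i0] + evc$amplitude[i]     # rectangular pulse, sharp edges
      } else if (evc$type[i] == "spindle") {
        sp <- render_spindle(t_axis, evc$onset_s[i], evc$offset_s[i],
                             evc$amplitude[i], evc$freq_hz[i])
        x[sp$idx] <- x[sp$idx] + sp$wave
        gmod[sp$idx] <- gmod[sp$idx] * (1 + 3 * sp$burst)
      }
    }
    gmod <- 3 * tanh(gmod / 3)          # firing-rate saturation
    wa <- region_param(cfg$white_amp, region)
    if (wa > 0) {
      # broadband instrument/muscle noise; band-limited above the
      # slow-wave band (amplifier noise has negligible sub-delta power)
      w <- bandpass_filter(stats::rnorm(n), cfg$rate_hz, 4,
                           cfg$rate_hz / 2 - 1, zero_phase = TRUE)
      x <- x + w / stats::sd(w) * wa
    }
    if (cfg$gamma_amp > 0) {
      g <- stats::rnorm(n)
      hi <- min(100, cfg$rate_hz / 2 - 2)
      g <- bandpass_filter(g, cfg$rate_hz, 60, hi, zero_phase = TRUE)
      x <- x + cfg$gamma_amp * gmod * (g / stats::sd(g))
    }
    data[, j] <- x
  }
  colnames(data) <- cfg$channels
  block <- 300
  edges <- seq(0, cfg$duration_s, by = block)
  if (edges[length(edges)] < cfg$duration_s) edges <- c(edges, cfg$duration_s)
  stages <- data.frame(onset_s = edges[-length(edges)], offset_s = edges[-1],
                       stage = rep_len(c("N2", "N3"),
                                       length(edges) - 1))
  # artifact intervals (any channel) become excluded time, emulating the
  # visually marked bad periods supplied with clinical recordings
  art <- gt[gt$type == "artifact", , drop = FALSE]
  exclusions <- if (nrow(art)) {
    data.frame(onset_s = pmax(0, art$onset_s - 0.5),
               offset_s = pmin(cfg$duration_s, art$offset_s + 0.5))
  } else NULL
  recording(data, cfg$rate_hz, channels = cfg$channels,
            regions = cfg$regions, stages = stages, exclusions = exclusions)
}

#' Simulate a full recording with ground truth
#'
#' Convenience wrapper: builds the schedule and synthesizes the signals.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{recording} and \code{truth}.
#' @export
simulate_recording <- function(cfg = sim_config()) {
  gt <- build_event_schedule(cfg)
  rec <- synthesize_signals(cfg, gt)
  list(recording = rec, truth = gt)
}
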