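#' Multichannel recording container
#'
#' Bundles a continuous multichannel signal with its sampling rate, channel
#' region labels (cortex or thalamus), sleep-stage intervals and excluded
#' time intervals. All detection and coordination functions in this package
#' consume this container.
#'
#' @param data Numeric matrix, samples x channels.
#' @param rate_hz Sampling rate in Hz.
#' @param channels Character vector of channel names (defaults to column
#'   names of \code{data}).
#' @param regions Character vector, one of \code{"cortex"} or
#'   \code{"thalamus"} per channel.
#' @param stages Data frame with columns \code{onset_s}, \code{offset_s},
#'   \code{stage} (\code{"N2"} or \code{"N3"}); defaults to the whole
#'   recording as N2.
#' @param exclusions Data frame with columns \code{onset_s}, \code{offset_s}
#'   of time to exclude from analysis (default none).
#' @param t0_s Time of the first sample in seconds (default 0).
#' @return An object of class \code{ctc_recording}.
#' @export
recording <- function(data, rate_hz, channels = colnames(data), regions,
                      stages = NULL, exclusions = NULL, t0_s = 0) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  stopifnot(rate_hz > 0, length(channels) == ncol(data),
            length(regions) == ncol(data))
  if (!all(regions %in% c("cortex", "thalamus"))) {
    stop("regions must be 'cortex' or 'thalamus'")
  }
  dur <- nrow(data) / rate_hz
  if (is.null(stages)) {
    stages <- data.frame(onset_s = 0, offset_s = dur, stage = "N2")
  }
  if (is.null(exclusions)) {
    exclusions <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  }
  colnames(data) <- channels
  structure(list(data = data, rate_hz = rate_hz, channels = channels,
                 regions = regions, stages = stages, exclusions = exclusions,
                 t0_s = t0_s),
            class = "ctc_recording")
}

#' @export
print.ctc_recording <- function(x, ...) {
  cat(sprintf("<ctc_recording> %d channels x %.1f s @ %g Hz\n",
              ncol(x$data), nrow(x$data) / x$rate_hz, x$rate_hz))
  cat("  channels:",
      paste(sprintf("%s(%s)", x$channels, substr(x$regions, 1, 1)),
            collapse = " "), "\n")
  cat(sprintf("  stages: %d intervals; exclusions: %d intervals\n",
              nrow(x$stages), nrow(x$exclusions)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A \code{ctc_recording}.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$rate_hz

#' Total stage time in minutes
#'
#' Minutes of N2/N3 sleep minus excluded time, used as the denominator of
#' event densities.
#' @param rec A \code{ctc_recording}.
#' @export
stage_minutes <- function(rec) {
  tot <- sum(rec$stages$offset_s - rec$stages$onset_s)
  if (nrow(rec$exclusions)) {
    # subtract exclusion overlap with stage intervals
    for (i in seq_len(nrow(rec$exclusions))) {
      o <- pmax(rec$stages$onset_s, rec$exclusions$onset_s[i])
      f <- pmin(rec$stages$offset_s, rec$exclusions$offset_s[i])
      tot <- tot - sum(pmax(0, f - o))
    }
  }
  tot / 60
}

in_any_interval <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, length(t)))
  res <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals))) {
    res <- res | (t >= intervals$onset_s[i] & t <= intervals$offset_s[i])
  }
  res
}

stage_of_time <- function(t, stages) {
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(stages))) {
    hit <- t >= stages$onset_s[i] & t <= stages$offset_s[i]
    out[hit] <- stages$stage[i]
  }
  out
}

#' Read a recording from disk
#'
#' Supports EDF/EDF+ files (16-bit, identical sampling rate across channels)
#' and plain CSV sample matrices (one column per channel, header row of
#' channel names).
#'
#' @param path File path.
#' @param format \code{"edf"} or \code{"csv-matrix"}.
#' @param rate_hz Required for \code{"csv-matrix"}.
#' @param regions Channel regions; default guesses \code{"thalamus"} for
#'   channel names containing "thal" or "pulv", else \code{"cortex"}.
#' @param montage Optional data frame with columns \code{name},
#'   \code{medial}, \code{lateral}: bipolar channels are derived as
#'   medial minus lateral.
#' @return A \code{\link{recording}}.
#' @export
read_recording <- function(path, format = c("edf", "csv-matrix"),
                           rate_hz = NULL, regions = NULL, montage = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    ed <- read_edf(path)
    data <- ed$data
    rate_hz <- ed$rate_hz
  } else {
    if (is.null(rate_hz)) stop("rate_hz is required for csv-matrix input")
    data <- as.matrix(utils::read.csv(path, check.names = FALSE))
  }
  if (!is.null(montage)) {
    miss <- setdiff(c(montage$medial, montage$lateral), colnames(data))
    if (length(miss)) stop("montage references missing contacts: ",
                           paste(miss, collapse = ", "))
    data <- vapply(seq_len(nrow(montage)), function(i) {
      data[, montage$medial[i]] - data[, montage$lateral[i]]
    }, numeric(nrow(data)))
    colnames(data) <- montage$name
  }
  if (is.null(regions)) {
    regions <- ifelse(grepl("thal|pulv", colnames(data), ignore.case = TRUE),
                      "thalamus", "cortex")
  }
  recording(data, rate_hz, regions = regions)
}

# ---- minimal EDF (16-bit) I/O -----------------------------------------------

pad_field <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a signal matrix as an EDF file
#'
#' Minimal EDF writer: one data record per second, identical sampling rate
#' across channels, 16-bit integers with per-channel physical scaling.
#'
#' @param data Samples x channels numeric matrix (column names used as
#'   labels).
#' @param rate_hz Sampling rate (integer samples per second).
#' @param path Output path.
#' @export
write_edf <- function(data, rate_hz, path) {
  data <- as.matrix(data)
  ns <- ncol(data)
  spr <- as.integer(round(rate_hz))
  n_rec <- floor(nrow(data) / spr)
  if (n_rec < 1) stop("recording shorter than one data record")
  labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  pmin_ <- apply(data, 2, min); pmax_ <- apply(data, 2, max)
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("recording", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(vapply(labels, pad_field, "", width = 16),
              rep(pad_field("", 80), ns),               # transducer
              rep(pad_field("uV", 8), ns),              # physical dim
              vapply(sprintf("%.6g", pmin_), pad_field, "", width = 8),
              vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
              rep(pad_field("-32768", 8), ns),
              rep(pad_field("32767", 8), ns),
              rep(pad_field("", 80), ns),               # prefilter
              rep(pad_field(spr, 8), ns),
              rep(pad_field("", 32), ns))
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(ns)) {
      dig <- round((data[rows, j] - pmin_[j]) / scale[j]) - 32768
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written with a uniform sampling rate
#'
#' @param path EDF file path.
#' @return List with \code{data} (samples x channels, physical units) and
#'   \code{rate_hz}.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 184, useBytes = TRUE)
  as.integer(readChar(con, 8, useBytes = TRUE))  # header bytes (unused)
  readChar(con, 44, useBytes = TRUE)
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  rec_dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  rd <- function(w) vapply(seq_len(ns), function(i)
    trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rd(16); rd(80); rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin_ <- as.numeric(rd(8)); dmax_ <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8)); rd(32)
  if (length(unique(spr)) != 1L) stop("channels have differing sampling rates")
  out <- matrix(0, n_rec * spr[1], ns)
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[j], size = 2, endian = "little")
      out[((r - 1L) * spr[1] + 1L):(r * spr[1]), j] <-
        (dig - dmin_[j]) * scale[j] + pmin_[j]
    }
  }
  colnames(out) <- labels
  list(data = out, rate_hz = spr[1] / rec_dur)
}

#' Write / read an event table
#'
#' Event tables are plain CSV files with a fixed column order:
#' channel, type, onset_s, offset_s, peak_s, amplitude, freq_hz, parent_id.
#' Missing fields are written as NA.
#'
#' @param events Data frame of events.
#' @param path Output path.
#' @export
write_event_table <- function(events, path) {
  cols <- c("channel", "type", "onset_s", "offset_s", "peak_s", "amplitude",
            "freq_hz", "parent_id")
  for (cl in setdiff(cols, names(events))) events[[cl]] <- NA
  utils::write.csv(events[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
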