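#' Filter specification for sEMG preprocessing
#'
#' Defaults follow standard surface-EMG practice: a 4th-order Butterworth
#' band-pass with 20-200 Hz cutoffs plus a 60 Hz mains notch. The notch
#' quality factor `q` sets the -3 dB width to roughly `notch_hz / q`
#' (about 2 Hz at the defaults).
#'
#' @param band_low,band_high band-pass cutoff frequencies in Hz.
#' @param order Butterworth order.
#' @param notch_hz notch center frequency in Hz (`NULL` disables).
#' @param notch_q notch quality factor.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(band_low = 20, band_high = 200, order = 4,
                        notch_hz = 60, notch_q = 30) {
  stopifnot(band_low > 0, band_low < band_high, order >= 1)
  structure(list(band_low = band_low, band_high = band_high,
                 order = as.integer(order), notch_hz = notch_hz,
                 notch_q = notch_q),
            class = "filter_spec")
}

check_band <- function(lo, hi, fs) {
  if (lo <= 0 || hi >= fs / 2 || lo >= hi)
    stop("band edges (", lo, ", ", hi, ") must satisfy 0 < low < high < fs/2")
}

#' Butterworth band-pass filter
#'
#' Causal (forward-only) IIR filtering by default, matching on-line use;
#' `zero_phase = TRUE` applies the filter forward and backward
#' (zero-phase, off-line only).
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @param zero_phase logical.
#' @return filtered series, same length as `x`.
#' @export
bandpass <- function(x, fs, spec = filter_spec(), zero_phase = FALSE) {
  check_band(spec$band_low, spec$band_high, fs)
  if (length(x) <= 3 * spec$order) stop("series too short to filter")
  bf <- signal::butter(spec$order,
                       c(spec$band_low, spec$band_high) / (fs / 2),
                       type = "pass")
  if (zero_phase) as.numeric(signal::filtfilt(bf, x))
  else as.numeric(signal::filter(bf, x))
}

#' Mains notch filter
#'
#' Second-order IIR notch (constrained-pole biquad): a unit-circle zero at
#' the notch frequency gives full rejection of a steady tone there, while
#' the pole radius set by `q` keeps the -3 dB stopband to about
#' `notch_hz / q` Hz so neighboring frequencies pass nearly unchanged.
#'
#' @inheritParams bandpass
#' @param notch_hz center frequency in Hz.
#' @param q quality factor.
#' @return filtered series, same length as `x`.
#' @export
notch <- function(x, fs, notch_hz = 60, q = 30, zero_phase = FALSE) {
  if (notch_hz <= 0 || notch_hz >= fs / 2)
    stop("notch_hz must lie in (0, fs/2)")
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  flt <- signal::Arma(b = b, a = a)
  if (zero_phase) as.numeric(signal::filtfilt(flt, x))
  else as.numeric(signal::filter(flt, x))
}

#' Apply band-pass and notch to all channels of a recording
#'
#' @param recording an `emg_recording`.
#' @param spec a [filter_spec()].
#' @param zero_phase logical, see [bandpass()].
#' @return the recording with filtered `emg`.
#' @export
preprocess_recording <- function(recording, spec = filter_spec(),
                                 zero_phase = FALSE) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$fs
  emg <- recording$emg
  for (c in seq_len(nrow(emg))) {
    y <- bandpass(emg[c, ], fs, spec, zero_phase)
    if (!is.null(spec$notch_hz))
      y <- notch(y, fs, spec$notch_hz, spec$notch_q, zero_phase)
    emg[c, ] <- y
  }
  recording$emg <- emg
  recording
}

#' Label gait phases from hip angle and plantar pressure
#'
#' Cycle boundaries are placed at hip-angle maxima (one per cycle). Stance
#' and swing are separated by the plantar pressure: samples with pressure
#' above `pressure_threshold` are stance, the rest swing (`SW`). Each
#' contiguous stance interval is split deterministically into
#' `DS1 / SS / DS2`: DS1 starts at the pressure onset and takes the first
#' `ds_fractions[1]` of the stance samples, DS2 ends at the pressure offset
#' and takes the last `ds_fractions[2]`, SS is the remainder. Within every
#' cycle the labels therefore follow `DS1 -> SS -> DS2 -> SW`.
#'
#' @param hip_angle numeric hip-angle series in degrees.
#' @param pressure numeric plantar-pressure series (>= 0), same length.
#' @param fs sampling rate in Hz.
#' @param ds_fractions fractions of each stance interval assigned to DS1
#'   and DS2.
#' @param pressure_threshold stance threshold; default 5% of the maximum
#'   pressure.
#' @param min_cycle_s minimum separation of hip-angle maxima, in seconds.
#' @return a [phase_timeline()].
#' @export
label_phases <- function(hip_angle, pressure, fs,
                         ds_fractions = c(0.24, 0.24),
                         pressure_threshold = NULL, min_cycle_s = 0.5) {
  stopifnot(length(hip_angle) == length(pressure), fs > 0,
            length(ds_fractions) == 2L, all(ds_fractions > 0),
            sum(ds_fractions) < 1)
  n <- length(hip_angle)
  if (diff(range(hip_angle)) < 1e-9)
    stop("no gait cycles detected: hip angle has no extrema")
  pk <- pracma::findpeaks(hip_angle,
                          minpeakdistance = max(1L, round(min_cycle_s * fs)),
                          minpeakheight = min(hip_angle) +
                            0.5 * diff(range(hip_angle)))
  # findpeaks misses maxima at the very edges; treat a starting/ending
  # plateau at near-max level as a boundary too.
  peaks <- if (is.null(pk)) integer(0) else sort(pk[, 2])
  hi <- min(hip_angle) + 0.9 * diff(range(hip_angle))
  if (hip_angle[1] >= hi) peaks <- union(1L, peaks)
  if (length(peaks) == 0L)
    stop("no gait cycles detected: hip angle has no extrema")

  if (is.null(pressure_threshold))
    pressure_threshold <- 0.05 * max(pressure)
  stance <- pressure > pressure_threshold
  labels <- rep("SW", n)
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    len <- r$lengths[i]
    n1 <- max(1L, round(ds_fractions[1] * len))
    n3 <- max(1L, round(ds_fractions[2] * len))
    if (n1 + n3 >= len) {  # degenerate short stance: split evenly
      n1 <- max(1L, len %/% 3L)
      n3 <- max(1L, len %/% 3L)
      if (n1 + n3 >= len) n3 <- max(0L, len - n1 - 1L)
    }
    seg <- starts[i]:ends[i]
    labels[seg[seq_len(n1)]] <- "DS1"
    if (len - n1 - n3 > 0L)
      labels[seg[(n1 + 1L):(len - n3)]] <- "SS"
    if (n3 > 0L)
      labels[seg[(len - n3 + 1L):len]] <- "DS2"
  }
  phase_timeline(labels, peaks)
}

#' Segment a recording into labeled windows
#'
#' Slides a window of `window_ms` (step `step_ms`) over the recording and
#' assigns each window the majority phase of its samples. Windows whose
#' majority phase covers less than `majority` of the window (i.e. windows
#' straddling a phase boundary too evenly) are dropped; the number of
#' dropped windows is reported in the `dropped` attribute.
#'
#' Before dropping, the number of windows is
#' `floor((T - W) / S) + 1` for window `W` and step `S` in samples.
#'
#' @param recording an `emg_recording`.
#' @param timeline a [phase_timeline()] aligned to the recording.
#' @param window_ms,step_ms window length and step in milliseconds.
#' @param majority minimum fraction of the window the majority label must
#'   cover.
#' @return object of class `windowed_samples`: list with `segments` (array
#'   `12 x W x n`), `labels` (factor), `mode`, `subject_id`, `fs`; attribute
#'   `dropped` counts discarded ambiguous windows.
#' @export
segment_windows <- function(recording, timeline, window_ms = 100,
                            step_ms = 100, majority = 0.6) {
  stopifnot(inherits(recording, "emg_recording"),
            inherits(timeline, "phase_timeline"))
  T_ <- ncol(recording$emg)
  if (T_ == 0L) stop("empty recording")
  if (length(timeline$labels) != T_)
    stop("timeline length does not match recording")
  W <- round(window_ms / 1000 * recording$fs)
  S <- round(step_ms / 1000 * recording$fs)
  if (W > T_) stop("window longer than recording")
  n_all <- (T_ - W) %/% S + 1L
  keep <- logical(n_all)
  labs <- character(n_all)
  for (i in seq_len(n_all)) {
    idx <- (i - 1L) * S + seq_len(W)
    tab <- table(timeline$labels[idx])
    top <- which.max(tab)
    if (tab[top] / W >= majority) {
      keep[i] <- TRUE
      labs[i] <- names(tab)[top]
    }
  }
  n <- sum(keep)
  segments <- array(NA_real_, c(nrow(recording$emg), W, n))
  j <- 0L
  for (i in which(keep)) {
    j <- j + 1L
    segments[, , j] <- recording$emg[, (i - 1L) * S + seq_len(W)]
  }
  out <- structure(list(segments = segments,
                        labels = phase_factor(labs[keep]),
                        mode = recording$mode,
                        subject_id = recording$subject_id,
                        fs = recording$fs),
                   class = "windowed_samples")
  attr(out, "dropped") <- n_all - n
  attr(out, "n_windows_raw") <- n_all
  out
}

#' @export
print.windowed_samples <- function(x, ...) {
  d <- dim(x$segments)
  cat("<windowed_samples> ", d[3L], " windows of ", d[2L], " samples x ",
      d[1L], " channels (", attr(x, "dropped"), " dropped)\n", sep = "")
  print(table(x$labels))
  invisible(x)
}
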