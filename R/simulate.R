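#' Activation profile: relative muscle activation per gait phase
#'
#' An activation profile maps each of the 12 muscle channels to a relative
#' activation level in \[0, 1\] for each of the 4 gait phases. Profiles encode
#' the qualitative rest/active structure of lower-limb muscles across the
#' cycle (e.g. in early stance of level walking the posterior/anterior group
#' ST, BF, TA, MG is active while the quadriceps RF, VM rest).
#'
#' @param amplitude numeric matrix `12 x 4` (rows in [muscle_channels()]
#'   order, columns `DS1, SS, DS2, SW`), values in \[0, 1\].
#' @return object of class `activation_profile`.
#' @export
activation_profile <- function(amplitude) {
  amplitude <- as.matrix(amplitude)
  if (!all(dim(amplitude) == c(12L, 4L)))
    stop("amplitude must be a 12 x 4 matrix (channels x phases)")
  if (any(amplitude < 0 | amplitude > 1))
    stop("activation amplitudes must lie in [0, 1]")
  for (p in 1:4) {
    if (max(amplitude[, p]) < 0.5 || min(amplitude[, p]) > 0.1)
      stop("phase ", gait_phases()[p],
           ": need at least one active (>= 0.5) and one resting (<= 0.1) muscle")
  }
  dimnames(amplitude) <- list(muscle_channels()$channel, gait_phases())
  structure(list(amplitude = amplitude), class = "activation_profile")
}

# Left-leg base pattern for level walking (rows RF, VM, ST, BF, TA, MG;
# cols DS1, SS, DS2, SW). DS1 follows the observed early-stance pattern:
# ST/MG/TA/BF active, RF/VM resting.
lw_left_base <- function() {
  m <- rbind(
    RF = c(0.05, 0.20, 0.60, 0.70),
    VM = c(0.08, 0.25, 0.55, 0.30),
    ST = c(0.70, 0.20, 0.10, 0.60),
    BF = c(0.65, 0.25, 0.10, 0.55),
    TA = c(0.80, 0.10, 0.30, 0.75),
    MG = c(0.60, 0.70, 0.90, 0.05)
  )
  colnames(m) <- gait_phases()
  m
}

# Per-mode additive tweaks (muscle, phase, delta) on top of the LW pattern,
# applied to the left leg and mirrored to the right. Each mode differs from
# every other in at least 4 (muscle, phase) amplitudes.
mode_tweaks <- function() {
  list(
    LW = NULL,
    SA = rbind(c("RF", "SS", +0.35), c("VM", "SS", +0.35),
               c("MG", "DS2", -0.25), c("TA", "SW", +0.15)),
    SD = rbind(c("ST", "SS", +0.30), c("MG", "SW", +0.30),
               c("TA", "DS2", +0.25), c("RF", "DS2", -0.30)),
    RA = rbind(c("VM", "DS2", +0.30), c("BF", "SS", +0.30),
               c("MG", "SS", -0.30), c("RF", "SW", -0.25)),
    RD = rbind(c("TA", "SS", +0.35), c("VM", "SW", +0.35),
               c("MG", "SS", -0.25), c("ST", "SW", -0.30))
  )
}

#' Default mode-specific activation profiles
#'
#' Builds the built-in [activation_profile()] for a locomotion mode. All
#' modes share a level-walking base pattern; each non-LW mode applies its
#' own set of additive adjustments (at least 4 entries) so any two modes
#' differ in at least 4 (muscle, phase) amplitudes. The right leg mirrors
#' the left with a half-cycle phase shift (DS1 <-> DS2, SS <-> SW), which is
#' what alternating bipedal gait implies for the contralateral limb.
#'
#' @param mode one of `"LW", "SA", "SD", "RA", "RD"`.
#' @return an `activation_profile`.
#' @export
default_profile <- function(mode = "LW") {
  assert_mode(mode)
  left <- lw_left_base()
  tw <- mode_tweaks()[[mode]]
  if (!is.null(tw)) {
    for (i in seq_len(nrow(tw))) {
      mu <- tw[i, 1]; ph <- tw[i, 2]; d <- as.numeric(tw[i, 3])
      left[mu, ph] <- min(1, max(0, left[mu, ph] + d))
    }
  }
  shift <- c(DS1 = "DS2", SS = "SW", DS2 = "DS1", SW = "SS")
  right <- left[, shift[gait_phases()]]
  colnames(right) <- gait_phases()
  activation_profile(rbind(left, right))
}

#' Configuration of the synthetic gait-sEMG generator
#'
#' @param fs sampling rate in Hz.
#' @param cycle_duration gait cycle duration in seconds.
#' @param phase_fractions fractions of the cycle spent in DS1, SS, DS2, SW;
#'   must be positive and sum to 1.
#' @param n_cycles number of gait cycles to simulate.
#' @param noise_band `(low, high)` passband in Hz of the stochastic carrier.
#' @param mains_hz mains interference frequency in Hz, or `NULL` for none.
#' @param mains_amplitude mains amplitude relative to `amplitude_uv`.
#' @param drift_hz baseline drift frequency in Hz.
#' @param drift_amplitude drift amplitude relative to `amplitude_uv`.
#' @param rest_noise_floor relative amplitude of the ever-present carrier
#'   floor (models electrode/thermal noise during muscle rest).
#' @param amplitude_uv scale, in microvolts, corresponding to relative
#'   activation 1.0.
#' @param seed integer seed fixing all randomness of the simulation.
#' @param mode locomotion mode label.
#' @param profile an [activation_profile()]; default [default_profile()] of
#'   `mode`.
#' @param subject_id subject label stored in the recording.
#' @param rise_ms envelope rise/fall time in milliseconds.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(fs = 1000, cycle_duration = 1.0,
                              phase_fractions = c(0.12, 0.38, 0.12, 0.38),
                              n_cycles = 10L,
                              noise_band = c(20, 200),
                              mains_hz = 60, mains_amplitude = 0.05,
                              drift_hz = 0.4, drift_amplitude = 0.05,
                              rest_noise_floor = 0.05,
                              amplitude_uv = 150,
                              seed = 1L, mode = "LW", profile = NULL,
                              subject_id = "S01", rise_ms = 30) {
  stopifnot(fs > 0, cycle_duration > 0, length(phase_fractions) == 4L,
            all(phase_fractions > 0), n_cycles >= 1L,
            length(noise_band) == 2L, noise_band[1] > 0,
            noise_band[1] < noise_band[2])
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stop("phase_fractions must sum to 1")
  if (fs <= 2 * noise_band[2])
    stop("fs must exceed twice the upper noise band edge")
  assert_mode(mode)
  if (is.null(profile)) profile <- default_profile(mode)
  stopifnot(inherits(profile, "activation_profile"))
  structure(list(fs = fs, cycle_duration = cycle_duration,
                 phase_fractions = phase_fractions,
                 n_cycles = as.integer(n_cycles), noise_band = noise_band,
                 mains_hz = mains_hz, mains_amplitude = mains_amplitude,
                 drift_hz = drift_hz, drift_amplitude = drift_amplitude,
                 rest_noise_floor = rest_noise_floor,
                 amplitude_uv = amplitude_uv, seed = as.integer(seed),
                 mode = mode, profile = profile, subject_id = subject_id,
                 rise_ms = rise_ms),
            class = "simulation_config")
}

#' Phase timeline
#'
#' Per-sample gait-phase labels plus the sample indices at which cycles
#' start (DS1 onsets).
#'
#' @param labels factor (or character) of per-sample phase labels.
#' @param cycle_boundaries sorted integer sample indices of cycle starts.
#' @return object of class `phase_timeline`.
#' @export
phase_timeline <- function(labels, cycle_boundaries = integer(0)) {
  structure(list(labels = phase_factor(labels),
                 cycle_boundaries = as.integer(sort(cycle_boundaries))),
            class = "phase_timeline")
}

#' @export
print.phase_timeline <- function(x, ...) {
  cat("<phase_timeline> ", length(x$labels), " samples, ",
      length(x$cycle_boundaries), " cycle starts\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

# Per-cycle phase sample counts that honor the fractions to within one
# sample and sum exactly to the cycle length.
phase_counts <- function(n_cycle, fractions) {
  edges <- round(cumsum(c(0, fractions)) * n_cycle)
  diff(edges)
}

# Run lengths of a label vector as (value, length) pairs.
label_runs <- function(labels) {
  r <- rle(as.character(labels))
  data.frame(value = r$values, length = r$lengths)
}

#' Smoothed activation envelope for one channel
#'
#' Expands the per-phase activation amplitudes of a profile along a phase
#' timeline and smooths the resulting step function with a centered moving
#' average of width `rise_ms`, producing linear rise/fall transitions
#' without discontinuities. The envelope plateaus at the profile amplitude
#' inside every phase, which requires the smoothing window to be shorter
#' than the shortest phase.
#'
#' @param profile an [activation_profile()].
#' @param timeline a [phase_timeline()].
#' @param channel channel name (e.g. `"L_TA"`) or index 1..12.
#' @param fs sampling rate in Hz.
#' @param rise_ms rise/fall time in milliseconds.
#' @return numeric envelope in \[0, 1\], same length as the timeline.
#' @export
activation_envelope <- function(profile, timeline, channel, fs, rise_ms = 30) {
  stopifnot(inherits(profile, "activation_profile"),
            inherits(timeline, "phase_timeline"))
  if (length(timeline$labels) == 0L) stop("empty timeline")
  if (is.character(channel)) {
    channel <- match(channel, muscle_channels()$channel)
    if (is.na(channel)) stop("unknown channel name")
  }
  amp <- profile$amplitude[channel, ]
  step <- unname(amp[as.character(timeline$labels)])
  w <- max(1L, round(rise_ms / 1000 * fs))
  shortest <- min(label_runs(timeline$labels)$length)
  if (w > shortest)
    stop("rise_ms (", w, " samples) exceeds the shortest phase (",
         shortest, " samples); envelope would never plateau")
  if (w == 1L) return(step)
  padded <- c(rep(step[1L], w), step, rep(step[length(step)], w))
  sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
  out <- sm[w + seq_along(step)]
  pmin(1, pmax(0, out))
}

# Evaluate all randomness under a local, restored RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Band-limited zero-mean unit-variance Gaussian carrier. White noise is
# shaped with a zero-phase Butterworth band-pass; padding absorbs the
# filter edge transients.
band_carrier <- function(n, fs, band, order = 4) {
  pad <- min(n, as.integer(fs))
  w <- stats::rnorm(n + 2L * pad)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, w)
  y <- y[(pad + 1L):(pad + n)]
  y / stats::sd(y)
}

# Hip angle: one maximum (at the DS1 onset) and one minimum (at the swing
# onset) per cycle, built from two half-cosine arcs so the curve is smooth.
hip_curve <- function(n_cycle, stance_frac, hip_max = 30, hip_min = -10) {
  u <- (seq_len(n_cycle) - 1L) / n_cycle
  y <- numeric(n_cycle)
  down <- u < stance_frac
  y[down] <- hip_min + (hip_max - hip_min) *
    (1 + cos(pi * u[down] / stance_frac)) / 2
  y[!down] <- hip_min + (hip_max - hip_min) *
    (1 - cos(pi * (u[!down] - stance_frac) / (1 - stance_frac))) / 2
  y
}

#' Simulate a labeled gait-sEMG recording
#'
#' Generates a 12-channel surface EMG recording with hip-angle and
#' plantar-pressure auxiliaries and a ground-truth phase timeline. Each sEMG
#' channel is amplitude-modulated band-limited Gaussian noise (the standard
#' surrogate for surface EMG): a smoothed phase-driven activation envelope
#' multiplies a 20-200 Hz carrier, a small carrier floor models rest noise,
#' and optional mains interference and baseline drift are added. The hip
#' angle has exactly one maximum (cycle start) and one minimum (swing onset)
#' per cycle; pressure is positive throughout stance and exactly zero in
#' swing. Identical configurations (including the seed) give bit-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return list with elements `recording` (class `emg_recording`: `emg`
#'   matrix `12 x T` in microvolt-scale units, `hip_angle`, `pressure`,
#'   `fs`, `mode`, `subject_id`) and `timeline` (a [phase_timeline()]).
#' @export
simulate_recording <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$fs
  n_cycle <- round(config$cycle_duration * fs)
  counts <- phase_counts(n_cycle, config$phase_fractions)
  if (any(counts < 1)) stop("cycle too short for the given phase fractions")
  labels_cycle <- rep(gait_phases(), times = counts)
  labels <- rep(labels_cycle, times = config$n_cycles)
  T_ <- length(labels)
  boundaries <- 1L + (seq_len(config$n_cycles) - 1L) * n_cycle
  timeline <- phase_timeline(labels, boundaries)

  stance_n <- sum(counts[1:3])
  stance_frac <- stance_n / n_cycle
  hip1 <- hip_curve(n_cycle, stance_frac)
  hip <- rep(hip1, config$n_cycles)

  press1 <- numeric(n_cycle)
  u <- (seq_len(stance_n) - 0.5) / stance_n
  press1[seq_len(stance_n)] <- 0.15 + 0.85 * sin(pi * u)
  pressure <- rep(press1, config$n_cycles) * 700  # ~body-weight scale, N

  chans <- muscle_channels()$channel
  emg <- with_seed(config$seed, {
    out <- matrix(0, nrow = 12L, ncol = T_, dimnames = list(chans, NULL))
    tvec <- (seq_len(T_) - 1L) / fs
    for (c in seq_len(12L)) {
      env <- activation_envelope(config$profile, timeline, c, fs,
                                 config$rise_ms)
      carrier <- band_carrier(T_, fs, config$noise_band)
      floor_carrier <- band_carrier(T_, fs, config$noise_band)
      sig <- env * carrier + config$rest_noise_floor * floor_carrier
      if (!is.null(config$mains_hz) && config$mains_amplitude > 0)
        sig <- sig + config$mains_amplitude *
          sin(2 * pi * config$mains_hz * tvec + stats::runif(1, 0, 2 * pi))
      if (config$drift_amplitude > 0)
        sig <- sig + config$drift_amplitude *
          sin(2 * pi * config$drift_hz * tvec + stats::runif(1, 0, 2 * pi))
      out[c, ] <- config$amplitude_uv * sig
    }
    out
  })

  rec <- structure(list(emg = emg, hip_angle = hip, pressure = pressure,
                        fs = fs, mode = config$mode,
                        subject_id = config$subject_id),
                   class = "emg_recording")
  list(recording = rec, timeline = timeline)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording> ", ncol(x$emg), " samples @ ", x$fs, " Hz, mode ",
      x$mode, ", subject ", x$subject_id, "\n", sep = "")
  invisible(x)
}

#' Write / read a recording as annotated CSV
#'
#' Columnar text format: comment header lines `#key=value` carrying `fs`,
#' `mode` and `subject_id`, then columns `time`, the 12 named sEMG channels,
#' `hip_angle`, `pressure` and (when a timeline is given) `phase_label`.
#'
#' @param recording an `emg_recording`.
#' @param path file path.
#' @param timeline optional [phase_timeline()] written as a label column.
#' @return `write_recording()`: `path`, invisibly. `read_recording()`: a
#'   list with `recording` and `timeline` (`NULL` when no label column).
#' @export
write_recording <- function(recording, path, timeline = NULL) {
  stopifnot(inherits(recording, "emg_recording"))
  df <- data.frame(time = (seq_len(ncol(recording$emg)) - 1L) / recording$fs,
                   t(recording$emg),
                   hip_angle = recording$hip_angle,
                   pressure = recording$pressure,
                   check.names = FALSE)
  if (!is.null(timeline)) df$phase_label <- as.character(timeline$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#fs=", recording$fs),
               paste0("#mode=", recording$mode),
               paste0("#subject_id=", recording$subject_id)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  chans <- muscle_channels()$channel
  rec <- structure(list(emg = t(as.matrix(df[, chans])),
                        hip_angle = df$hip_angle, pressure = df$pressure,
                        fs = as.numeric(meta[["fs"]]),
                        mode = meta[["mode"]],
                        subject_id = meta[["subject_id"]]),
                   class = "emg_recording")
  tl <- NULL
  if ("phase_label" %in% names(df)) {
    starts <- which(df$phase_label == "DS1" &
                      c("", df$phase_label[-nrow(df)]) != "DS1")
    tl <- phase_timeline(df$phase_label, starts)
  }
  list(recording = rec, timeline = tl)
}
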