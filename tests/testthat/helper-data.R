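# Shared synthetic datasets, built once per test run.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache))
    assign(key, force(expr), envir = .test_cache)
  get(key, envir = .test_cache)
}

# Simulate -> filter -> label -> segment -> MFAREn features for a set of
# subjects and modes; ground-truth stance sub-fractions are passed to the
# labeler so label recovery is exact up to rounding.
sim_feature_set <- function(subjects = "S01", modes = "LW", n_cycles = 20L,
                            seed = 100L) {
  frac <- eval(formals(simulation_config)$phase_fractions)
  ds <- c(frac[1], frac[3]) / sum(frac[1:3])
  sets <- list()
  k <- 0L
  for (s in seq_along(subjects)) for (m in seq_along(modes)) {
    k <- k + 1L
    sim <- simulate_recording(simulation_config(
      n_cycles = n_cycles, seed = seed + 97L * s + m, mode = modes[m],
      subject_id = subjects[s]))
    rec <- preprocess_recording(sim$recording)
    tl <- label_phases(rec$hip_angle, rec$pressure, rec$fs,
                       ds_fractions = ds)
    sets[[k]] <- mfaren_features(segment_windows(rec, tl))
  }
  do.call(bind_feature_sets, list(sets))
}

# ~2000 windows: 2 subjects x 2 modes x 50 cycles (1 s each) at 1000 Hz.
acceptance_features <- function() {
  cached("acceptance_features",
         sim_feature_set(c("S01", "S02"), c("LW", "SA"), n_cycles = 50L,
                         seed = 2024L))
}

# Small single-mode set for fast classifier tests.
small_feature_set <- function() {
  cached("small_feature_set",
         sim_feature_set("S01", "LW", n_cycles = 20L, seed = 7L))
}

# Compact model/training settings used by classifier tests; sizes chosen so
# a training run takes seconds, not minutes.
tiny_model_config <- function(...) {
  model_config(channels = c(4L, 8L, 16L), ema_groups = 2L,
               lstm_hidden = 16L, ...)
}
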