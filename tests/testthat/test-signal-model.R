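test_that("channel and phase vocabularies are fixed", {
  ch <- muscle_channels()
  expect_equal(nrow(ch), 12L)
  expect_equal(anyDuplicated(ch$channel), 0L)
  expect_equal(ch$channel[1:6], paste0("L_", muscles()))
  expect_equal(length(gait_phases()), 4L)
  expect_equal(length(movement_modes()), 5L)
  expect_error(phase_factor("XX"), "unknown")
})

test_that("default profiles encode the early-stance activation pattern", {
  for (mode in movement_modes()) {
    pr <- default_profile(mode)
    amp <- pr$amplitude
    expect_true(all(amp >= 0 & amp <= 1))
    # every phase separable: someone active, someone resting
    expect_true(all(apply(amp, 2, max) >= 0.5))
    expect_true(all(apply(amp, 2, min) <= 0.1))
  }
  lw <- default_profile("LW")$amplitude
  expect_lte(lw["L_RF", "DS1"], 0.1)
  expect_lte(lw["L_VM", "DS1"], 0.1)
  for (m in c("L_ST", "L_BF", "L_TA", "L_MG"))
    expect_gte(lw[m, "DS1"], 0.5)
  # any two modes differ in at least 4 (muscle, phase) amplitudes
  for (a in movement_modes()) for (b in movement_modes()) {
    if (a >= b) next
    da <- default_profile(a)$amplitude
    db <- default_profile(b)$amplitude
    expect_gte(sum(da != db), 4)
  }
})

test_that("activation envelope plateaus, smooths and validates", {
  tl1 <- phase_timeline(rep("SS", 500), 1L)
  pr <- activation_profile({
    m <- matrix(0.3, 12, 4)
    m[5, ] <- 0.8   # L_TA active everywhere
    m[1, ] <- 0.05  # L_RF resting
    m
  })
  env <- activation_envelope(pr, tl1, "L_TA", fs = 1000)
  expect_equal(env, rep(0.8, 500), tolerance = 1e-12)
  zero_pr <- activation_profile({
    m <- matrix(0, 12, 4); m[5, ] <- 0.8; m
  })
  expect_equal(activation_envelope(zero_pr, tl1, "L_RF", 1000), rep(0, 500))
  # monotone non-decreasing across a 0 -> 1-ish step
  tl2 <- phase_timeline(c(rep("SS", 250), rep("SW", 250)), 1L)
  pr2 <- activation_profile({
    m <- matrix(0.05, 12, 4)
    m[5, 4] <- 0.9       # L_TA ramps up in SW
    m[6, ] <- 0.5        # keeps every phase separable
    m
  })
  env2 <- activation_envelope(pr2, tl2, "L_TA", 1000)
  expect_true(all(diff(env2) >= -1e-12))
  expect_equal(env2[1], 0.05, tolerance = 1e-9)
  expect_equal(env2[500], 0.9, tolerance = 1e-9)
  # rise time longer than the shortest phase is rejected
  tl3 <- phase_timeline(c(rep("DS1", 20), rep("SS", 300)), 1L)
  expect_error(activation_envelope(pr, tl3, "L_TA", 1000, rise_ms = 40),
               "shortest phase")
})

test_that("simulation is seed-deterministic and label bookkeeping is exact", {
  cfg <- simulation_config(n_cycles = 4, seed = 42)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a, b)
  d <- simulate_recording(simulation_config(n_cycles = 4, seed = 43))
  expect_false(identical(a$recording$emg, d$recording$emg))
  # per-cycle phase counts match the fractions to within one sample
  counts <- table(a$timeline$labels) / 4
  expect_equal(as.numeric(counts), c(120, 380, 120, 380), tolerance = 1)
  expect_error(simulate_recording(simulation_config(n_cycles = 0)),
               "n_cycles")
})

test_that("hip angle and pressure carry the gait geometry", {
  sim <- simulate_recording(simulation_config(n_cycles = 5, seed = 8))
  hip <- sim$recording$hip_angle
  press <- sim$recording$pressure
  lab <- sim$timeline$labels
  # pressure strictly positive in stance, exactly zero in swing
  expect_true(all(press[lab != "SW"] > 0))
  expect_true(all(press[lab == "SW"] == 0))
  # one interior maximum and one minimum per cycle
  n_cycle <- 1000L
  one <- hip[1:n_cycle]
  s <- sign(diff(one))
  expect_equal(rle(s[s != 0])$values, c(-1, 1))  # one descent, one ascent
  expect_equal(which.max(one), 1L)
  # minimum sits at the swing onset
  expect_equal(which.min(one), sum(c(0.12, 0.38, 0.12) * n_cycle) + 1L,
               tolerance = 2)
})

test_that("carrier power is band-limited and phases are separable by RMS", {
  cfg <- simulation_config(n_cycles = 10, seed = 3, mains_amplitude = 0,
                           drift_amplitude = 0)
  sim <- simulate_recording(cfg)
  x <- sim$recording$emg[6, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = cfg$fs), plot = FALSE,
                          taper = 0)
  inband <- sum(sp$spec[sp$freq >= 18 & sp$freq <= 202]) / sum(sp$spec)
  expect_gte(inband, 0.90)
  # per-phase mean channel RMS vectors pairwise distinct (relative units)
  lab <- sim$timeline$labels
  rms_mat <- sapply(gait_phases(), function(ph) {
    apply(sim$recording$emg[, lab == ph, drop = FALSE], 1, rms)
  }) / cfg$amplitude_uv
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gt(sqrt(sum((rms_mat[, i] - rms_mat[, j])^2)), 0.1)
  }
})

test_that("active channels dominate resting ones across seeds", {
  wins <- 0L
  for (s in 1:20) {
    sim <- simulate_recording(simulation_config(n_cycles = 2, seed = 200 + s))
    lab <- sim$timeline$labels
    active <- rms(sim$recording$emg[5, lab == "DS1"])   # L_TA at 0.8
    resting <- rms(sim$recording$emg[1, lab == "DS1"])  # L_RF at 0.05
    if (active > 3 * resting) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("recordings round-trip through the annotated CSV format", {
  sim <- simulate_recording(simulation_config(n_cycles = 2, seed = 5,
                                              mode = "RA",
                                              subject_id = "S09"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(sim$recording, path, sim$timeline)
  back <- read_recording(path)
  expect_equal(back$recording$fs, 1000)
  expect_equal(back$recording$mode, "RA")
  expect_equal(back$recording$subject_id, "S09")
  expect_equal(back$recording$emg, sim$recording$emg, tolerance = 1e-9)
  expect_equal(as.character(back$timeline$labels),
               as.character(sim$timeline$labels))
  expect_equal(back$timeline$cycle_boundaries,
               sim$timeline$cycle_boundaries)
})
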