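analytic_gain <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

test_that("band-pass attenuates out-of-band tones per the Butterworth response", {
  fs <- 1000
  t <- (0:4999) / fs
  spec <- filter_spec()
  bf <- signal::butter(spec$order, c(20, 200) / (fs / 2), type = "pass")
  s5 <- sin(2 * pi * 5 * t)
  y5 <- bandpass(s5, fs, spec)
  g5 <- analytic_gain(bf$b, bf$a, 5, fs)
  expect_lt(rms(y5) / rms(s5), 0.2)
  expect_lt(g5, 0.2)
  s100 <- sin(2 * pi * 100 * t)
  y100 <- bandpass(s100, fs, spec)
  steady <- 1001:5000
  g100 <- analytic_gain(bf$b, bf$a, 100, fs)
  expect_gt(rms(y100[steady]) / rms(s100[steady]), 0.9)
  expect_equal(rms(y100[steady]) / rms(s100[steady]), g100, tolerance = 0.01)
  expect_equal(bandpass(rep(0, 100), fs), rep(0, 100))
  expect_error(bandpass(s5, fs, filter_spec(band_low = 20, band_high = 600)),
               "band edges")
})

test_that("filtering is linear", {
  fs <- 1000
  set.seed(4)
  x <- rnorm(600)
  y <- rnorm(600)
  lhs <- bandpass(2 * x - 3 * y, fs)
  rhs <- 2 * bandpass(x, fs) - 3 * bandpass(y, fs)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  lhs_n <- notch(0.5 * x + y, fs)
  rhs_n <- 0.5 * notch(x, fs) + notch(y, fs)
  expect_equal(lhs_n, rhs_n, tolerance = 1e-9)
})

test_that("notch rejects its center tone and passes neighbors", {
  fs <- 1000
  t <- (0:4999) / fs
  steady <- 2001:5000
  s60 <- sin(2 * pi * 60 * t)
  att <- 20 * log10(rms(notch(s60, fs)[steady]) / rms(s60[steady]))
  expect_lte(att, -20)
  for (f in c(50, 70)) {
    sf <- sin(2 * pi * f * t)
    ch <- 20 * log10(rms(notch(sf, fs)[steady]) / rms(sf[steady]))
    expect_gt(ch, -3)
  }
  expect_equal(notch(rep(0, 50), fs), rep(0, 50))
  expect_error(notch(s60, fs, notch_hz = 600), "notch_hz")
})

test_that("phase labeling recovers the simulator ground truth", {
  frac <- eval(formals(simulation_config)$phase_fractions)
  ds <- c(frac[1], frac[3]) / sum(frac[1:3])
  agreements <- vapply(1:10, function(s) {
    sim <- simulate_recording(simulation_config(n_cycles = 5, seed = 300 + s))
    tl <- label_phases(sim$recording$hip_angle, sim$recording$pressure,
                       sim$recording$fs, ds_fractions = ds)
    mean(tl$labels == sim$timeline$labels)
  }, numeric(1))
  expect_gte(mean(agreements), 0.99)
  # cycle boundaries from the hip maxima sit on the true boundaries
  sim <- simulate_recording(simulation_config(n_cycles = 6, seed = 77))
  tl <- label_phases(sim$recording$hip_angle, sim$recording$pressure,
                     sim$recording$fs, ds_fractions = ds)
  truth <- sim$timeline$cycle_boundaries
  for (b in tl$cycle_boundaries)
    expect_lte(min(abs(b - truth)), 2)
  expect_error(label_phases(rep(1, 1000), rep(0:1, 500), 1000),
               "no gait cycles")
})

test_that("segmentation follows the window-count formula and majority rule", {
  mk_rec <- function(T_) {
    structure(list(emg = matrix(rnorm(12 * T_), 12), hip_angle = numeric(T_),
                   pressure = numeric(T_), fs = 1000, mode = "LW",
                   subject_id = "S01"), class = "emg_recording")
  }
  rec <- mk_rec(10000)
  tl <- phase_timeline(rep("SS", 10000), 1L)
  w <- segment_windows(rec, tl)
  expect_equal(dim(w$segments)[3L], 100L)
  expect_true(all(w$labels == "SS"))
  rec1 <- mk_rec(100)
  expect_equal(dim(segment_windows(rec1, phase_timeline(rep("SW", 100)),
                                   100, 100)$segments)[3L], 1L)
  # property: count formula over assorted (T, W, S)
  set.seed(1)
  for (i in 1:8) {
    T_ <- sample(200:1500, 1)
    W_ <- sample(c(50, 100, 150), 1)
    S_ <- sample(c(25, 50, 100), 1)
    r <- mk_rec(T_)
    ww <- segment_windows(r, phase_timeline(rep("DS2", T_)), W_, S_)
    expect_equal(attr(ww, "n_windows_raw"), (T_ - W_) %/% S_ + 1L)
  }
  # a 50/50 window is ambiguous and dropped
  rec2 <- mk_rec(100)
  tl2 <- phase_timeline(c(rep("SS", 50), rep("SW", 50)))
  w2 <- segment_windows(rec2, tl2)
  expect_equal(dim(w2$segments)[3L], 0L)
  expect_equal(attr(w2, "dropped"), 1L)
  # 80/20 keeps the majority label
  tl3 <- phase_timeline(c(rep("SS", 80), rep("SW", 20)))
  w3 <- segment_windows(rec2, tl3)
  expect_equal(as.character(w3$labels), "SS")
  expect_error(segment_windows(mk_rec(50), phase_timeline(rep("SS", 50)),
                               100), "window longer")
})

test_that("preprocessing a recording filters every channel", {
  sim <- simulate_recording(simulation_config(n_cycles = 2, seed = 12,
                                              mains_amplitude = 0.5))
  rec <- preprocess_recording(sim$recording)
  expect_equal(dim(rec$emg), dim(sim$recording$emg))
  # the 60 Hz mains line is strongly reduced
  fs <- rec$fs
  pow60 <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0)
    sum(sp$spec[abs(sp$freq - 60) < 1.5])
  }
  expect_lt(pow60(rec$emg[3, ]), 0.05 * pow60(sim$recording$emg[3, ]))
})
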