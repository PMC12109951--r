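test_that("embedding produces baseline-removed templates", {
  e <- embed_templates(1:5, 2)
  expect_equal(nrow(e), 4L)
  expect_equal(unname(e), matrix(rep(c(-0.5, 0.5), each = 4), 4))
  expect_equal(embed_templates(rep(3, 8), 3),
               matrix(0, 6, 3), ignore_attr = TRUE)
  expect_equal(nrow(embed_templates(rnorm(10), 6)), 5L)
  expect_error(embed_templates(1:3, 5), "length")
})

test_that("Chebyshev distance and Gaussian membership behave analytically", {
  expect_equal(cheb_dist(c(1, 5), c(4, 3)), 3)
  expect_equal(cheb_dist(c(2, 2), c(2, 2)), 0)
  expect_equal(cheb_dist(c(0, 0), c(0, -2)), 2)
  expect_error(cheb_dist(1:2, 1:3), "length")
  expect_equal(fuzzy_membership(0, 0.5), 1)
  expect_equal(fuzzy_membership(0.3, 0.3), exp(-0.5))
  d <- seq(0, 2, by = 0.25)
  expect_true(all(diff(fuzzy_membership(d, 0.4)) < 0))
  expect_error(fuzzy_membership(1, 0), "r must be")
})

test_that("phi is nonpositive, zero for constants, monotone in r", {
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(30)
    expect_lte(phi_m(x, 2, 0.2 * sd(x)), 0)
  }
  xc <- rep(2.5, 15)
  expect_equal(phi_m(xc, 2, 1e-12), 0)
  x <- rnorm(40)
  rs <- c(0.1, 0.2, 0.5, 1, 2) * sd(x)
  vals <- vapply(rs, function(r) phi_m(x, 2, r), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(phi_m(rnorm(3), 3, 0.1), "template")
})

test_that("fApEn matches the brute-force reference and its invariances", {
  set.seed(11)
  for (i in 1:6) {
    x <- rnorm(8 + 4 * i)
    expect_equal(fapen(x, 2), oracle_fapen(x, 2), tolerance = 1e-12)
  }
  x <- rnorm(60)
  expect_equal(fapen(rep(4, 20), 2), 0)
  expect_equal(fapen(3 * x + 7, 2), fapen(x, 2), tolerance = 1e-9)
  expect_equal(fapen(0.01 * x - 2, 2), fapen(x, 2), tolerance = 1e-9)
})

test_that("white noise is more irregular than a sinusoid at matched std", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    noise <- rnorm(100)
    sine <- sin(2 * pi * 4 * seq(0, 1, length.out = 100) + runif(1, 0, pi))
    sine <- sine / sd(sine) * sd(noise)
    if (fapen(noise, 2) > fapen(sine, 2)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
  expect_gt(fapen(rnorm(100), 2), 0)
})

test_that("per-scale entropies use enlarged embedding dimensions", {
  set.seed(5)
  x <- rnorm(40)
  p1 <- entropy_params(scales = 1L)
  se <- scale_entropies(x, p1)
  expect_equal(se$EX, fapen(x, 2, p1), tolerance = 1e-12)
  r <- 0.2 * sd(x)
  se3 <- scale_entropies(x)
  for (s in 1:3) {
    expect_equal(se3$EX[s], oracle_phi(x, 2 * s, r) - oracle_phi(x, 2 * s + 1, r),
                 tolerance = 1e-12)
    expect_equal(se3$EY[s], oracle_phi(x, 2 * s + 1, r) - oracle_phi(x, 2 * s + 2, r),
                 tolerance = 1e-12)
  }
  expect_equal(scale_entropies(rep(1, 30))$EX, rep(0, 3))
  expect_error(scale_entropies(rnorm(7)), "scale")
})

test_that("multi-scale aggregate matches the reference and degenerates to 0", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(10 + 6 * i)
    expect_equal(mfapen(x), oracle_mfapen(x), tolerance = 1e-12)
  }
  expect_equal(mfapen(rep(0.3, 25)), 0)
  # literal printed form: numerator and denominator coincide -> exactly 0
  expect_equal(mfapen(rnorm(30), entropy_params(literal = TRUE)), 0)
})

test_that("rms satisfies its analytic identities", {
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2.5, 9)), 2.5)
  x <- rnorm(17)
  expect_equal(rms(-x), rms(x))
  expect_error(rms(numeric(0)), "empty")
})

test_that("MFAREn fuses entropy and RMS", {
  set.seed(9)
  x <- rnorm(30)
  expect_equal(mfaren_value(x), mfapen(x) + rms(x), tolerance = 1e-12)
  expect_equal(mfaren_value(rep(1.5, 20)), 1.5)
  expect_equal(mfaren_value(rep(0, 20)), 0)
})

test_that("windowed extraction obeys the F = L - w + 1 bookkeeping", {
  set.seed(2)
  for (L in c(20L, 35L, 100L)) for (w in c(10L, 12L)) {
    seg <- matrix(rnorm(2 * L), 2, L)
    fm <- mfaren_features(seg, inner_window = w)
    expect_equal(ncol(fm), L - w + 1L)
  }
  seg1 <- matrix(rnorm(10), 1, 10)
  expect_equal(dim(mfaren_features(seg1)), c(1L, 1L))
  expect_equal(unname(mfaren_features(matrix(0, 3, 40))[, ]),
               matrix(0, 3, 31), ignore_attr = TRUE)
  expect_error(mfaren_features(matrix(rnorm(8), 1, 8)), "longer")
  # one window equals the direct per-window computation
  seg <- matrix(rnorm(60), 2, 30)
  fm <- mfaren_features(seg)
  expect_equal(fm[2, 5], mfaren_value(seg[2, 5:14]), tolerance = 1e-12)
})

test_that("active muscle windows score well above resting ones", {
  fs <- small_feature_set()
  # in DS1 of level walking, L_TA (row 5) is active and L_RF (row 1) rests
  sel <- fs$labels == "DS1"
  active <- mean(fs$features[sel, 5, ])
  resting <- mean(fs$features[sel, 1, ])
  expect_gt(active, 2 * resting)
})
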