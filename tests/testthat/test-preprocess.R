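test_that("zero-phase Butterworth has unit DC gain and the expected band edges", {
  # constant passes through exactly (DC gain 1, no edge transients)
  expect_equal(butterworth_zero_phase(rep(7.3, 50), fs = 120), rep(7.3, 50),
               tolerance = 1e-10)

  t <- seq(0, 5, by = 1 / 120)
  # 0.5 Hz is deep in the passband: < 1% attenuation
  y <- butterworth_zero_phase(sin(2 * pi * 0.5 * t), fs = 120)
  expect_gt(max(abs(y[150:450])), 0.99)
  # 30 Hz (5x cutoff) is crushed by the two-pass stopband: > 99% attenuation
  y <- butterworth_zero_phase(sin(2 * pi * 30 * t), fs = 120)
  expect_lt(max(abs(y[150:450])), 0.01)

  expect_error(butterworth_zero_phase(rnorm(5), fs = 120), "too short")
  expect_error(butterworth_zero_phase(rnorm(100), fs = 120, cutoff = 80),
               "Nyquist")
})

test_that("differentiation is exact on lines and accurate on smooth signals", {
  expect_equal(differentiate(3 + 2 * (0:49) / 50, fs = 50), rep(2, 50))
  expect_equal(differentiate(rep(4, 20), fs = 120), rep(0, 20))

  t <- seq(0, 2, by = 1 / 120)
  v <- differentiate(sin(2 * pi * t), fs = 120)
  truth <- 2 * pi * cos(2 * pi * t)
  interior <- 2:(length(t) - 1)
  # within 0.1% of the analytic derivative, relative to the amplitude
  expect_lt(max(abs(v[interior] - truth[interior])) / (2 * pi), 1e-3)

  expect_error(differentiate(1, fs = 10), "at least 2")
})

test_that("tangential speed matches analytic speeds of simple motions", {
  fs <- 100
  t <- (0:200) / fs
  # straight line at 10 cm/s
  pos <- cbind(10 * t, 0 * t, 0 * t)
  expect_equal(tangential_speed(pos, fs), rep(10, length(t)))
  # stationary
  expect_equal(tangential_speed(pos * 0, fs), rep(0, length(t)))
  # circular motion: |v| = r * omega
  r <- 3; omega <- 2
  circ <- cbind(r * cos(omega * t), r * sin(omega * t), 0 * t)
  sp <- tangential_speed(circ, fs)
  interior <- 5:(length(t) - 5)
  expect_lt(max(abs(sp[interior] - r * omega)) / (r * omega), 0.005)
})

test_that("movement bounds match a brute-force scan of the triangular profile", {
  sp <- triangle_speed()
  b <- detect_movement_bounds(sp, fs = 120)
  bf <- brute_force_bounds(sp, fs = 120)
  expect_identical(b$onset_idx, 7L)
  expect_identical(b$offset_idx, 114L)
  expect_equal(c(b$onset_idx, b$offset_idx), unname(bf))
  expect_false(b$offset_fallback)
})

test_that("movement bounds handle degenerate and sub-hold profiles", {
  expect_error(detect_movement_bounds(rep(0, 100), fs = 120), "no movement")
  # 0.05 s rectangular pulse: hold unmet, no onset
  pulse <- c(rep(0, 50), rep(100, 6), rep(0, 50))
  expect_error(detect_movement_bounds(pulse, fs = 120), "onset")
  # speed that never settles below threshold after the peak -> fallback
  sp <- c(seq(0, 100, length.out = 61), rep(60, 60))
  b <- detect_movement_bounds(sp, fs = 120)
  expect_true(b$offset_fallback)
  expect_identical(b$offset_idx, length(sp) - 1L)
})

test_that("movement bounds are scale-invariant and mirror under time reversal", {
  fs <- 120
  t <- (0:240) / fs
  sp <- exp(-((t - 1) / 0.25)^2) * 80  # generic smooth bell
  b1 <- detect_movement_bounds(sp, fs)
  for (c in c(0.01, 3.7, 1e4)) {
    b2 <- detect_movement_bounds(c * sp, fs)
    expect_identical(b2$onset_idx, b1$onset_idx)
    expect_identical(b2$offset_idx, b1$offset_idx)
  }
  br <- detect_movement_bounds(rev(sp), fs)
  n <- length(sp)
  expect_identical(br$onset_idx, n - 1L - b1$offset_idx)
  expect_identical(br$offset_idx, n - 1L - b1$onset_idx)
})

test_that("elbow angle reproduces known geometries and rigid-motion invariance", {
  sh <- matrix(c(0, 0, 0), 1)
  el <- matrix(c(30, 0, 0), 1)
  # collinear, elbow between shoulder and wrist -> 180 (full extension)
  expect_equal(elbow_angle_series(sh, el, matrix(c(60, 0, 0), 1)), 180)
  # perpendicular segments -> 90
  expect_equal(elbow_angle_series(sh, el, matrix(c(30, 25, 0), 1)), 90)
  # 120-degree geometry from the law of cosines construction
  wr <- matrix(c(30 + 25 * cos(pi / 3), 25 * sin(pi / 3), 0), 1)
  expect_equal(elbow_angle_series(sh, el, wr), 120)

  # invariance under rigid rotation + translation
  set.seed(42)
  ang <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3)
  Rz <- matrix(c(cos(ang[2]), sin(ang[2]), 0,
                 -sin(ang[2]), cos(ang[2]), 0, 0, 0, 1), 3)
  R <- Rx %*% Rz
  shift <- matrix(runif(3, -50, 50), 1)
  rot <- function(m) m %*% t(R) + shift[rep(1, nrow(m)), ]
  expect_equal(elbow_angle_series(rot(sh), rot(el), rot(wr)), 120)

  expect_error(elbow_angle_series(sh, sh, wr), "degenerate")
})

test_that("filtered segmentation of a reversed signal mirrors the bounds", {
  set.seed(3)
  fs <- 120
  t <- (0:360) / fs
  sp <- 60 * exp(-((t - 1.5) / 0.3)^2) + abs(rnorm(length(t), 0, 0.3))
  f1 <- butterworth_zero_phase(sp, fs)
  b1 <- detect_movement_bounds(pmax(f1, 0), fs)
  f2 <- butterworth_zero_phase(rev(sp), fs)
  b2 <- detect_movement_bounds(pmax(f2, 0), fs)
  n <- length(sp)
  # zero-phase filtering commutes with reversal, so bounds mirror exactly
  expect_identical(b2$onset_idx, n - 1L - b1$offset_idx)
  expect_identical(b2$offset_idx, n - 1L - b1$onset_idx)
})
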