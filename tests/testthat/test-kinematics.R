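test_that("circular mean respects wrap-around", {
  expect_equal(circular_mean(c(350, 10)), 0)
  expect_equal(circular_mean(c(90, 90, 90)), 90)
  expect_equal(circular_mean(c(0, 90)), 45)
  expect_error(circular_mean(c(0, 180)), "undefined")
  expect_error(circular_mean(numeric(0)), "empty")
})

test_that("movement time is the sample difference over the sampling rate", {
  expect_equal(movement_time(7, 114, 120), 107 / 120)  # 0.8917 s
  expect_equal(movement_time(10, 11, 120), 1 / 120)
  expect_equal(movement_time(7, 114, 240), 107 / 240)
  expect_error(movement_time(10, 10, 120), "precede")
})

test_that("thresholded mean velocity averages only the moving part", {
  expect_equal(mean_velocity_thresholded(c(0, 5, 50, 100, 50, 5, 0)),
               mean(c(50, 100, 50)))
  expect_equal(mean_velocity_thresholded(rep(12, 10)), 12)
  v <- c(0, 5, 50, 100, 50, 5, 0)
  expect_equal(mean_velocity_thresholded(3 * v), 3 * mean_velocity_thresholded(v))
  expect_error(mean_velocity_thresholded(c(-1, 0)), "positive")
})

test_that("velocity peak counting matches run-length oracles on constructed profiles", {
  fs <- 120
  # single minimum-jerk bell of 1 s: one rising phase of ~0.5 s
  tau <- seq(0, 1, by = 1 / fs)
  bell <- 30 * tau^2 * (1 - tau)^2  # single-peak velocity profile
  expect_identical(count_velocity_peaks(bell, fs), 1L)
  # two bells offset by 1.2 s: two qualifying rises
  t2 <- seq(0, 2.2, by = 1 / fs)
  two <- 30 * pmax(t2 * (1 - t2), 0)^2 + 30 * pmax((t2 - 1.2) * (2.2 - t2), 0)^2
  expect_identical(count_velocity_peaks(two, fs), 2L)
  # constant velocity: acceleration never positive
  expect_identical(count_velocity_peaks(rep(5, 100), fs), 0L)

  # invariance to positive scaling and constant shifts
  expect_identical(count_velocity_peaks(7 * two, fs), 2L)
  expect_identical(count_velocity_peaks(two + 100, fs), 2L)
})

make_kin_trial <- function(dur, end_angle, nsub = 1, spacing = 0,
                           id = "1", seed = 1) {
  p <- trial_params(duration = dur, start_angle = 30, end_angle = end_angle,
                    n_submovements = nsub, submovement_spacing = spacing,
                    noise_sd = 0, fs = 120)
  segment_trial(simulate_trial(p, seed = seed, trial_id = id))
}

test_that("a single trial summarizes to its own measures", {
  tr <- make_kin_trial(1, 95)
  s <- summarize_participant_target(list(tr))
  idx <- (tr$onset_idx + 1):(tr$offset_idx + 1)
  vel <- abs(differentiate(tr$angle[idx], tr$fs))
  expect_equal(s$movement_time, (tr$offset_idx - tr$onset_idx) / tr$fs)
  expect_equal(s$final_angle, tr$angle[tr$offset_idx + 1] %% 360)
  expect_equal(s$peak_velocity, max(vel))
  expect_equal(s$mean_velocity, mean_velocity_thresholded(vel))
  expect_equal(s$n_velocity_peaks, 1)
  expect_identical(s$n_trials, 1L)
})

test_that("aggregation uses circular means for angles and brute-force trial maxima", {
  trs <- list(make_kin_trial(0.8, 92, id = "1", seed = 1),
              make_kin_trial(1.0, 98, id = "2", seed = 2),
              make_kin_trial(1.2, 95, id = "3", seed = 3))
  s <- summarize_participant_target(trs)
  # peak velocity of the summary = mean of per-trial maxima (brute force)
  peaks <- vapply(trs, function(tr) {
    idx <- (tr$onset_idx + 1):(tr$offset_idx + 1)
    max(abs(differentiate(tr$angle[idx], tr$fs)))
  }, 0)
  expect_equal(s$peak_velocity, mean(peaks))
  expect_equal(s$final_angle, circular_mean(s$per_trial$final_angle))
  # per-trial invariant: peak >= thresholded mean
  expect_true(all(s$per_trial$peak_velocity >= s$per_trial$mean_velocity))
  # arithmetic option for velocity aggregation
  s2 <- summarize_participant_target(trs, velocity_aggregate = "arithmetic")
  expect_equal(s2$mean_velocity, mean(s$per_trial$mean_velocity))
})

test_that("circular aggregation of wrap-around final angles behaves circularly", {
  trs <- list(make_kin_trial(1, 95, id = "1"), make_kin_trial(1, 95, id = "2"))
  # shift whole angle traces so the final angles straddle the 0/360 wrap
  f1 <- trs[[1]]$angle[trs[[1]]$offset_idx + 1]
  f2 <- trs[[2]]$angle[trs[[2]]$offset_idx + 1]
  trs[[1]]$angle <- trs[[1]]$angle - f1 + 350
  trs[[2]]$angle <- trs[[2]]$angle - f2 + 370  # == 10 mod 360
  s <- suppressWarnings(summarize_participant_target(trs))
  expect_equal(s$final_angle, 0)
})

test_that("TSRT estimation recovers exact lines and flags degenerate input", {
  est <- estimate_tsrt(data.frame(stretch_velocity = c(100, 200),
                                  threshold_angle = c(80, 60)))
  expect_equal(est$tsrt_angle, 100)
  expect_equal(est$slope, -0.2)
  expect_equal(est$r_squared, 1)

  # flat thresholds: slope 0, intercept the common angle
  est2 <- estimate_tsrt(data.frame(stretch_velocity = c(50, 120, 300),
                                   threshold_angle = rep(95, 3)))
  expect_equal(est2$tsrt_angle, 95)
  expect_equal(est2$slope, 0)

  expect_error(estimate_tsrt(data.frame(stretch_velocity = 100,
                                        threshold_angle = 80)), "at least 2")
  expect_error(estimate_tsrt(data.frame(stretch_velocity = c(100, 100),
                                        threshold_angle = c(80, 85))),
               "distinct")
})

test_that("TSRT recovery from noisy dynamic thresholds is unbiased to ~1 degree", {
  errs <- vapply(1:60, function(s) {
    obs <- simulate_threshold_data(tsrt = 101, slope = -0.15,
                                   velocities = seq(50, 400, length.out = 8),
                                   noise_sd = 2, seed = s)
    estimate_tsrt(obs)$tsrt_angle - 101
  }, 0)
  expect_lt(abs(mean(errs)), 1)
})
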