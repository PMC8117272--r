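#' Circular mean of angles in degrees
#'
#' Mean direction of the unit vectors of the inputs (atan2 of the mean
#' sine and cosine), wrapped to `[0, 360)`.  Avoids the wrap-around
#' artifact of the arithmetic mean (e.g. 350 and 10 average to 0, not
#' 180).
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return mean angle in `[0, 360)`.
#' @export
circular_mean <- function(angles_deg) {
  if (length(angles_deg) == 0) stop("empty input")
  rad <- angles_deg * pi / 180
  s <- mean(sin(rad))
  c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12) {
    stop("circular mean undefined: resultant length is zero")
  }
  r <- (atan2(s, c) * 180 / pi) %% 360
  if (360 - r < 1e-9) r <- 0  # guard rounding just below the wrap point
  r
}

#' Movement time from segmentation bounds
#'
#' @param onset_idx,offset_idx 0-based sample indices, onset < offset.
#' @param fs sampling rate in Hz.
#' @return duration in seconds, `(offset - onset) / fs`.
#' @export
movement_time <- function(onset_idx, offset_idx, fs) {
  if (!(onset_idx < offset_idx)) stop("onset must precede offset")
  if (fs <= 0) stop("`fs` must be positive")
  (offset_idx - onset_idx) / fs
}

#' Thresholded mean velocity
#'
#' Arithmetic mean of the velocity samples exceeding 10% (by default) of
#' the peak; restricting to the moving part keeps segmented, stop-and-go
#' movements from dragging the mean toward zero.
#'
#' @param vel numeric velocity samples (deg/s); the peak must be positive.
#' @param frac threshold fraction of the peak (default 0.1).
#' @return mean of the samples with `vel > frac * max(vel)`.
#' @export
mean_velocity_thresholded <- function(vel, frac = 0.1) {
  m <- max(vel)
  if (m <= 0) stop("velocity profile has no positive samples")
  mean(vel[vel > frac * m])
}

#' Count velocity peaks via positive acceleration runs
#'
#' Differentiates the velocity profile and counts the maximal runs of
#' strictly positive acceleration lasting more than `hold` seconds.  A
#' smooth single reach has one such rise; segmented movements have one
#' per submovement, so the count is a smoothness measure.
#'
#' @param vel numeric velocity profile (length >= 3).
#' @param fs sampling rate in Hz.
#' @param hold minimum run duration in seconds (strictly greater than;
#'   default 0.1).
#' @return integer count (>= 0).
#' @export
count_velocity_peaks <- function(vel, fs, hold = 0.1) {
  if (length(vel) < 3) return(0L)
  acc <- differentiate(vel, fs)
  r <- rle(acc > 0)
  runs <- r$lengths[r$values]
  sum(runs / fs > hold)
}

#' Per-participant, per-target kinematic summary
#'
#' Computes the five clinical kinematic measures for each trial and
#' aggregates them over trials: movement time (from the segmentation
#' bounds), final elbow angle (angle at the movement offset sample),
#' mean and peak elbow velocity (velocity obtained by differentiating
#' the angle series within the movement segment; peak is the maximum
#' velocity magnitude, the mean is thresholded at 10% of the peak), and
#' the number of velocity peaks.  Final angle and mean velocity are
#' aggregated with the circular mean (values treated modulo 360);
#' movement time, peak velocity and peak count with the arithmetic mean.
#' Because velocities well above 360 deg/s wrap under circular
#' averaging, a message flags that case and
#' `velocity_aggregate = "arithmetic"` provides a plain alternative.
#'
#' @param trials list of [reach_trial()] objects sharing one participant
#'   and target; discarded trials are ignored.
#' @param velocity_aggregate "circular" (default) or "arithmetic"
#'   aggregation for the mean-velocity measure.
#' @return list of class `kinematic_summary` with the per-trial table in
#'   `$per_trial` and the aggregates as top-level fields.
#' @export
summarize_participant_target <- function(trials,
                                         velocity_aggregate = c("circular", "arithmetic")) {
  velocity_aggregate <- match.arg(velocity_aggregate)
  trials <- Filter(function(tr) !isTRUE(tr$discarded), trials)
  if (length(trials) == 0) stop("no valid trials")
  pid <- unique(vapply(trials, `[[`, "", "participant_id"))
  tgt <- unique(vapply(trials, `[[`, "", "target"))
  if (length(pid) != 1 || length(tgt) != 1) {
    stop("all trials must share one participant and one target")
  }

  per <- lapply(trials, function(tr) {
    idx <- (tr$onset_idx + 1L):(tr$offset_idx + 1L)
    seg <- tr$angle[idx]
    vel <- abs(differentiate(seg, tr$fs))
    data.frame(
      trial_id = tr$trial_id,
      movement_time = movement_time(tr$onset_idx, tr$offset_idx, tr$fs),
      final_angle = tr$angle[tr$offset_idx + 1L],
      mean_velocity = mean_velocity_thresholded(vel),
      peak_velocity = max(vel),
      n_velocity_peaks = count_velocity_peaks(vel, tr$fs),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)

  mv <- per$mean_velocity
  if (velocity_aggregate == "circular") {
    if (max(mv) >= 360) {
      message("mean velocities exceed 360 deg/s; circular aggregation wraps ",
              "(use velocity_aggregate = \"arithmetic\" to avoid)")
    }
    mean_vel <- circular_mean(mv)
  } else {
    mean_vel <- mean(mv)
  }

  structure(list(
    participant_id = pid, target = tgt, n_trials = nrow(per),
    movement_time = mean(per$movement_time),
    final_angle = circular_mean(per$final_angle),
    mean_velocity = mean_vel,
    peak_velocity = mean(per$peak_velocity),
    n_velocity_peaks = mean(per$n_velocity_peaks),
    velocity_aggregate = velocity_aggregate,
    per_trial = per
  ), class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf(paste0("<kinematic_summary> %s / %s (%d trials): MT %.3f s, ",
                     "final %.1f deg, mean vel %.1f, peak vel %.1f deg/s, ",
                     "%.2f peaks\n"),
              x$participant_id, x$target, x$n_trials, x$movement_time,
              x$final_angle, x$mean_velocity, x$peak_velocity,
              x$n_velocity_peaks))
  invisible(x)
}

#' Estimate the tonic stretch reflex threshold (TSRT)
#'
#' Ordinary least-squares regression of dynamic threshold angles on
#' stretch velocity; the TSRT is the extrapolated threshold angle at
#' zero stretch velocity (the regression intercept).
#'
#' @param observations data frame with columns `stretch_velocity`
#'   (deg/s, positive) and `threshold_angle` (deg); at least two
#'   observations with distinct velocities.
#' @return list of class `tsrt_estimate` with `tsrt_angle` (deg),
#'   `slope` (deg per deg/s) and `r_squared`.
#' @examples
#' obs <- data.frame(stretch_velocity = c(100, 200),
#'                   threshold_angle = c(80, 60))
#' estimate_tsrt(obs)  # TSRT 100, slope -0.2
#' @export
estimate_tsrt <- function(observations) {
  v <- observations$stretch_velocity
  a <- observations$threshold_angle
  if (length(v) < 2) stop("need at least 2 observations")
  if (length(unique(v)) < 2) {
    stop("rank-deficient: need at least 2 distinct stretch velocities")
  }
  if (any(v <= 0)) stop("stretch velocities must be positive")
  fit <- stats::lm(a ~ v)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    tsrt_angle = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    r_squared = r2
  ), class = "tsrt_estimate")
}

#' @export
print.tsrt_estimate <- function(x, ...) {
  cat(sprintf("<tsrt_estimate> TSRT %.2f deg, slope %.4f deg/(deg/s), R^2 %.3f\n",
              x$tsrt_angle, x$slope, x$r_squared))
  invisible(x)
}
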