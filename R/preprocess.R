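#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward so the net
#' result has zero phase lag, the standard way of smoothing motion-capture
#' signals before differentiation.  Edge transients are suppressed by
#' odd-reflection padding combined with steady-state initial conditions,
#' so a constant input is returned unchanged (unit DC gain).
#'
#' @param series numeric vector to filter.
#' @param fs sampling rate in Hz.
#' @param cutoff low-pass cutoff frequency in Hz (default 6).
#' @param order filter order (default 3); the two-pass application doubles
#'   the effective roll-off.
#' @return filtered numeric vector of the same length.
#' @examples
#' t <- seq(0, 2, by = 1 / 120)
#' x <- sin(2 * pi * 0.5 * t) + rnorm(length(t), sd = 0.05)
#' xf <- butterworth_zero_phase(x, fs = 120)
#' @export
butterworth_zero_phase <- function(series, fs, cutoff = 6, order = 3) {
  if (!is.numeric(series)) stop("`series` must be numeric")
  if (fs <= 0) stop("`fs` must be positive")
  if (cutoff >= fs / 2) {
    stop("`cutoff` must be below the Nyquist frequency fs/2")
  }
  n <- length(series)
  if (n < 3 * order) {
    stop("series too short to filter: need at least 3 * order samples")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- bf$b
  a <- bf$a

  # steady-state initial filter state (direct form II transposed), so a
  # step input produces no start-up transient
  m <- length(a) - 1
  comp <- rbind(-a[-1], cbind(diag(1, m - 1), rep(0, m - 1)))
  zi <- solve(diag(m) - t(comp), b[-1] - a[-1] * b[1])

  pad <- min(n - 1, max(3 * (m + 1), 12))
  left <- 2 * series[1] - series[seq(pad + 1, 2)]
  right <- 2 * series[n] - series[seq(n - 1, n - pad)]
  ext <- c(left, series, right)

  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[seq(pad + 1, pad + n)]
}

#' Differentiate a sampled signal
#'
#' Central differences at interior samples and one-sided differences at
#' the two ends; second-order accurate in the interior with no phase lag.
#'
#' @param series numeric vector.
#' @param fs sampling rate in Hz.
#' @return numeric vector of the same length, in input units per second.
#' @examples
#' differentiate(c(0, 1, 2, 3), fs = 10)  # constant slope 10
#' @export
differentiate <- function(series, fs) {
  n <- length(series)
  if (n < 2) stop("need at least 2 samples to differentiate")
  if (fs <= 0) stop("`fs` must be positive")
  v <- numeric(n)
  v[1] <- (series[2] - series[1]) * fs
  v[n] <- (series[n] - series[n - 1]) * fs
  if (n > 2) {
    idx <- 2:(n - 1)
    v[idx] <- (series[idx + 1] - series[idx - 1]) * fs / 2
  }
  v
}

#' Tangential speed of a 3-D marker trajectory
#'
#' Euclidean norm of the componentwise derivative of a position series;
#' used on the forearm marker to drive movement segmentation.
#'
#' @param positions numeric matrix with one row per sample and 3 columns
#'   (x, y, z), in cm.
#' @param fs sampling rate in Hz.
#' @return nonnegative numeric vector (cm/s), same number of samples.
#' @export
tangential_speed <- function(positions, fs) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("need at least 2 samples")
  d <- apply(positions, 2, differentiate, fs = fs)
  sqrt(rowSums(d^2))
}

#' Detect movement onset and offset from a speed profile
#'
#' Onset is the first sample at which the speed exceeds \code{frac} of its
#' peak and stays above that threshold for at least \code{hold} seconds.
#' Offset is the last moving sample: the sample immediately before the
#' speed first drops below the threshold after the global peak and stays
#' below it for at least \code{hold} seconds (a below-threshold run that
#' reaches the end of the recording also qualifies, since the movement has
#' clearly ended).  If the speed never settles below the threshold after
#' the peak, the offset falls back to the last sample and the result is
#' flagged.  Indices are 0-based sample offsets, so durations are simply
#' \code{(offset - onset) / fs} regardless of indexing origin.
#'
#' @param speed nonnegative numeric vector.
#' @param fs sampling rate in Hz.
#' @param frac threshold as a fraction of the peak speed (default 0.1).
#' @param hold minimum time in seconds the speed must remain beyond the
#'   threshold (default 0.1).
#' @return list with elements \code{onset_idx}, \code{offset_idx} (0-based
#'   integers) and \code{offset_fallback} (logical).
#' @examples
#' sp <- c(seq(0, 100, length.out = 61), seq(100, 0, length.out = 61)[-1])
#' detect_movement_bounds(sp, fs = 120)
#' @export
detect_movement_bounds <- function(speed, fs, frac = 0.1, hold = 0.1) {
  if (any(!is.finite(speed))) stop("`speed` must be finite")
  if (max(speed) <= 0) stop("no movement: speed profile has no positive peak")
  hold_n <- max(1L, as.integer(round(hold * fs)))
  thr <- frac * max(speed)
  n <- length(speed)

  runs <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values],
               len = r$lengths[r$values])
  }

  above <- runs(speed > thr)
  above <- above[above$len >= hold_n, , drop = FALSE]
  if (nrow(above) == 0) {
    stop("no movement onset: speed never holds above threshold for `hold` s")
  }
  onset <- above$start[1] - 1L  # 0-based

  peak <- which.max(speed)
  below <- runs(seq_len(n) > peak & speed < thr)
  qualifies <- below$len >= hold_n | below$end == n
  below <- below[qualifies, , drop = FALSE]
  if (nrow(below) > 0) {
    offset <- below$start[1] - 2L  # 0-based index of the sample before the run
    fallback <- FALSE
  } else {
    offset <- n - 1L
    fallback <- TRUE
  }
  if (offset <= onset) stop("degenerate segmentation: offset <= onset")
  list(onset_idx = as.integer(onset), offset_idx = as.integer(offset),
       offset_fallback = fallback)
}

#' Elbow angle from shoulder, elbow and wrist joint centers
#'
#' The included angle at the elbow between the upper-arm vector
#' (shoulder - elbow) and the forearm vector (wrist - elbow), in degrees.
#' 180 degrees corresponds to full extension.  For elbow
#' flexion/extension this 3-point angle equals the flexion component of a
#' Cardan decomposition up to sign and offset.
#'
#' @param shoulder,elbow,wrist numeric matrices of equal size, one row per
#'   sample, 3 columns (x, y, z).
#' @return numeric vector of angles in `[0, 180]` degrees.
#' @export
elbow_angle_series <- function(shoulder, elbow, wrist) {
  shoulder <- as.matrix(shoulder); elbow <- as.matrix(elbow); wrist <- as.matrix(wrist)
  if (nrow(shoulder) != nrow(elbow) || nrow(elbow) != nrow(wrist)) {
    stop("landmark series must have equal lengths")
  }
  u <- shoulder - elbow
  v <- wrist - elbow
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  if (any(nu < 1e-9) || any(nv < 1e-9)) {
    stop("degenerate geometry: elbow coincides with shoulder or wrist")
  }
  cosang <- rowSums(u * v) / (nu * nv)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Construct an analyzed reach trial
#'
#' Bundles a segmented trial: the (filtered) elbow-angle series, the speed
#' series used for segmentation, the movement bounds and metadata.
#'
#' @param participant_id,target,trial_id character labels; `target` is one
#'   of "NC", "FC", "CL", "IL" (near-center, far-center, contra-, ipsilateral).
#' @param fs sampling rate in Hz.
#' @param angle elbow-angle series in degrees.
#' @param speed forearm tangential speed series (cm/s), same length.
#' @param onset_idx,offset_idx 0-based movement bounds.
#' @param group optional cohort label ("control" or "stroke").
#' @param discarded logical; flagged trials are excluded from modeling.
#' @param discard_reason character.
#' @param offset_fallback logical, see [detect_movement_bounds()].
#' @return an object of class `reach_trial`.
#' @export
reach_trial <- function(participant_id, target, trial_id, fs, angle, speed,
                        onset_idx, offset_idx, group = NA_character_,
                        discarded = FALSE, discard_reason = NA_character_,
                        offset_fallback = FALSE) {
  stopifnot(fs > 0, length(angle) == length(speed))
  if (!(onset_idx >= 0 && onset_idx < offset_idx &&
        offset_idx < length(angle))) {
    stop("invalid movement bounds: need 0 <= onset < offset < length")
  }
  structure(list(
    participant_id = as.character(participant_id),
    target = as.character(target),
    trial_id = as.character(trial_id),
    group = as.character(group),
    fs = fs, angle = as.numeric(angle), speed = as.numeric(speed),
    onset_idx = as.integer(onset_idx), offset_idx = as.integer(offset_idx),
    discarded = isTRUE(discarded), discard_reason = discard_reason,
    offset_fallback = isTRUE(offset_fallback)
  ), class = "reach_trial")
}

#' @export
print.reach_trial <- function(x, ...) {
  cat(sprintf("<reach_trial> %s / %s / trial %s: %d samples @ %g Hz, movement [%d, %d] (%.3f s)%s\n",
              x$participant_id, x$target, x$trial_id, length(x$angle), x$fs,
              x$onset_idx, x$offset_idx, (x$offset_idx - x$onset_idx) / x$fs,
              if (x$discarded) " [discarded]" else ""))
  invisible(x)
}

#' Filter and segment one recorded trial
#'
#' The per-trial preprocessing chain: zero-phase Butterworth filtering of
#' the angle and speed traces, then velocity-threshold segmentation of the
#' first movement.
#'
#' @param recording a `reach_recording` (see [simulate_trial()]) or a list
#'   with fields `participant_id`, `target`, `trial_id`, `fs`, `angle`,
#'   `speed` and optionally `group`.
#' @param cutoff,order Butterworth parameters, see [butterworth_zero_phase()].
#' @param frac,hold segmentation parameters, see [detect_movement_bounds()].
#' @return a [reach_trial()] object.
#' @export
segment_trial <- function(recording, cutoff = 6, order = 3,
                          frac = 0.1, hold = 0.1) {
  fs <- recording$fs
  angle <- butterworth_zero_phase(recording$angle, fs, cutoff, order)
  speed <- butterworth_zero_phase(recording$speed, fs, cutoff, order)
  speed <- pmax(speed, 0)
  b <- detect_movement_bounds(speed, fs, frac = frac, hold = hold)
  reach_trial(
    participant_id = recording$participant_id,
    target = recording$target,
    trial_id = recording$trial_id,
    group = if (is.null(recording$group)) NA_character_ else recording$group,
    fs = fs, angle = angle, speed = speed,
    onset_idx = b$onset_idx, offset_idx = b$offset_idx,
    discarded = isTRUE(recording$discarded),
    discard_reason = if (is.null(recording$discard_reason)) NA_character_ else recording$discard_reason,
    offset_fallback = b$offset_fallback
  )
}
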