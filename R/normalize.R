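#' Min-max scaling parameters
#'
#' Records the original-unit range of one model dimension (time or angle)
#' so that scaling to `[-1, 1]` is invertible.
#'
#' @param dim "time" or "angle".
#' @param min_val,max_val range in original units; `max_val > min_val`.
#' @return an object of class `scale_params`.
#' @export
scale_params <- function(dim, min_val, max_val) {
  dim <- match.arg(dim, c("time", "angle"))
  if (!(max_val > min_val)) stop("degenerate range: max_val must exceed min_val")
  structure(list(dim = dim, min_val = min_val, max_val = max_val,
                 lo = -1, hi = 1), class = "scale_params")
}

#' Linearly scale values to `[-1, 1]`
#'
#' `x_new = 2 (x - min) / (max - min) - 1`, so the recorded minimum maps
#' to -1 and the maximum to +1.  Scaling both model dimensions to the same
#' range keeps the mixture model from being dominated by the dimension
#' with the larger numeric magnitude.
#'
#' @param values numeric vector.
#' @param params a [scale_params()] object.
#' @return scaled numeric vector.
#' @seealso [minmax_unscale()]
#' @export
minmax_scale <- function(values, params) {
  stopifnot(inherits(params, "scale_params"))
  2 * (values - params$min_val) / (params$max_val - params$min_val) - 1
}

#' Invert [minmax_scale()]
#' @param values scaled numeric vector.
#' @param params a [scale_params()] object.
#' @return values in original units.
#' @export
minmax_unscale <- function(values, params) {
  stopifnot(inherits(params, "scale_params"))
  (values + 1) / 2 * (params$max_val - params$min_val) + params$min_val
}

#' Gaussian-kernel regression (general regression neural network)
#'
#' Nadaraya-Watson kernel regression with a Gaussian kernel,
#' \deqn{\hat y(t) = \sum_i y_i e^{-(t - t_i)^2 / 2\sigma^2} /
#'       \sum_i e^{-(t - t_i)^2 / 2\sigma^2},}
#' the normalized-radial-basis form of a general regression neural
#' network.  Used to approximate each trial's angle-versus-time function
#' so that all trials can be resampled to a common length.
#'
#' @param train_t,train_y training abscissae and values.
#' @param query_t points at which to evaluate the fit.
#' @param bandwidth Gaussian kernel width \eqn{\sigma} (> 0), in units of
#'   `train_t`.
#' @return fitted values at `query_t`; always within the range of `train_y`.
#' @export
grnn_regress <- function(train_t, train_y, query_t, bandwidth) {
  if (length(train_t) < 1) stop("empty training set")
  if (length(train_t) != length(train_y)) stop("train_t and train_y lengths differ")
  if (bandwidth <= 0) stop("`bandwidth` must be positive")
  # log-space weights, shifted per query point so distant queries do not underflow
  a <- -outer(query_t, train_t, "-")^2 / (2 * bandwidth^2)
  a <- a - apply(a, 1, max)
  w <- exp(a)
  as.numeric((w %*% train_y) / rowSums(w))
}

#' Pool, resample and scale trials into a model input set
#'
#' Builds the point cloud a spatiotemporal mixture model is fitted to,
#' for one participant and target.  The common resampling count is
#' `n_samples = round(mean movement duration * fs)`.  Each trial's
#' angle-versus-time function (within its own movement segment) is
#' approximated by Gaussian-kernel regression and sampled at `n_samples`
#' uniformly spaced times across that trial's segment, so duration
#' differences between trials are preserved.  Per-trial time is expressed
#' in units of the mean movement duration, and both dimensions are then
#' min-max scaled to `[-1, 1]` using the pooled (across-trial) range, so
#' relative amplitude differences between trials survive scaling.
#'
#' @param trials list of [reach_trial()] objects for one participant and
#'   target; discarded trials are ignored.
#' @param bandwidth_mult kernel bandwidth as a multiple of the mean
#'   spacing of the trial's time samples (default 2).
#' @return an object of class `model_input_set` with fields `points`
#'   (matrix, columns scaled time and scaled angle), `scale_params`,
#'   `n_samples`, `n_trials`, `participant_id`, `target`.
#' @export
build_model_set <- function(trials, bandwidth_mult = 2) {
  trials <- Filter(function(tr) !isTRUE(tr$discarded), trials)
  if (length(trials) == 0) stop("no valid trials")
  pid <- unique(vapply(trials, `[[`, "", "participant_id"))
  tgt <- unique(vapply(trials, `[[`, "", "target"))
  if (length(pid) != 1 || length(tgt) != 1) {
    stop("all trials must share one participant and one target")
  }
  fs <- trials[[1]]$fs

  seg_len <- vapply(trials, function(tr) tr$offset_idx - tr$onset_idx + 1L, 1L)
  keep <- seg_len >= 2L
  if (!all(keep)) {
    message(sum(!keep), " trial(s) shorter than 2 samples skipped")
    trials <- trials[keep]
  }
  if (length(trials) == 0) stop("no valid trials")

  durations <- vapply(trials, function(tr) (tr$offset_idx - tr$onset_idx) / tr$fs, 0)
  mean_dur <- mean(durations)
  n_samples <- max(2L, as.integer(round(mean_dur * fs)))

  times <- numeric(0)
  angles <- numeric(0)
  for (tr in trials) {
    idx <- (tr$onset_idx + 1L):(tr$offset_idx + 1L)  # 0-based bounds -> R slice
    seg <- tr$angle[idx]
    t_seg <- (seq_along(seg) - 1) / tr$fs
    bw <- bandwidth_mult * mean(diff(t_seg))
    q <- seq(0, max(t_seg), length.out = n_samples)
    yhat <- grnn_regress(t_seg, seg, q, bw)
    times <- c(times, q / mean_dur)
    angles <- c(angles, yhat)
  }

  sp_t <- scale_params("time", min(times), max(times))
  sp_a <- scale_params("angle", min(angles), max(angles))
  pts <- cbind(time = minmax_scale(times, sp_t),
               angle = minmax_scale(angles, sp_a))
  structure(list(
    participant_id = pid, target = tgt,
    points = pts, n_samples = n_samples, n_trials = length(trials),
    scale_params = list(time = sp_t, angle = sp_a)
  ), class = "model_input_set")
}

#' @export
print.model_input_set <- function(x, ...) {
  cat(sprintf("<model_input_set> %s / %s: %d trials x %d samples = %d points\n",
              x$participant_id, x$target, x$n_trials, x$n_samples,
              nrow(x$points)))
  invisible(x)
}
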