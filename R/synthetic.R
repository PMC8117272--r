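#' Parameters of one simulated reach trial
#'
#' @param duration movement duration in seconds (> 0).
#' @param start_angle,end_angle elbow extension angle (degrees) at
#'   movement start and end.
#' @param n_submovements number of superimposed minimum-jerk
#'   submovements (>= 1); healthy reaches have one, segmented stroke-like
#'   reaches several.
#' @param submovement_spacing onset-to-onset spacing of consecutive
#'   submovements in seconds; `duration >= (n_submovements - 1) * spacing`.
#' @param noise_sd Gaussian measurement noise SD on the angle trace (deg).
#' @param motor_sd SD (deg) of slow within-trial motor variability
#'   (~2 Hz path wander), amplitude-modulated by the movement
#'   (signal-dependent noise), so repeated trials follow visibly
#'   different trajectories while the resting arm stays still.
#' @param jitter_sd SD (deg) of fast corrective jitter (~5 Hz, still
#'   below the 6-Hz analysis cutoff), also movement-gated; small relative
#'   to `motor_sd`, it roughens trajectories without reshaping them.
#' @param fs sampling rate in Hz (default 120).
#' @param pad quiet time in seconds prepended and appended to the
#'   movement so that segmentation has a rest baseline (default 0.4).
#' @param forearm_cm forearm length used to emit a consistent tangential
#'   speed trace (default 25 cm).
#' @return list of class `trial_params`.
#' @export
trial_params <- function(duration, start_angle = 30, end_angle = 90,
                         n_submovements = 1, submovement_spacing = 0,
                         noise_sd = 0, motor_sd = 0, jitter_sd = 0,
                         fs = 120, pad = 0.4, forearm_cm = 25) {
  if (duration <= 0) stop("duration must be positive")
  if (fs <= 0) stop("fs must be positive")
  if (n_submovements < 1) stop("n_submovements must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (motor_sd < 0) stop("motor_sd must be >= 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (duration < (n_submovements - 1) * submovement_spacing) {
    stop("infeasible timing: duration < (n_submovements - 1) * spacing")
  }
  structure(list(duration = duration, start_angle = start_angle,
                 end_angle = end_angle, n_submovements = n_submovements,
                 submovement_spacing = submovement_spacing,
                 noise_sd = noise_sd, motor_sd = motor_sd,
                 jitter_sd = jitter_sd, fs = fs,
                 pad = pad, forearm_cm = forearm_cm),
            class = "trial_params")
}

# minimum-jerk position profile on [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Simulate one reach trial
#'
#' The underlying movement is `start + (end - start) * s(t) + w(t) m(t)`,
#' where `s(t)` is a superposition of `n_submovements` minimum-jerk
#' position profiles (`10 tau^3 - 15 tau^4 + 6 tau^5`) of equal amplitude
#' summing to one, with onsets `submovement_spacing` apart, each lasting
#' `duration - (n_submovements - 1) * spacing` so the whole movement
#' spans `duration`; `m(t)` is a smooth (spline-interpolated) motor
#' wander of SD `motor_sd` modulated by the movement envelope
#' `w = 4 s (1 - s)`, so variability is signal-dependent and the resting
#' arm is still.  The emitted angle trace adds white measurement noise of
#' SD `noise_sd`; the forearm tangential speed trace is the scaled
#' magnitude of the derivative of the underlying movement (in practice
#' speed comes from heavily filtered position data, so it does not carry
#' the angle trace's white noise).  Quiet padding surrounds the movement.
#' The same seed reproduces the trial bitwise.
#'
#' @param p a [trial_params()] object.
#' @param seed integer RNG seed.
#' @param participant_id,target,trial_id,group metadata labels.
#' @return list of class `reach_recording` with fields `t`, `angle`,
#'   `speed`, `fs` and the metadata.
#' @export
simulate_trial <- function(p, seed, participant_id = "P1", target = "NC",
                           trial_id = "1", group = NA_character_) {
  stopifnot(inherits(p, "trial_params"))
  set.seed(as.integer(seed))
  d_sub <- p$duration - (p$n_submovements - 1) * p$submovement_spacing
  total <- p$pad + p$duration + p$pad
  n <- as.integer(round(total * p$fs)) + 1L
  t <- (seq_len(n) - 1) / p$fs

  s <- numeric(n)
  for (j in seq_len(p$n_submovements)) {
    onset <- p$pad + (j - 1) * p$submovement_spacing
    s <- s + min_jerk((t - onset) / d_sub) / p$n_submovements
  }
  movement <- p$start_angle + (p$end_angle - p$start_angle) * s
  # signal-dependent motor variability, gated by the movement envelope so
  # the resting arm stays still: slow path wander (knots every 0.25 s)
  # plus fast corrective jitter (knots every 0.1 s)
  envelope <- pmin(pmax(4 * s * (1 - s), 0), 1)
  smooth_noise <- function(spacing, sd) {
    knots <- seq(0, max(t), by = spacing)
    stats::spline(knots, stats::rnorm(length(knots), sd = sd), xout = t)$y
  }
  if (p$motor_sd > 0) {
    movement <- movement + envelope * smooth_noise(0.25, p$motor_sd)
  }
  if (p$jitter_sd > 0) {
    movement <- movement + envelope * smooth_noise(0.1, p$jitter_sd)
  }
  angle <- movement + stats::rnorm(n, sd = p$noise_sd)
  speed <- abs(differentiate(movement, p$fs)) * pi / 180 * p$forearm_cm

  structure(list(
    participant_id = participant_id, target = target, trial_id = trial_id,
    group = group, fs = p$fs, t = t, angle = angle, speed = speed,
    params = p, discarded = FALSE, discard_reason = NA_character_
  ), class = "reach_recording")
}

#' Cohort simulation settings
#'
#' Group-level distributions over trial parameters for a synthetic
#' cohort of healthy-like controls and stroke-like participants.  The
#' defaults emulate the contrast between fast, smooth, single-peaked
#' healthy reaches and slow, segmented, variable stroke-like reaches:
#' control movements last about 0.67 s with one submovement; stroke-like
#' movements last about 1.7 s and are composed of 5-9 submovements.
#' Endpoint angles per target follow typical final elbow extension
#' angles of reaches to near-center (NC), far-center (FC), contralateral
#' (CL) and ipsilateral (IL) targets.  Participant-level random effects
#' (offsets on duration and endpoint) sit on top of trial-level noise,
#' mirroring the random-effect structure of mixed-model analyses of such
#' cohorts.
#'
#' @param n_controls,n_stroke group sizes (default 13 each).
#' @param trials_per_target trials per participant per target (default 10).
#' @param targets target labels.
#' @param seed integer master seed.
#' @param control,stroke named lists of group parameters; see Details.
#' @details Each group list carries `duration_mean`, `duration_sd_participant`,
#'   `duration_sd_trial` (s), `n_submovements` (range, inclusive),
#'   `spread_frac` (fraction of the movement spanned by submovement
#'   onsets), `noise_sd` (deg, white measurement noise), `motor_sd` (deg,
#'   smooth within-trial motor variability), `start_angle` (deg),
#'   `end_angles` (named per-target vector, deg),
#'   `endpoint_sd_participant`, `endpoint_sd_trial` (deg), and `fs` (Hz).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 13, n_stroke = 13,
                          trials_per_target = 10,
                          targets = c("NC", "FC", "CL", "IL"),
                          seed = 1,
                          control = list(), stroke = list()) {
  ctrl_default <- list(
    duration_mean = 0.67, duration_sd_participant = 0.08,
    duration_sd_trial = 0.08, n_submovements = c(1, 1), spread_frac = 0.6,
    noise_sd = 0.75, motor_sd = 1.5, jitter_sd = 0.5, start_angle = 30,
    end_angles = c(NC = 81, FC = 101.6, CL = 98.4, IL = 100.1),
    endpoint_sd_participant = 5, endpoint_sd_trial = 3, fs = 120)
  strk_default <- list(
    duration_mean = 1.7, duration_sd_participant = 0.35,
    duration_sd_trial = 0.2, n_submovements = c(5, 9), spread_frac = 0.85,
    noise_sd = 1.5, motor_sd = 4, jitter_sd = 1, start_angle = 30,
    end_angles = c(NC = 89.3, FC = 98.1, CL = 96.5, IL = 100.0),
    endpoint_sd_participant = 9, endpoint_sd_trial = 6, fs = 120)
  ctrl <- utils::modifyList(ctrl_default, control)
  strk <- utils::modifyList(strk_default, stroke)
  if (n_controls < 1 || n_stroke < 1) stop("group sizes must be >= 1")
  if (strk$duration_mean <= ctrl$duration_mean) {
    stop("stroke mean duration must exceed control mean duration")
  }
  if (max(strk$n_submovements) < max(ctrl$n_submovements)) {
    stop("stroke submovement count must be >= control's")
  }
  structure(list(n_controls = n_controls, n_stroke = n_stroke,
                 trials_per_target = trials_per_target, targets = targets,
                 seed = as.integer(seed), control = ctrl, stroke = strk),
            class = "cohort_config")
}

#' Simulate a synthetic cohort of reach trials
#'
#' Generates `trials_per_target` trials per participant per target for
#' both groups of a [cohort_config()].  Participant random effects are
#' Gaussian offsets on movement duration and endpoint angle; trial-level
#' draws add duration and endpoint jitter and, for multi-submovement
#' groups, a per-trial submovement count.  Fully reproducible from the
#' config seed.
#'
#' @param cfg a [cohort_config()].
#' @return list of `reach_recording` objects.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  recordings <- list()
  trial_counter <- 0L
  for (grp in c("control", "stroke")) {
    g <- cfg[[grp]]
    n_part <- if (grp == "control") cfg$n_controls else cfg$n_stroke
    for (i in seq_len(n_part)) {
      pid <- sprintf("%s%02d", if (grp == "control") "C" else "S", i)
      pseed <- cfg$seed * 1000L + trial_counter
      set.seed(pseed %% .Machine$integer.max)
      dur_off <- stats::rnorm(1, sd = g$duration_sd_participant)
      end_off <- stats::rnorm(1, sd = g$endpoint_sd_participant)
      for (tgt in cfg$targets) {
        for (k in seq_len(cfg$trials_per_target)) {
          trial_counter <- trial_counter + 1L
          tseed <- (cfg$seed * 1000003L + trial_counter * 7919L) %% 2147483647L
          set.seed(tseed)
          duration <- max(0.3, g$duration_mean + dur_off +
                            stats::rnorm(1, sd = g$duration_sd_trial))
          endpoint <- g$end_angles[[tgt]] + end_off +
            stats::rnorm(1, sd = g$endpoint_sd_trial)
          nsub <- if (g$n_submovements[1] == g$n_submovements[2]) {
            g$n_submovements[1]
          } else {
            sample(seq(g$n_submovements[1], g$n_submovements[2]), 1)
          }
          spacing <- if (nsub > 1) duration * g$spread_frac / (nsub - 1) else 0
          p <- trial_params(duration = duration, start_angle = g$start_angle,
                            end_angle = endpoint, n_submovements = nsub,
                            submovement_spacing = spacing,
                            noise_sd = g$noise_sd, motor_sd = g$motor_sd,
                            jitter_sd = g$jitter_sd, fs = g$fs)
          recordings[[length(recordings) + 1L]] <-
            simulate_trial(p, seed = tseed, participant_id = pid,
                           target = tgt, trial_id = as.character(k),
                           group = grp)
        }
      }
    }
  }
  attr(recordings, "config") <- cfg
  recordings
}

#' Simulate dynamic stretch-threshold observations
#'
#' Linear dynamic threshold data for TSRT estimation: threshold angles
#' `tsrt + slope * velocity + noise` at the given stretch velocities.
#'
#' @param tsrt true threshold angle at zero velocity (deg).
#' @param slope deg per (deg/s); typically negative.
#' @param velocities positive stretch velocities (deg/s).
#' @param noise_sd Gaussian noise SD on the angles (deg).
#' @param seed integer RNG seed.
#' @return data frame with `stretch_velocity` and `threshold_angle`.
#' @export
simulate_threshold_data <- function(tsrt, slope, velocities,
                                    noise_sd = 2, seed = 1) {
  set.seed(as.integer(seed))
  data.frame(
    stretch_velocity = velocities,
    threshold_angle = tsrt + slope * velocities +
      stats::rnorm(length(velocities), sd = noise_sd)
  )
}
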