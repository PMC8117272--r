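#' Read reach trials from a long-format CSV
#'
#' Two dialects are accepted, distinguished by the columns present.
#' The angle dialect has columns `participant_id, group, target,
#' trial_id, t, elbow_angle_deg` and optionally `speed`; if `speed` is
#' missing, a forearm tangential speed consistent with the angle
#' derivative is derived.  The landmark dialect has
#' `shoulder_x..shoulder_z, elbow_x..elbow_z, wrist_x..wrist_z` (cm)
#' instead of the angle, from which the elbow angle (3-point included
#' angle) and the wrist tangential speed are computed.  Rows with
#' missing mandatory values are skipped with a message.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz (default 120); used when the `t` column
#'   is absent and for derived speeds.
#' @param forearm_cm scale used when deriving speed from angle (cm).
#' @return list of `reach_recording` objects.
#' @export
read_trials <- function(path, fs = 120, forearm_cm = 25) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("schema error: empty trial file")
  landmark_cols <- as.vector(outer(c("shoulder", "elbow", "wrist"),
                                   c("x", "y", "z"), paste, sep = "_"))
  has_landmarks <- all(landmark_cols %in% names(df))
  has_angle <- "elbow_angle_deg" %in% names(df)
  key_cols <- c("participant_id", "target", "trial_id")
  if (!all(key_cols %in% names(df))) {
    stop("schema error: missing columns ",
         paste(setdiff(key_cols, names(df)), collapse = ", "))
  }
  if (!has_landmarks && !has_angle) {
    stop("schema error: need either elbow_angle_deg or landmark columns")
  }
  value_cols <- if (has_landmarks) landmark_cols else "elbow_angle_deg"
  bad <- !stats::complete.cases(df[, c(key_cols, value_cols)])
  if (any(bad)) {
    message(sum(bad), " malformed row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("schema error: no valid rows")
  if (!"group" %in% names(df)) df$group <- NA_character_

  split_keys <- interaction(df$participant_id, df$target, df$trial_id,
                            drop = TRUE)
  out <- lapply(split(df, split_keys), function(tr) {
    tr <- tr[order(if ("t" %in% names(tr)) tr$t else seq_len(nrow(tr))), ]
    this_fs <- if ("t" %in% names(tr) && nrow(tr) > 1) {
      1 / stats::median(diff(tr$t))
    } else {
      fs
    }
    if (has_landmarks) {
      sh <- as.matrix(tr[, paste0("shoulder_", c("x", "y", "z"))])
      el <- as.matrix(tr[, paste0("elbow_", c("x", "y", "z"))])
      wr <- as.matrix(tr[, paste0("wrist_", c("x", "y", "z"))])
      angle <- elbow_angle_series(sh, el, wr)
      speed <- tangential_speed(wr, this_fs)
    } else {
      angle <- tr$elbow_angle_deg
      speed <- if ("speed" %in% names(tr)) {
        tr$speed
      } else {
        abs(differentiate(angle, this_fs)) * pi / 180 * forearm_cm
      }
    }
    structure(list(
      participant_id = as.character(tr$participant_id[1]),
      target = as.character(tr$target[1]),
      trial_id = as.character(tr$trial_id[1]),
      group = as.character(tr$group[1]),
      fs = this_fs, t = (seq_along(angle) - 1) / this_fs,
      angle = angle, speed = speed,
      discarded = FALSE, discard_reason = NA_character_
    ), class = "reach_recording")
  })
  unname(out)
}

#' Write reach recordings to a long-format CSV
#'
#' Inverse of the angle dialect of [read_trials()].
#'
#' @param recordings list of `reach_recording` objects.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trials <- function(recordings, path) {
  rows <- lapply(recordings, function(r) {
    data.frame(participant_id = r$participant_id, group = r$group,
               target = r$target, trial_id = r$trial_id,
               t = r$t, elbow_angle_deg = r$angle, speed = r$speed,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted mixture models to JSON
#'
#' @param models list of `reach_gmm` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_models_json <- function(models, path) {
  enc <- lapply(models, function(m) {
    list(participant = m$participant_id, target = m$target, K = m$K,
         weights = m$weights, means = m$means,
         covariances = lapply(seq_len(m$K), function(k) m$covariances[, , k]),
         logL = m$log_likelihood, bic = m$bic, n_points = m$n_points,
         seed = m$seed)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read mixture models written by [write_models_json()]
#' @param path JSON path.
#' @return list of `reach_gmm` objects.
#' @export
read_models_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    K <- as.integer(m$K)
    means <- do.call(rbind, lapply(m$means, function(r) unlist(r, use.names = FALSE)))
    d <- ncol(means)
    covs <- array(0, c(d, d, K))
    for (k in seq_len(K)) {
      covs[, , k] <- do.call(rbind, lapply(m$covariances[[k]],
                                           function(r) unlist(r, use.names = FALSE)))
    }
    structure(list(weights = unlist(m$weights, use.names = FALSE),
                   means = means, covariances = covs, K = K,
                   log_likelihood = m$logL, bic = m$bic,
                   n_points = m$n_points,
                   seed = if (is.null(m$seed)) NA_integer_ else m$seed,
                   participant_id = m$participant, target = m$target),
              class = "reach_gmm")
  })
}

#' Pipeline configuration
#'
#' Collects and validates every tunable of the analysis pipeline.
#'
#' @param fs sampling rate (Hz).
#' @param cutoff,order zero-phase Butterworth settings.
#' @param frac,hold segmentation threshold fraction and hold time (s).
#' @param bandwidth_mult kernel-regression bandwidth multiplier.
#' @param kmin,kmax mixture order search range.
#' @param metrics distance metrics to compute.
#' @param kappa unscented-transform spread parameter.
#' @param leave_one_out leave-one-out scoring for control participants.
#' @param velocity_aggregate aggregation of the mean-velocity measure.
#' @param seed master seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(fs = 120, cutoff = 6, order = 3, frac = 0.1,
                       hold = 0.1, bandwidth_mult = 2, kmin = 2, kmax = 25,
                       metrics = c("HD", "BKLD", "logBKLD"), kappa = 1,
                       leave_one_out = TRUE,
                       velocity_aggregate = c("circular", "arithmetic"),
                       seed = 1) {
  velocity_aggregate <- match.arg(velocity_aggregate)
  metrics <- match.arg(metrics, c("HD", "BKLD", "logBKLD"), several.ok = TRUE)
  if (fs <= 0 || cutoff <= 0 || cutoff >= fs / 2) {
    stop("invalid fs/cutoff combination")
  }
  if (order < 1 || frac <= 0 || frac >= 1 || hold < 0) {
    stop("invalid filter/segmentation settings")
  }
  if (bandwidth_mult <= 0) stop("bandwidth_mult must be positive")
  if (kmin < 1 || kmax < kmin) stop("need 1 <= kmin <= kmax")
  structure(list(fs = fs, cutoff = cutoff, order = order, frac = frac,
                 hold = hold, bandwidth_mult = bandwidth_mult, kmin = kmin,
                 kmax = kmax, metrics = metrics, kappa = kappa,
                 leave_one_out = leave_one_out,
                 velocity_aggregate = velocity_aggregate,
                 seed = as.integer(seed)), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Segments every recording, builds one model input set per participant
#' and target, fits BIC-selected Gaussian mixtures, scores each stroke
#' participant's model against the control models of the same target
#' (and each control against the other controls, leave-one-out) with the
#' configured stochastic distances, and computes the kinematic
#' summaries.  All randomness derives from `config$seed`, so a rerun
#' with the same inputs and config reproduces the outputs exactly.
#'
#' @param recordings list of `reach_recording` objects (e.g. from
#'   [simulate_cohort()] or [read_trials()]).
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, `distances.csv`,
#'   `kinematics.csv`, `models.csv` and `provenance.json` are written.
#' @return list with data frames `models`, `distances`, `kinematics`,
#'   the fitted `gmms`, and `provenance`.
#' @export
run_pipeline <- function(recordings, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  # --- segment ---------------------------------------------------------
  n_discarded <- 0L
  trials <- list()
  for (r in recordings) {
    if (isTRUE(r$discarded)) { n_discarded <- n_discarded + 1L; next }
    tr <- tryCatch(
      segment_trial(r, cutoff = config$cutoff, order = config$order,
                    frac = config$frac, hold = config$hold),
      error = function(e) NULL)
    if (is.null(tr)) { n_discarded <- n_discarded + 1L; next }
    trials[[length(trials) + 1L]] <- tr
  }
  if (length(trials) == 0) stop("pipeline error at stage segment: no usable trials")
  if (n_discarded > 0) message(n_discarded, " recording(s) discarded")

  keys <- vapply(trials, function(tr) paste(tr$participant_id, tr$target, sep = "\r"), "")
  groups <- split(trials, keys)
  groups <- groups[order(names(groups))]

  # --- model fitting ---------------------------------------------------
  gmms <- vector("list", length(groups))
  model_rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    mset <- tryCatch(build_model_set(g, bandwidth_mult = config$bandwidth_mult),
                     error = function(e)
                       stop("pipeline error at stage normalize: ",
                            conditionMessage(e)))
    fit <- tryCatch(
      select_gmm(mset$points, kmin = config$kmin, kmax = config$kmax,
                 seed = config$seed + 131L * i,
                 participant_id = mset$participant_id, target = mset$target),
      error = function(e) stop("pipeline error at stage fit: ",
                               conditionMessage(e)))
    gmms[[i]] <- fit
    model_rows[[i]] <- data.frame(
      participant_id = fit$participant_id, target = fit$target,
      group = g[[1]]$group, K = fit$K, log_likelihood = fit$log_likelihood,
      bic = fit$bic, n_points = fit$n_points, stringsAsFactors = FALSE)
  }
  models_df <- do.call(rbind, model_rows)

  # --- distances -------------------------------------------------------
  dist_rows <- list()
  for (tgt in unique(models_df$target)) {
    idx <- which(models_df$target == tgt)
    ctrl_idx <- idx[models_df$group[idx] == "control"]
    refs <- gmms[ctrl_idx]
    if (length(refs) == 0) next
    for (i in idx) {
      is_control <- identical(models_df$group[i], "control")
      if (is_control && !config$leave_one_out && length(refs) < 2) next
      for (metric in config$metrics) {
        res <- tryCatch(
          suppressWarnings(nearest_neighbor_distance(
            gmms[[i]], refs, metric = metric, kappa = config$kappa)),
          error = function(e) NULL)
        if (is.null(res)) next
        dist_rows[[length(dist_rows) + 1L]] <- data.frame(
          participant_id = models_df$participant_id[i], target = tgt,
          group = models_df$group[i],
          comparison = if (is_control) "control-control" else "stroke-control",
          metric = metric, value = res$value,
          nearest_ref = res$nearest_ref_id, stringsAsFactors = FALSE)
      }
    }
  }
  distances_df <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame()

  # --- kinematics ------------------------------------------------------
  kin_rows <- lapply(groups, function(g) {
    s <- suppressMessages(
      summarize_participant_target(g, velocity_aggregate = config$velocity_aggregate))
    data.frame(participant_id = s$participant_id, target = s$target,
               group = g[[1]]$group, n_trials = s$n_trials,
               movement_time = s$movement_time, final_angle = s$final_angle,
               mean_velocity = s$mean_velocity,
               peak_velocity = s$peak_velocity,
               n_velocity_peaks = s$n_velocity_peaks,
               stringsAsFactors = FALSE)
  })
  kinematics_df <- do.call(rbind, kin_rows)
  rownames(models_df) <- rownames(kinematics_df) <- NULL

  provenance <- list(
    package = "reachdist",
    version = as.character(utils::packageVersion("reachdist")),
    config = unclass(config),
    n_recordings = length(recordings),
    n_trials_used = length(trials),
    n_discarded = n_discarded)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(distances_df, file.path(out_dir, "distances.csv"),
                     row.names = FALSE)
    utils::write.csv(kinematics_df, file.path(out_dir, "kinematics.csv"),
                     row.names = FALSE)
    utils::write.csv(models_df, file.path(out_dir, "models.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(models = models_df, distances = distances_df,
       kinematics = kinematics_df, gmms = gmms, provenance = provenance)
}
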