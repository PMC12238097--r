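# Outcome variables of an EQI contraction, computed over the segmented
# window [onset, offset] on the raw channels.

check_segment <- function(trial, segment) {
  stopifnot(inherits(segment, "eqi_segment"))
  validate_eqi_trial(trial)
  if (segment$offset_index > nrow(trial)) {
    abort("segment extends beyond trial")
  }
  invisible(TRUE)
}

#' Total contraction time
#'
#' Duration of the contraction window:
#' `(offset_index - onset_index) / sampling_rate` seconds.
#'
#' @param trial An EQI [eqi_trial()].
#' @param segment Its `eqi_segment`.
#' @return Seconds.
#' @export
total_time <- function(trial, segment) {
  check_segment(trial, segment)
  (segment$offset_index - segment$onset_index) / trial_meta(trial)$sampling_rate_hz
}

#' Torque impulse
#'
#' Area under the torque-time curve over the contraction window, by
#' composite trapezoid integration against the recorded time axis. Exact for
#' affine torque traces; for twice-differentiable traces the error is bounded
#' by `(h^2 / 12) * (b - a) * max|f''|` with `h` the sample period.
#'
#' @inheritParams total_time
#' @return Nm.s.
#' @export
torque_impulse <- function(trial, segment) {
  check_segment(trial, segment)
  idx <- segment$onset_index:segment$offset_index
  trapz_impulse(trial$time_s[idx], trial$torque_nm[idx])
}

# composite trapezoid rule (hand-written on purpose: it is the defined
# integration scheme for this outcome, and two lines long)
trapz_impulse <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}

#' Mean angular velocity
#'
#' Mean of the magnitude of the recorded velocity channel over the window.
#' The dynamometer records velocity as its own channel, so this is averaged
#' directly rather than derived as RoM/time; on monotone motion the two
#' coincide (a tested identity). Magnitude is used because the yield is
#' unidirectional by protocol.
#'
#' @inheritParams total_time
#' @return Degrees/second (non-negative).
#' @export
mean_angular_velocity <- function(trial, segment) {
  check_segment(trial, segment)
  idx <- segment$onset_index:segment$offset_index
  mean(abs(trial$velocity_deg_s[idx]))
}

#' Range of motion and its endpoints
#'
#' Start angle is the angle at the onset sample (apex of the concentric
#' push), final angle the angle at the offset sample, both read at the exact
#' samples with no local averaging. Total RoM is `start - final` under the
#' internal plantarflexion-positive convention, so it is non-negative on
#' valid EQI trials; a negative value flags inverted motion.
#'
#' @inheritParams total_time
#' @return Named list: `total_rom`, `start_angle`, `final_angle` (degrees)
#'   and `flags` (contains `"inverted_motion"` when RoM < 0).
#' @export
range_of_motion <- function(trial, segment) {
  check_segment(trial, segment)
  start <- trial$angle_deg[segment$onset_index]
  final <- trial$angle_deg[segment$offset_index]
  rom <- start - final
  list(total_rom = rom, start_angle = start, final_angle = final,
       flags = if (rom < 0) "inverted_motion" else character(0))
}

#' Outcome record for one trial
#'
#' All six per-contraction metrics as one analysis-table row.
#'
#' @inheritParams total_time
#' @return One-row tibble in the study-table layout (see
#'   [build_study_table()]).
#' @export
trial_outcomes <- function(trial, segment) {
  m <- trial_meta(trial)
  rom <- range_of_motion(trial, segment)
  tibble(
    subject_id = m$subject_id, sex = m$sex, leg = m$leg,
    load = m$load_condition, repetition = m$repetition,
    total_time_s = total_time(trial, segment),
    impulse_nms = torque_impulse(trial, segment),
    mean_velocity_deg_s = mean_angular_velocity(trial, segment),
    rom_deg = rom$total_rom,
    start_angle_deg = rom$start_angle,
    final_angle_deg = rom$final_angle
  )
}

#' Extract outcome records for a collection of trials
#'
#' Applies [trial_outcomes()] to every EQI trial, matching trials to
#' segments; a trial without a segment is an error naming the trial. Rows are
#' ordered by (subject, leg, load, repetition).
#'
#' @param trials List of EQI [eqi_trial()]s.
#' @param segments List of `eqi_segment`s, parallel to `trials`, or `NULL` to
#'   segment each trial with [segment_trial()] defaults.
#' @param ... Segmentation parameters forwarded to [segment_trial()] when
#'   `segments` is `NULL`.
#' @return Study table (tibble), one row per trial.
#' @export
extract_all <- function(trials, segments = NULL, ...) {
  if (is.null(segments)) {
    segments <- map(trials, segment_trial, ...)
  }
  if (length(segments) != length(trials)) {
    abort("trials and segments must have equal length")
  }
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    m <- trial_meta(trials[[i]])
    if (is.null(segments[[i]])) {
      abort(paste0("no segment for trial ", m$subject_id, "/", m$leg,
                   "/load", m$load_condition, "/rep", m$repetition))
    }
    rows[[i]] <- trial_outcomes(trials[[i]], segments[[i]])
  }
  build_study_table(rows)
}
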