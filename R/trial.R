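#' Construct a dynamometer trial
#'
#' A trial is one continuous recording from the dynamometer: three
#' synchronised channels (joint angle, angular velocity, torque) sampled at a
#' constant rate, plus the metadata needed to interpret them. Internally the
#' package uses a plantarflexion-positive sign convention with the neutral
#' ankle at 0 degrees: plantarflexed angles are positive, dorsiflexed angles
#' negative, and plantarflexion torque is positive. Under this convention the
#' start of an EQI contraction is a local *maximum* of the angle channel and
#' the yield proceeds downwards towards the dorsiflexion limit.
#'
#' @param time Numeric vector of sample times in seconds, uniformly spaced.
#' @param angle Joint angle in degrees, plantarflexion-positive.
#' @param velocity Angular velocity in degrees/second.
#' @param torque Joint torque in Nm, plantarflexion-positive.
#' @param subject_id Opaque subject identifier.
#' @param sex `"M"` or `"F"`.
#' @param leg `"left"` or `"right"`.
#' @param trial_type `"MVIC"` or `"EQI"`.
#' @param load_condition Load as percent of MVIC, 75 or 90 (EQI trials; `NA`
#'   for MVIC trials).
#' @param repetition Repetition number, 1-3.
#' @param prescribed_load Prescribed dynamometer torque in Nm (EQI trials).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param rom_pf Subject's maximal plantarflexion angle (deg, positive).
#' @param rom_df Subject's maximal dorsiflexion angle (deg, negative).
#' @param time_point `"pre"` or `"post"` for MVIC trials, `NA` otherwise.
#'
#' @return A tibble of class `eqi_trial` with columns `time_s`, `angle_deg`,
#'   `velocity_deg_s`, `torque_nm`; trial metadata is stored in the `meta`
#'   attribute (see [trial_meta()]).
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' tr <- eqi_trial(t, angle = 10 - 5 * t, velocity = rep(-5, length(t)),
#'                 torque = rep(100, length(t)), subject_id = "s1", sex = "M",
#'                 leg = "left", trial_type = "EQI", load_condition = 75,
#'                 repetition = 1, prescribed_load = 120,
#'                 rom_pf = 20, rom_df = -15)
#' trial_meta(tr)$prescribed_load_nm
eqi_trial <- function(time, angle, velocity, torque,
                      subject_id, sex, leg, trial_type,
                      load_condition = NA_real_, repetition = 1L,
                      prescribed_load = NA_real_, sampling_rate = 100,
                      rom_pf = NA_real_, rom_df = NA_real_,
                      time_point = NA_character_) {
  x <- tibble(
    time_s = as.numeric(time),
    angle_deg = as.numeric(angle),
    velocity_deg_s = as.numeric(velocity),
    torque_nm = as.numeric(torque)
  )
  meta <- list(
    subject_id = as.character(subject_id),
    sex = as.character(sex),
    leg = as.character(leg),
    trial_type = as.character(trial_type),
    load_condition = as.numeric(load_condition),
    repetition = as.integer(repetition),
    prescribed_load_nm = as.numeric(prescribed_load),
    sampling_rate_hz = as.numeric(sampling_rate),
    rom_pf_deg = as.numeric(rom_pf),
    rom_df_deg = as.numeric(rom_df),
    time_point = as.character(time_point)
  )
  attr(x, "meta") <- meta
  class(x) <- c("eqi_trial", class(x))
  validate_eqi_trial(x)
}

#' Trial metadata
#'
#' @param trial An [eqi_trial()].
#' @return Named list of trial metadata.
#' @export
trial_meta <- function(trial) {
  attr(trial, "meta")
}

#' Validate a dynamometer trial
#'
#' Checks the structural invariants every downstream operation relies on:
#' equal channel lengths of at least 2, finite values, a strictly increasing
#' time axis with constant step `1/sampling_rate` (to 1e-9 s), a positive
#' prescribed load on EQI trials, and `rom_pf > rom_df` when range-of-motion
#' limits are present. Gaps are a hard error: signals are analysed raw, so
#' missing samples are never interpolated.
#'
#' @param trial An [eqi_trial()].
#' @return The trial, invisibly unchanged, or an error naming the offending
#'   field.
#' @export
validate_eqi_trial <- function(trial) {
  m <- trial_meta(trial)
  if (is.null(m)) abort("trial has no metadata attribute; not an eqi_trial")
  need <- c("time_s", "angle_deg", "velocity_deg_s", "torque_nm")
  miss <- setdiff(need, names(trial))
  if (length(miss) > 0) {
    abort(paste0("trial is missing column(s): ", paste(miss, collapse = ", ")))
  }
  n <- nrow(trial)
  if (n < 2) abort("trial must have at least 2 samples")
  for (col in need) {
    if (anyNA(trial[[col]]) || any(!is.finite(trial[[col]]))) {
      abort(paste0("non-finite values in channel '", col, "'"))
    }
  }
  if (!is.finite(m$sampling_rate_hz) || m$sampling_rate_hz <= 0) {
    abort("sampling_rate_hz must be a positive number")
  }
  dt <- diff(trial$time_s)
  if (any(dt <= 0)) abort("time_s must be strictly increasing")
  step <- 1 / m$sampling_rate_hz
  if (any(abs(dt - step) > 1e-9)) {
    abort(paste0("time_s is not uniform at 1/", m$sampling_rate_hz,
                 " s; largest deviation ",
                 format(max(abs(dt - step)), digits = 3), " s"))
  }
  if (!m$trial_type %in% c("MVIC", "EQI")) {
    abort("trial_type must be 'MVIC' or 'EQI'")
  }
  if (m$trial_type == "EQI") {
    if (!is.finite(m$prescribed_load_nm) || m$prescribed_load_nm <= 0) {
      abort("EQI trial requires prescribed_load_nm > 0")
    }
  }
  if (is.finite(m$rom_pf_deg) && is.finite(m$rom_df_deg) &&
      m$rom_pf_deg <= m$rom_df_deg) {
    abort("rom_pf_deg must exceed rom_df_deg (plantarflexion-positive)")
  }
  invisible(trial)
}

#' @export
print.eqi_trial <- function(x, ...) {
  m <- trial_meta(x)
  cat(sprintf(
    "<eqi_trial> %s %s %s leg, %s%s rep %d: %d samples @ %g Hz (%.2f s)\n",
    m$subject_id, m$sex, m$leg, m$trial_type,
    if (is.finite(m$load_condition)) sprintf(" %g%%", m$load_condition) else "",
    m$repetition, nrow(x), m$sampling_rate_hz, nrow(x) / m$sampling_rate_hz
  ))
  NextMethod()
}

#' Diagnostic plot of a trial
#'
#' Angle, velocity and torque stacked on a shared time axis; if a segment is
#' supplied, the contraction window is shaded and the onset/offset marked.
#'
#' @param object An [eqi_trial()].
#' @param segment Optional [eqi_segment()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eqi_trial <- function(object, segment = NULL, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), -"time_s",
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel,
                         levels = c("angle_deg", "velocity_deg_s", "torque_nm"),
                         labels = c("angle (deg)", "velocity (deg/s)",
                                    "torque (Nm)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(segment)) {
    t0 <- object$time_s[segment$onset_index]
    t1 <- object$time_s[segment$offset_index]
    p <- p +
      ggplot2::annotate("rect", xmin = t0, xmax = t1, ymin = -Inf, ymax = Inf,
                        alpha = 0.15, fill = "steelblue") +
      ggplot2::geom_vline(xintercept = c(t0, t1), linetype = 2,
                          colour = "steelblue")
  }
  p
}
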