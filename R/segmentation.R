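# Segmentation of EQI trials: onset at the first confirmed local maximum of
# the angle channel, offset at end of RoM or at a sustained drop of torque
# below half the prescribed load. Signals are analysed raw (no filtering), so
# both rules carry explicit robustness parameters.

running_max <- function(x, half_width) {
  # centred running max with clipped edges, via shifted pmax (vectorised)
  n <- length(x)
  m <- x
  if (half_width >= 1) {
    for (k in seq_len(half_width)) {
      lag_k <- c(rep(-Inf, k), x[seq_len(n - k)])
      lead_k <- c(x[(k + 1):n], rep(-Inf, k))
      if (n <= k) lag_k <- lead_k <- rep(-Inf, n)
      m <- pmax(m, lag_k, lead_k)
    }
  }
  m
}

#' Detect the EQI contraction onset
#'
#' The contraction starts at the first local maximum of the angle channel:
#' the apex of the concentric push, i.e. the most plantarflexed position the
#' participant reaches before yielding. Because the signal is unfiltered, a
#' "local maximum" needs a neighbourhood and a confirmation: the onset is the
#' first sample `i` with `angle[i] >= angle[j]` for all `j` within
#' `window` seconds either side (ties resolve to the earliest index), such
#' that the angle subsequently falls at least `min_drop` degrees below
#' `angle[i]` before the end of the trial — ruling out plateau edges and the
#' rising flank itself. No onset is reported within the first `window`
#' seconds: a recording that starts mid-decline has no identifiable apex.
#'
#' @param trial An EQI [eqi_trial()].
#' @param window Half-width of the local-maximum neighbourhood, seconds
#'   (default 0.25).
#' @param min_drop Confirmation drop, degrees (default 1.0).
#' @return Onset sample index (1-based).
#' @export
detect_onset <- function(trial, window = 0.25, min_drop = 1.0) {
  validate_eqi_trial(trial)
  m <- trial_meta(trial)
  if (m$trial_type != "EQI") abort("detect_onset expects an EQI trial")
  fs <- m$sampling_rate_hz
  n <- nrow(trial)
  w <- as.integer(round(window * fs))
  if (n < 2 * w) {
    abort(sprintf("trial too short for onset detection: %d samples < 2*window (%d)",
                  n, 2L * w))
  }
  ang <- trial$angle_deg
  win_max <- running_max(ang, w)
  # smallest angle seen at-or-after each sample (suffix minimum)
  suf_min <- rev(cummin(rev(ang)))
  # a maximum cannot be identified before one full window has elapsed:
  # otherwise a recording that starts mid-decline would misread its first
  # sample as an apex
  ok <- (ang >= win_max) & (ang - suf_min >= min_drop) & (seq_along(ang) > w)
  idx <- which(ok)
  if (length(idx) == 0) {
    abort("no qualifying local maximum in angle channel (no onset found)",
          class = "eqi_no_onset")
  }
  idx[1]
}

#' Detect the EQI contraction offset
#'
#' The contraction ends at whichever of two rules fires first after the
#' onset: (1) *end of range of motion* — the angle reaches the subject's
#' maximal dorsiflexion limit to within `rom_tolerance` degrees; or (2)
#' *torque collapse* — torque stays below `half_load_fraction` of the
#' prescribed load continuously for at least `debounce` seconds (the offset
#' is the first sample of the sustained run; the debounce stops single-sample
#' noise from ending the contraction). A simultaneous firing resolves to
#' `end_of_rom`. If neither rule fires before the recording ends, the offset
#' is the last sample and the segment is flagged `open_ended`.
#'
#' @param trial An EQI [eqi_trial()].
#' @param onset Onset index from [detect_onset()].
#' @param rom_tolerance Degrees of slack on the dorsiflexion limit
#'   (default 0.5): exact equality with a calibrated limit never happens on
#'   sampled data.
#' @param half_load_fraction Fraction of the prescribed load defining torque
#'   collapse (default 0.5).
#' @param debounce Minimum sustained duration of the collapse, seconds
#'   (default 0.1, i.e. 10 samples at 100 Hz).
#' @return List with `offset_index`, `offset_reason` (`"end_of_rom"`,
#'   `"torque_below_half_load"` or `"open_ended"`) and `flags`.
#' @export
detect_offset <- function(trial, onset, rom_tolerance = 0.5,
                          half_load_fraction = 0.5, debounce = 0.1) {
  validate_eqi_trial(trial)
  m <- trial_meta(trial)
  n <- nrow(trial)
  if (!is.numeric(onset) || length(onset) != 1 || onset < 1 || onset >= n) {
    abort("onset must be a single index in [1, nrow(trial) - 1]")
  }
  onset <- as.integer(onset)
  fs <- m$sampling_rate_hz
  run_len <- as.integer(ceiling(debounce * fs))
  run_len <- max(run_len, 1L)

  post <- (onset + 1L):n  # strictly after the onset sample
  # rule 1: end of RoM
  i_rom <- NA_integer_
  if (is.finite(m$rom_df_deg)) {
    hit <- which(trial$angle_deg[post] <= m$rom_df_deg + rom_tolerance)
    if (length(hit) > 0) i_rom <- post[hit[1]]
  }
  # rule 2: sustained torque drop below half the prescribed load
  i_trq <- NA_integer_
  if (is.finite(m$prescribed_load_nm)) {
    thr <- half_load_fraction * m$prescribed_load_nm
    below <- trial$torque_nm[post] < thr
    if (any(below)) {
      r <- rle(below)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      good <- which(r$values & r$lengths >= run_len)
      if (length(good) > 0) i_trq <- post[starts[good[1]]]
    }
  }

  flags <- character(0)
  if (is.na(i_rom) && is.na(i_trq)) {
    return(list(offset_index = n, offset_reason = "open_ended",
                flags = "open_ended"))
  }
  if (!is.na(i_rom) && (is.na(i_trq) || i_rom <= i_trq)) {
    list(offset_index = i_rom, offset_reason = "end_of_rom", flags = flags)
  } else {
    list(offset_index = i_trq, offset_reason = "torque_below_half_load",
         flags = flags)
  }
}

#' Segment an EQI trial
#'
#' Runs [detect_onset()] and [detect_offset()] and packages the result with
#' the rule parameters used, so a segmentation is fully reproducible from its
#' report.
#'
#' @inheritParams detect_onset
#' @inheritParams detect_offset
#' @param min_duration Segments shorter than this (seconds) are flagged
#'   `short_segment` (default 1).
#' @return An `eqi_segment`: onset/offset indices and times, the rule that
#'   ended the contraction, quality flags, and the parameters used.
#' @export
segment_trial <- function(trial, window = 0.25, min_drop = 1.0,
                          rom_tolerance = 0.5, half_load_fraction = 0.5,
                          debounce = 0.1, min_duration = 1) {
  m <- trial_meta(trial)
  onset <- detect_onset(trial, window = window, min_drop = min_drop)
  off <- detect_offset(trial, onset, rom_tolerance = rom_tolerance,
                       half_load_fraction = half_load_fraction,
                       debounce = debounce)
  flags <- off$flags
  fs <- m$sampling_rate_hz
  if ((off$offset_index - onset) / fs < min_duration) {
    flags <- c(flags, "short_segment")
  }
  eqi_segment(
    onset_index = onset, offset_index = off$offset_index,
    offset_reason = off$offset_reason,
    prescribed_load = m$prescribed_load_nm, flags = flags,
    params = list(window = window, min_drop = min_drop,
                  rom_tolerance = rom_tolerance,
                  half_load_fraction = half_load_fraction,
                  debounce = debounce, min_duration = min_duration),
    trial_length = nrow(trial), sampling_rate = fs
  )
}

#' Construct a segment object
#'
#' @param onset_index,offset_index Sample indices (1-based),
#'   `onset_index < offset_index`.
#' @param offset_reason Which rule ended the contraction.
#' @param prescribed_load Prescribed load (Nm) the half-load rule used.
#' @param flags Character vector of quality flags.
#' @param params Rule parameters used.
#' @param trial_length,sampling_rate Length (samples) and rate (Hz) of the
#'   segmented trial.
#' @return An `eqi_segment` object.
#' @export
eqi_segment <- function(onset_index, offset_index, offset_reason,
                        prescribed_load = NA_real_, flags = character(0),
                        params = list(), trial_length = NA_integer_,
                        sampling_rate = 100) {
  onset_index <- as.integer(onset_index)
  offset_index <- as.integer(offset_index)
  if (is.na(onset_index) || is.na(offset_index) || onset_index < 1 ||
      offset_index <= onset_index) {
    abort("require 1 <= onset_index < offset_index")
  }
  if (is.finite(trial_length) && offset_index > trial_length) {
    abort("offset_index beyond end of trial")
  }
  structure(
    list(onset_index = onset_index, offset_index = offset_index,
         onset_time_s = (onset_index - 1) / sampling_rate,
         offset_time_s = (offset_index - 1) / sampling_rate,
         offset_reason = offset_reason, prescribed_load = prescribed_load,
         flags = flags, params = params, trial_length = trial_length,
         sampling_rate = sampling_rate, note = NULL, original = NULL),
    class = "eqi_segment"
  )
}

#' @export
print.eqi_segment <- function(x, ...) {
  cat(sprintf(
    "<eqi_segment> samples %d..%d (%.2f..%.2f s), reason: %s%s\n",
    x$onset_index, x$offset_index, x$onset_time_s, x$offset_time_s,
    x$offset_reason,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' Manually override a segment
#'
#' Programmatic replacement for visual inspection: shifts the onset and/or
#' offset, flags the segment `manual_override`, records an audit note, and
#' preserves the original segment in the result so the correction is
#' traceable.
#'
#' @param segment An `eqi_segment`.
#' @param onset_index,offset_index Replacement indices (either may be `NULL`
#'   to keep the detected value).
#' @param note Audit note explaining the correction.
#' @return The corrected `eqi_segment`.
#' @export
apply_override <- function(segment, onset_index = NULL, offset_index = NULL,
                           note = "") {
  stopifnot(inherits(segment, "eqi_segment"))
  new_on <- if (is.null(onset_index)) segment$onset_index else as.integer(onset_index)
  new_off <- if (is.null(offset_index)) segment$offset_index else as.integer(offset_index)
  if (new_on < 1 || (is.finite(segment$trial_length) && new_off > segment$trial_length)) {
    abort("override indices out of trial range")
  }
  if (new_off <= new_on) abort("override requires onset_index < offset_index")
  out <- segment
  out$onset_index <- new_on
  out$offset_index <- new_off
  out$onset_time_s <- (new_on - 1) / segment$sampling_rate
  out$offset_time_s <- (new_off - 1) / segment$sampling_rate
  out$flags <- union(segment$flags, "manual_override")
  out$note <- note
  out$original <- segment[c("onset_index", "offset_index", "offset_reason",
                            "flags")]
  out
}

#' Segmentation report
#'
#' Serialisable per-trial report: indices, times, rule fired, flags and the
#' parameters used, suitable for writing as JSON next to the study table.
#'
#' @param segment An `eqi_segment`.
#' @param trial Optionally, the segmented trial (adds its identity fields).
#' @return A named list (JSON-ready).
#' @export
segment_report <- function(segment, trial = NULL) {
  rep <- list(
    onset_index = segment$onset_index,
    offset_index = segment$offset_index,
    onset_time_s = segment$onset_time_s,
    offset_time_s = segment$offset_time_s,
    offset_reason = segment$offset_reason,
    flags = as.list(segment$flags),
    params = segment$params,
    note = segment$note,
    original = segment$original
  )
  if (!is.null(trial)) {
    m <- trial_meta(trial)
    rep <- c(list(subject_id = m$subject_id, leg = m$leg,
                  load_condition = m$load_condition,
                  repetition = m$repetition), rep)
  }
  rep
}

#' Extract the MVIC result from a set of repetitions
#'
#' Each MVIC repetition contributes its raw torque peak (maximum of the
#' unfiltered torque channel); the best repetition's peak is the dependent
#' variable.
#'
#' @param trials A list of 1-3 MVIC [eqi_trial()]s from the same subject,
#'   leg and time point.
#' @return One-row tibble: `subject_id`, `sex`, `leg`, `load`, `time_point`,
#'   `n_reps`, `peak_torques` (list column), `best_peak_nm`.
#' @export
extract_mvic <- function(trials) {
  if (inherits(trials, "eqi_trial")) trials <- list(trials)
  if (length(trials) < 1 || length(trials) > 3) {
    abort("extract_mvic expects 1-3 MVIC trials")
  }
  metas <- map(trials, trial_meta)
  types <- map_chr(metas, "trial_type")
  if (any(types != "MVIC")) abort("non-MVIC trial passed to extract_mvic")
  key <- map_chr(metas, ~ paste(.x$subject_id, .x$leg, .x$time_point, sep = "/"))
  if (length(unique(key)) != 1) {
    abort("MVIC trials must share subject, leg and time point")
  }
  peaks <- map_dbl(trials, ~ max(.x$torque_nm))
  if (any(peaks <= 0)) abort("non-positive MVIC peak torque")
  m <- metas[[1]]
  tibble(
    subject_id = m$subject_id, sex = m$sex, leg = m$leg,
    load = m$load_condition, time_point = m$time_point,
    n_reps = length(peaks), peak_torques = list(peaks),
    best_peak_nm = max(peaks)
  )
}
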