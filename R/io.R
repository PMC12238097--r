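#' Read a trial CSV
#'
#' Trial files are plain CSV with a `#`-prefixed metadata header, one file per
#' trial: lines of the form `# key: value` for the metadata keys
#' `subject_id`, `sex`, `leg`, `trial_type`, `load_condition`, `repetition`,
#' `prescribed_load_nm`, `sampling_rate_hz`, `rom_pf_deg`, `rom_df_deg`
#' (and, for MVIC trials, `time_point`), followed by the data columns
#' `time_s,angle_deg,velocity_deg_s,torque_nm`. UTF-8, `.` decimal separator.
#' The file is validated on read; any violation of the trial invariants
#' (missing column, non-uniform time axis, length mismatch, non-finite
#' samples) is a format error naming the offending field.
#'
#' @param path Path to a trial CSV.
#' @return An [eqi_trial()].
#' @seealso [write_trial()] for the lossless inverse.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || !identical(hdr, seq_along(hdr))) {
    abort(paste0(path, ": expected a leading '#' metadata header block"))
  }
  kv <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  need <- c("subject_id", "sex", "leg", "trial_type", "repetition",
            "sampling_rate_hz")
  miss <- setdiff(need, names(kv))
  if (length(miss) > 0) {
    abort(paste0(path, ": header missing key(s): ", paste(miss, collapse = ", ")))
  }
  num <- function(key) {
    if (is.null(kv[[key]]) || kv[[key]] %in% c("", "NA")) return(NA_real_)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) abort(paste0(path, ": header key '", key, "' is not numeric"))
    v
  }
  body <- lines[-hdr]
  dat <- readr::read_csv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  cols <- c("time_s", "angle_deg", "velocity_deg_s", "torque_nm")
  miss <- setdiff(cols, names(dat))
  if (length(miss) > 0) {
    abort(paste0(path, ": missing data column(s): ", paste(miss, collapse = ", ")))
  }
  tryCatch(
    eqi_trial(
      time = dat$time_s, angle = dat$angle_deg,
      velocity = dat$velocity_deg_s, torque = dat$torque_nm,
      subject_id = kv$subject_id, sex = kv$sex, leg = kv$leg,
      trial_type = kv$trial_type,
      load_condition = num("load_condition"),
      repetition = as.integer(num("repetition")),
      prescribed_load = num("prescribed_load_nm"),
      sampling_rate = num("sampling_rate_hz"),
      rom_pf = num("rom_pf_deg"), rom_df = num("rom_df_deg"),
      time_point = if (is.null(kv$time_point)) NA_character_ else kv$time_point
    ),
    error = function(e) abort(paste0(path, ": ", conditionMessage(e)))
  )
}

#' Write a trial CSV
#'
#' Inverse of [read_trial()]: the written file round-trips losslessly at
#' 1e-9 precision (channels are written with 15 significant digits). The
#' trial is validated before writing, so e.g. a NaN in the torque channel is
#' an error rather than a corrupt file.
#'
#' @param trial An [eqi_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_eqi_trial(trial)
  m <- trial_meta(trial)
  fmt <- function(x) {
    ifelse(is.na(x), "NA", vapply(x, format, "", digits = 15))
  }
  hdr <- c(
    paste0("# subject_id: ", m$subject_id),
    paste0("# sex: ", m$sex),
    paste0("# leg: ", m$leg),
    paste0("# trial_type: ", m$trial_type),
    paste0("# load_condition: ", fmt(m$load_condition)),
    paste0("# repetition: ", m$repetition),
    paste0("# prescribed_load_nm: ", fmt(m$prescribed_load_nm)),
    paste0("# sampling_rate_hz: ", fmt(m$sampling_rate_hz)),
    paste0("# rom_pf_deg: ", fmt(m$rom_pf_deg)),
    paste0("# rom_df_deg: ", fmt(m$rom_df_deg)),
    paste0("# time_point: ", ifelse(is.na(m$time_point), "NA", m$time_point))
  )
  rows <- paste(fmt(trial$time_s), fmt(trial$angle_deg),
                fmt(trial$velocity_deg_s), fmt(trial$torque_nm), sep = ",")
  writeLines(c(hdr, "time_s,angle_deg,velocity_deg_s,torque_nm", rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' Assemble the long-format study table
#'
#' Binds per-trial outcome records (rows as produced by [trial_outcomes()] /
#' [extract_all()]) into the analysis table, one row per
#' (subject, leg, load, repetition), with a stable column order. Duplicate
#' keys are an error listing the offending combinations.
#'
#' @param records A data frame of outcome records, or a list of one-row
#'   records to bind.
#' @return A tibble with columns `subject_id`, `sex`, `leg`, `load`,
#'   `repetition`, `total_time_s`, `impulse_nms`, `mean_velocity_deg_s`,
#'   `rom_deg`, `start_angle_deg`, `final_angle_deg`.
#' @export
build_study_table <- function(records) {
  if (is.data.frame(records)) tab <- as_tibble(records)
  else tab <- dplyr::bind_rows(records)
  cols <- c("subject_id", "sex", "leg", "load", "repetition", "total_time_s",
            "impulse_nms", "mean_velocity_deg_s", "rom_deg",
            "start_angle_deg", "final_angle_deg")
  miss <- setdiff(cols, names(tab))
  if (length(miss) > 0) {
    abort(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  }
  key <- paste(tab$subject_id, tab$leg, tab$load, tab$repetition, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    abort(paste0("duplicate (subject, leg, load, repetition) key(s): ",
                 paste(dup, collapse = "; ")))
  }
  tab <- tab[cols]
  dplyr::arrange(tab, .data$subject_id, .data$leg, .data$load, .data$repetition)
}

#' Read / write the study table CSV
#'
#' Plain CSV in the column order documented in [build_study_table()].
#'
#' @param path File path.
#' @return `read_study_table()` returns the validated tibble;
#'   `write_study_table()` returns `path` invisibly.
#' @export
read_study_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  build_study_table(tab)
}

#' @rdname read_study_table
#' @param table Study table as returned by [build_study_table()].
#' @export
write_study_table <- function(table, path) {
  table <- build_study_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
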