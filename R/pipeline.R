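# Orchestration: extract -> tabulate -> analyze -> report, with a single
# config object, JSON reports and a reproducibility contract (every output
# directory carries the config and seed that produced it).

#' Pipeline run configuration
#'
#' All analysis parameters that the underlying methods leave open live here,
#' with their documented defaults: the segmentation robustness parameters,
#' the Cohen's d denominator, and the seed. A serialised copy is written
#' into every output directory so a run is reconstructible from its outputs.
#'
#' @param window,min_drop Onset rule parameters (see [detect_onset()]).
#' @param rom_tolerance,half_load_fraction,debounce Offset rule parameters
#'   (see [detect_offset()]).
#' @param min_duration Short-segment flag threshold, seconds.
#' @param d_denominator `"average"` or `"pooled"` (see [cohens_d_avgsd()]).
#' @param seed Integer seed used by any simulation step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window = 0.25, min_drop = 1.0, rom_tolerance = 0.5,
                       half_load_fraction = 0.5, debounce = 0.1,
                       min_duration = 1, d_denominator = "average",
                       seed = 1L) {
  stopifnot(window > 0, min_drop >= 0, rom_tolerance >= 0,
            half_load_fraction > 0, half_load_fraction < 1, debounce >= 0,
            d_denominator %in% c("average", "pooled"))
  structure(list(window = window, min_drop = min_drop,
                 rom_tolerance = rom_tolerance,
                 half_load_fraction = half_load_fraction, debounce = debounce,
                 min_duration = min_duration, d_denominator = d_denominator,
                 seed = as.integer(seed)),
            class = c("run_config", "list"))
}

#' Hash of a configuration
#'
#' Stable hash of any config object; changes whenever any parameter changes.
#'
#' @param config A `run_config` or [sim_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Extract outcomes from a directory (or list) of trials
#'
#' Reads every trial, segments the EQI trials with the config's rule
#' parameters, computes the outcome records and the MVIC results, and
#' (optionally) writes the study table, the MVIC table, per-trial
#' segmentation reports and the config copy into `out_dir`. Any unreadable
#' trial aborts with the offending file named.
#'
#' @param input A directory containing trial CSVs, or a list of
#'   [eqi_trial()] objects.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List: `study_table` (EQI outcome rows), `mvic_table` (one row per
#'   subject/leg/time point), `segments`, `reports`.
#' @export
run_extract <- function(input, config = run_config(), out_dir = NULL) {
  if (is.character(input)) {
    paths <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    if (length(paths) == 0) abort(paste0("no trial CSVs found in ", input))
    trials <- vector("list", length(paths))
    fails <- character(0)
    msgs <- character(0)
    for (i in seq_along(paths)) {
      trials[[i]] <- tryCatch(read_trial(paths[i]), error = function(e) {
        fails <<- c(fails, paths[i])
        msgs <<- c(msgs, conditionMessage(e))
        NULL
      })
    }
    if (length(fails) > 0) {
      abort(paste0("unreadable trial file(s):\n  ",
                   paste(msgs, collapse = "\n  ")))
    }
  } else {
    trials <- input
  }
  is_eqi <- map_chr(trials, ~ trial_meta(.x)$trial_type) == "EQI"
  eqi <- trials[is_eqi]
  mvic <- trials[!is_eqi]

  segments <- map(eqi, segment_trial,
                  window = config$window, min_drop = config$min_drop,
                  rom_tolerance = config$rom_tolerance,
                  half_load_fraction = config$half_load_fraction,
                  debounce = config$debounce,
                  min_duration = config$min_duration)
  study <- extract_all(eqi, segments)
  reports <- map2(segments, eqi, segment_report)

  mvic_table <- NULL
  if (length(mvic) > 0) {
    key <- map_chr(mvic, function(tr) {
      m <- trial_meta(tr)
      paste(m$subject_id, m$leg, m$time_point, sep = "/")
    })
    mvic_table <- split(mvic, key) %>%
      map(extract_mvic) %>%
      dplyr::bind_rows() %>%
      dplyr::arrange(.data$subject_id, .data$leg, .data$time_point)
    # the leg's load condition comes from that leg's EQI trials
    leg_load <- dplyr::distinct(study, .data$subject_id, .data$leg, .data$load)
    mvic_table <- mvic_table %>%
      select(-"load") %>%
      left_join(leg_load, by = c("subject_id", "leg"))
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_study_table(study, file.path(out_dir, "study_table.csv"))
    if (!is.null(mvic_table)) {
      readr::write_csv(select(mvic_table, -"peak_torques"),
                       file.path(out_dir, "mvic_table.csv"), progress = FALSE)
    }
    jsonlite::write_json(reports, file.path(out_dir, "segmentation.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(c(unclass(config), list(hash = config_hash(config))),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(study_table = study, mvic_table = mvic_table, segments = segments,
       reports = reports)
}

# One serialisable report: effects + sphericity + repetition post hocs +
# sex-by-load estimated marginal means (pooled across repetitions).
anova_report <- function(data, dv, within, between, subject,
                         posthoc_factor = NULL, emm_by = NULL) {
  fit <- mixed_rm_anova(data, dv = dv, within = within, between = between,
                        subject = subject)
  rep <- list(dv = dv, effects = tidy(fit), mauchly = fit$mauchly)
  if (!is.null(posthoc_factor) &&
      length(unique(data[[posthoc_factor]])) >= 2) {
    rep$posthoc <- bonferroni_posthoc(data, factor = posthoc_factor, dv = dv,
                                      subject = subject)
  }
  if (!is.null(emm_by)) {
    rep$emm <- estimated_marginal_means(data, by = emm_by, dv = dv,
                                        subject = subject, between = between)
  }
  rep$fit <- fit
  rep
}

#' Fit the full statistical battery
#'
#' One mixed repeated-measures model per EQI outcome (within: load,
#' repetition; between: sex) — total time, torque impulse, mean angular
#' velocity, total RoM, start angle and final angle — plus the MVIC model
#' (within: time, load; between: sex): seven reports, each with the effect
#' table, Mauchly tests, Bonferroni post hocs across repetitions and
#' sex-by-load estimated marginal means pooled across repetitions. JSON and
#' human-readable text reports are written when `out_dir` is given.
#'
#' @param study_table EQI study table (see [build_study_table()]).
#' @param mvic_table MVIC table from [run_extract()] (columns `subject_id`,
#'   `sex`, `leg`, `load`, `time_point`, `best_peak_nm`), or `NULL` to skip
#'   the MVIC model.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return Named list of reports (`total_time_s`, `impulse_nms`,
#'   `mean_velocity_deg_s`, `rom_deg`, `start_angle_deg`, `final_angle_deg`,
#'   and `mvic` when an MVIC table is supplied).
#' @export
run_stats <- function(study_table, mvic_table = NULL, config = run_config(),
                      out_dir = NULL) {
  study_table <- build_study_table(study_table)
  dvs <- c("total_time_s", "impulse_nms", "mean_velocity_deg_s", "rom_deg",
           "start_angle_deg", "final_angle_deg")
  reports <- list()
  for (dv in dvs) {
    reports[[dv]] <- anova_report(
      study_table, dv = dv, within = c("load", "repetition"), between = "sex",
      subject = "subject_id", posthoc_factor = "repetition",
      emm_by = c("sex", "load")
    )
  }
  if (!is.null(mvic_table)) {
    need <- c("subject_id", "sex", "load", "time_point", "best_peak_nm")
    miss <- setdiff(need, names(mvic_table))
    if (length(miss) > 0) {
      abort(paste0("mvic_table missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    reports$mvic <- anova_report(
      mvic_table, dv = "best_peak_nm", within = c("time_point", "load"),
      between = "sex", subject = "subject_id",
      emm_by = c("sex", "load")
    )
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    json <- map(reports, function(r) {
      r$fit <- NULL
      r
    })
    jsonlite::write_json(json, file.path(out_dir, "anova_reports.json"),
                         auto_unbox = TRUE, digits = NA)
    txt <- character(0)
    for (nm in names(reports)) {
      txt <- c(txt, paste0("==== ", nm, " ===="),
               utils::capture.output(print(reports[[nm]]$fit)), "")
    }
    writeLines(txt, file.path(out_dir, "anova_reports.txt"))
    jsonlite::write_json(c(unclass(config), list(hash = config_hash(config))),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  reports
}

#' Simulate, extract and analyse in one call
#'
#' End-to-end reproducible run: simulates a study from `sim_cfg` (seeded),
#' extracts outcomes with `config`'s segmentation parameters, fits the
#' statistical battery, and writes everything plus a provenance record
#' (package version, config hashes, seed) under `out_dir`. Rerunning with
#' the same configs reproduces the outputs byte for byte.
#'
#' @param sim_cfg A [sim_config()].
#' @param config A [run_config()].
#' @param out_dir Output directory (required: this is the reproduction
#'   entry point).
#' @return List with `extract` (tables) and `reports` (model reports),
#'   invisibly.
#' @export
run_all <- function(sim_cfg = sim_config(), config = run_config(),
                    out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  trial_dir <- file.path(out_dir, "trials")
  sim <- simulate_study(sim_cfg, dir = trial_dir)
  ext <- run_extract(trial_dir, config = config,
                     out_dir = file.path(out_dir, "extract"))
  reports <- run_stats(ext$study_table, ext$mvic_table, config = config,
                       out_dir = file.path(out_dir, "stats"))
  prov <- list(
    package = "eqitools",
    version = as.character(utils::packageVersion("eqitools")),
    sim_config_hash = config_hash(sim_cfg),
    run_config_hash = config_hash(config),
    seed = sim_cfg$seed,
    n_trials = length(sim$trials)
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(extract = ext, reports = reports))
}
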