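# Synthetic dynamometer study generator. The mechanism is deliberately
# minimal: isometric capacity = MVIC x force-length factor x (1 - fatigue),
# with capacity growing linearly towards dorsiflexion, fatigue integrating
# normalised torque-time, and the joint yielding dorsally in proportion to
# the capacity deficit. That is the smallest model that reproduces the
# phenomenology of an EQI bout: a concentric push to an apex that is more
# plantarflexed at lower loads, alternating near-isometric holds and slow
# yields, longer/larger contractions at 75% than 90% MVIC, and a decline
# across repetitions through incomplete recovery.

#' Simulator configuration
#'
#' Returns the default simulator configuration, optionally overriding fields.
#' Defaults emulate the study population and protocol the package targets:
#' 20 subjects (9 men, 11 women), two legs with the 75%/90% load assignment
#' counterbalanced, three 5-s MVIC repetitions before and after three EQI
#' contractions per leg, all sampled at 100 Hz. Magnitudes are calibrated so
#' that mean MVIC torque is about 200 Nm in men and 157 Nm in women (hence
#' mean prescribed loads near 132 and 161 Nm), EQI durations are tens of
#' seconds, and ranges of motion sit near 20 degrees at 75% load and 15
#' degrees at 90%.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `sim_config`.
#'
#' @section Fields:
#' \describe{
#'   \item{n_men, n_women}{cohort composition (9, 11).}
#'   \item{mvic_mean_men, mvic_mean_women}{true neutral-angle MVIC means, Nm
#'     (200, 157).}
#'   \item{mvic_between_subject_cv}{between-subject lognormal CV of true
#'     MVIC (0.17).}
#'   \item{load_fractions}{EQI loads as fractions of measured MVIC
#'     (0.75, 0.90).}
#'   \item{force_length_gain}{per-degree increase of capacity towards
#'     dorsiflexion (0.024 /deg).}
#'   \item{fatigue_rate}{capacity fraction lost per second per unit
#'     normalised torque (0.018 /s).}
#'   \item{recovery_fraction_between_reps}{fraction of newly acquired
#'     fatigue recovered in the 2-min rest (0.85).}
#'   \item{yield_gain}{dorsal drift rate per Nm of capacity deficit
#'     (2 deg/s/Nm).}
#'   \item{concentric_capacity_factor}{concentric-to-isometric capacity
#'     ratio (0.93): the push stops short of where an isometric hold could be
#'     kept, creating the initial hold.}
#'   \item{push_velocity}{concentric push speed (15 deg/s).}
#'   \item{rom_pf_mean, rom_pf_sd}{plantarflexion limit distribution
#'     (20, 3 deg).}
#'   \item{rom_df_mean_men, rom_df_mean_women, rom_df_sd}{dorsiflexion limit
#'     distribution (-12, -15, 2.5 deg); women reach further into
#'     dorsiflexion, which drives the sex effect on the final angle.}
#'   \item{subject_cv_fl_gain, subject_cv_fatigue}{between-subject lognormal
#'     CVs of the force-length gain and fatigue rate (0.10, 0.15).}
#'   \item{measurement_noise_cv}{bounded multiplicative noise on the torque
#'     and velocity channels: each sample is scaled by `1 + cv * U`,
#'     `U ~ Uniform(-1, 1)` (0.02).}
#'   \item{angle_resolution_deg}{encoder quantisation of the angle channel
#'     (0.01 deg); 0 disables it.}
#'   \item{giveup_prob, giveup_time_mean, giveup_time_sd}{optional stochastic
#'     give-up event: with this probability the voluntary drive collapses
#'     after roughly that many seconds of contraction, exercising the
#'     half-load offset rule (default off: prob 0).}
#'   \item{post_mvic_fatigue}{residual capacity deficit at the post-EQI MVIC
#'     (0: recovery for a maximal neutral-angle effort is complete, matching
#'     the absent time effect such protocols show).}
#'   \item{sampling_rate}{Hz (100).}
#'   \item{mvic_plateau_s, mvic_ramp_s}{MVIC plateau and ramp durations
#'     (5, 0.8 s).}
#'   \item{t_max, tail_s}{simulation cap and post-contraction tail (240,
#'     1.5 s).}
#'   \item{seed}{integer seed; fully determines the output.}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_men = 9L, n_women = 11L,
    mvic_mean_men = 200, mvic_mean_women = 157,
    mvic_between_subject_cv = 0.17,
    load_fractions = c(0.75, 0.90),
    force_length_gain = 0.024,
    fatigue_rate = 0.018,
    recovery_fraction_between_reps = 0.85,
    yield_gain = 2,
    concentric_capacity_factor = 0.93,
    push_velocity = 15,
    rom_pf_mean = 20, rom_pf_sd = 3,
    rom_df_mean_men = -12, rom_df_mean_women = -15, rom_df_sd = 2.5,
    subject_cv_fl_gain = 0.10, subject_cv_fatigue = 0.15,
    measurement_noise_cv = 0.02,
    angle_resolution_deg = 0.01,
    giveup_prob = 0, giveup_time_mean = 15, giveup_time_sd = 4,
    post_mvic_fatigue = 0,
    sampling_rate = 100,
    mvic_plateau_s = 5, mvic_ramp_s = 0.8,
    t_max = 240, tail_s = 1.5,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("unknown sim_config field(s): ", paste(bad, collapse = ", ")))
  }
  cfg <- modifyList(cfg, over)
  for (fld in c("force_length_gain", "fatigue_rate", "yield_gain",
                "measurement_noise_cv", "angle_resolution_deg",
                "mvic_between_subject_cv")) {
    if (cfg[[fld]] < 0) abort(paste0(fld, " must be >= 0"))
  }
  if (any(cfg$load_fractions <= 0 | cfg$load_fractions >= 1)) {
    abort("load_fractions must lie in (0, 1)")
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Read / write a simulator configuration as YAML
#'
#' The YAML file holds exactly the [sim_config()] fields; unknown keys are an
#' error, and omitted keys take their defaults, so a config file written by
#' one package version remains explicit about what it sets.
#'
#' @param path YAML file path.
#' @return `read_sim_config()` returns a validated [sim_config()];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$load_fractions)) {
    vals$load_fractions <- as.numeric(vals$load_fractions)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# bounded multiplicative channel noise: x * (1 + cv * U), U ~ Unif(-1, 1)
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  x * (1 + cv * stats::runif(length(x), -1, 1))
}

quantise <- function(x, res) {
  if (res <= 0) return(x)
  round(x / res) * res
}

#' Draw one subject's true parameters
#'
#' True MVIC is lognormal around the sex mean; range-of-motion limits are
#' normal (dorsiflexion limit further from neutral in women); the
#' force-length gain and fatigue rate vary lognormally between subjects.
#' Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param sex `"M"` or `"F"`.
#' @param seed Optional integer; when given, draws are made under this seed
#'   without disturbing the caller's RNG state.
#' @return A list of subject parameters (`mvic`, `rom_pf`, `rom_df`,
#'   `fl_gain`, `fatigue_rate`, `sex`).
#' @export
simulate_subject <- function(config, sex = c("M", "F"), seed = NULL) {
  sex <- match.arg(sex)
  draw <- function() {
    mvic_mean <- if (sex == "M") config$mvic_mean_men else config$mvic_mean_women
    rom_df_mean <- if (sex == "M") config$rom_df_mean_men else
      config$rom_df_mean_women
    list(
      sex = sex,
      mvic = rlnorm_mean_cv(1, mvic_mean, config$mvic_between_subject_cv),
      rom_pf = max(10, stats::rnorm(1, config$rom_pf_mean, config$rom_pf_sd)),
      rom_df = min(-6, stats::rnorm(1, rom_df_mean, config$rom_df_sd)),
      fl_gain = rlnorm_mean_cv(1, config$force_length_gain,
                               config$subject_cv_fl_gain),
      fatigue_rate = rlnorm_mean_cv(1, config$fatigue_rate,
                                    config$subject_cv_fatigue)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate one EQI contraction
#'
#' Forward-simulates the contraction at the sampling rate (see the package
#' vignette for the mechanism), then applies the measurement model: bounded
#' multiplicative noise on torque and velocity, encoder quantisation on the
#' angle. Returns both the recorded trial and the ground-truth event log used
#' as an oracle in tests.
#'
#' @param subject A subject from [simulate_subject()].
#' @param load_fraction Load as a fraction of `prescribed_from` (e.g. 0.75).
#' @param rep_index Repetition number 1-3.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (see [simulate_subject()]).
#' @param fatigue0 Capacity deficit carried into this repetition.
#' @param prescribed_from Torque the load prescription is based on; defaults
#'   to the subject's true MVIC (in a full study it is the measured pre-EQI
#'   best peak).
#' @param subject_id,leg Metadata for the emitted trial.
#' @param giveup_time Seconds of contraction after which the voluntary drive
#'   collapses (`Inf` = never; the default draws it from the config's
#'   stochastic give-up model).
#' @param keep_capacity Also return the per-sample true capacity trajectory
#'   in `truth$capacity` (off by default to keep truth logs small).
#' @return List with `trial` (an [eqi_trial()]) and `truth` (apex index/
#'   time/angle, hold/yield phase boundaries, end index/reason, fatigue
#'   trajectory endpoints, true capacities).
#' @export
simulate_eqi_trial <- function(subject, load_fraction, rep_index, config,
                               seed = NULL, fatigue0 = 0,
                               prescribed_from = NULL,
                               subject_id = "sim", leg = "left",
                               giveup_time = NULL, keep_capacity = FALSE) {
  run <- function() {
    if (is.null(prescribed_from)) prescribed_from <- subject$mvic
    load <- load_fraction * prescribed_from
    if (is.null(giveup_time)) {
      giveup_time <- if (config$giveup_prob > 0 &&
                         stats::runif(1) < config$giveup_prob) {
        max(3, stats::rnorm(1, config$giveup_time_mean, config$giveup_time_sd))
      } else {
        Inf
      }
    }
    dt <- 1 / config$sampling_rate
    core <- sim_eqi_core(
      dt = dt, rom_pf = subject$rom_pf, rom_df = subject$rom_df,
      mvic = subject$mvic, load = load, fl_gain = subject$fl_gain,
      fatigue_rate = subject$fatigue_rate, yield_gain = config$yield_gain,
      con_factor = config$concentric_capacity_factor,
      push_v = config$push_velocity, f0 = fatigue0,
      giveup_time = giveup_time, t_max = config$t_max, tail_s = config$tail_s
    )
    if (isTRUE(core$infeasible)) {
      abort("infeasible load: exceeds the subject's capacity at every angle",
            class = "eqi_infeasible_load")
    }
    n <- length(core$theta)
    cv <- config$measurement_noise_cv
    trial <- eqi_trial(
      time = (seq_len(n) - 1) * dt,
      angle = quantise(core$theta, config$angle_resolution_deg),
      velocity = mult_noise(core$velocity, cv),
      torque = mult_noise(core$torque, cv),
      subject_id = subject_id, sex = subject$sex, leg = leg,
      trial_type = "EQI", load_condition = 100 * load_fraction,
      repetition = rep_index, prescribed_load = load,
      sampling_rate = config$sampling_rate,
      rom_pf = subject$rom_pf, rom_df = subject$rom_df
    )
    apex <- core$apex_index
    # phase log after the apex, from the true velocity: hold = |v| below
    # 0.1 deg/s. The first phase after the apex is always a hold (the yield
    # velocity grows continuously from zero).
    v_post <- core$velocity[apex:core$end_index]
    r <- rle(abs(v_post) < 0.1)
    ends <- cumsum(r$lengths)
    phases <- tibble(
      phase = ifelse(r$values, "hold", "yield"),
      start_index = apex + c(0L, ends[-length(ends)]),
      end_index = apex + ends - 1L
    )
    truth <- list(
      subject_id = subject_id, leg = leg,
      load_fraction = load_fraction, rep_index = rep_index,
      prescribed_load = load, true_mvic = subject$mvic,
      apex_index = apex, apex_time = (apex - 1) * dt,
      apex_angle = core$theta[apex],
      end_index = core$end_index, end_time = (core$end_index - 1) * dt,
      end_reason = core$end_reason, end_angle = core$theta[core$end_index],
      f_start = fatigue0, f_end = core$f_end,
      scheduled_duration = (core$end_index - apex) * dt,
      phases = phases
    )
    if (keep_capacity) truth$capacity <- core$capacity
    list(trial = trial, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate one MVIC repetition
#'
#' A maximal isometric effort at the neutral ankle: torque ramps up over
#' `mvic_ramp_s`, plateaus at the subject's current neutral-angle capacity
#' `mvic * (1 - fatigue_state)` for `mvic_plateau_s`, and releases; angle
#' and velocity are zero throughout. The torque channel gets the bounded
#' multiplicative measurement noise, so the recorded peak lies within
#' `measurement_noise_cv` of the true capacity.
#'
#' @inheritParams simulate_eqi_trial
#' @param fatigue_state Capacity deficit at this effort (0 = fresh).
#' @param time_point `"pre"` or `"post"`.
#' @param rep_index Repetition number 1-3.
#' @return An MVIC [eqi_trial()] with the true capacity in
#'   `attr(, "true_capacity")`.
#' @export
simulate_mvic_trial <- function(subject, fatigue_state = 0, config = sim_config(),
                                seed = NULL, rep_index = 1L,
                                time_point = "pre",
                                subject_id = "sim", leg = "left") {
  run <- function() {
    dt <- 1 / config$sampling_rate
    ramp_n <- round(config$mvic_ramp_s / dt)
    plat_n <- round(config$mvic_plateau_s / dt)
    peak <- subject$mvic * (1 - fatigue_state)
    shape <- c(sin(seq(0, pi / 2, length.out = ramp_n))^2,
               rep(1, plat_n),
               rev(sin(seq(0, pi / 2, length.out = ramp_n))^2))
    n <- length(shape)
    trial <- eqi_trial(
      time = (seq_len(n) - 1) * dt,
      angle = rep(0, n), velocity = rep(0, n),
      torque = mult_noise(peak * shape, config$measurement_noise_cv),
      subject_id = subject_id, sex = subject$sex, leg = leg,
      trial_type = "MVIC", repetition = rep_index,
      sampling_rate = config$sampling_rate,
      rom_pf = subject$rom_pf, rom_df = subject$rom_df,
      time_point = time_point
    )
    attr(trial, "true_capacity") <- peak
    trial
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full study
#'
#' Generates the complete protocol: for every subject and leg, three pre
#' MVIC repetitions, three EQI contractions at that leg's load (75% or 90%
#' of the measured pre best peak, assignment counterbalanced across
#' subjects), and three post MVIC repetitions — 9 trials per leg, 18 per
#' subject, 360 in total under the defaults. Fatigue acquired in one EQI
#' repetition carries into the next minus the recovered fraction. The whole
#' study is a deterministic function of `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: when given, every trial is written as a
#'   trial CSV ([write_trial()]) and the ground-truth bundle as
#'   `sim_truth.json`.
#' @param include_mvic Generate the MVIC trials (default `TRUE`); turning
#'   this off (loads are then prescribed from the true MVIC) speeds up
#'   simulation batches that only analyse EQI outcomes.
#' @return (Invisibly when `dir` is given.) List with `trials` (list of
#'   [eqi_trial()]), `truth` (per-EQI-trial ground-truth logs), `subjects`
#'   (per-subject true parameters) and `config`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL,
                           include_mvic = TRUE) {
  out <- withr::with_seed(config$seed, {
    n_sub <- config$n_men + config$n_women
    sexes <- rep(c("M", "F"), c(config$n_men, config$n_women))
    trials <- list()
    truths <- list()
    subjects <- list()
    for (i in seq_len(n_sub)) {
      sid <- sprintf("s%02d", i)
      subj <- simulate_subject(config, sexes[i])
      subjects[[sid]] <- subj
      # counterbalanced leg-load assignment
      legs <- c("left", "right")
      fracs <- if (i %% 2 == 1) config$load_fractions else
        rev(config$load_fractions)
      for (l in 1:2) {
        leg <- legs[l]
        frac <- fracs[l]
        # pre MVIC x3, best peak anchors the load prescription
        if (include_mvic) {
          pre <- map(1:3, function(r) {
            simulate_mvic_trial(subj, fatigue_state = 0, config = config,
                                rep_index = r, time_point = "pre",
                                subject_id = sid, leg = leg)
          })
          best_pre <- max(map_dbl(pre, ~ max(.x$torque_nm)))
          trials <- c(trials, pre)
        } else {
          best_pre <- subj$mvic
        }
        # EQI x3 with partial fatigue recovery between repetitions
        carry <- 0
        for (r in 1:3) {
          st <- simulate_eqi_trial(
            subj, load_fraction = frac, rep_index = r, config = config,
            fatigue0 = carry, prescribed_from = best_pre,
            subject_id = sid, leg = leg
          )
          gained <- st$truth$f_end - st$truth$f_start
          carry <- carry + gained * (1 - config$recovery_fraction_between_reps)
          trials[[length(trials) + 1]] <- st$trial
          truths[[length(truths) + 1]] <- st$truth
        }
        # post MVIC x3
        if (include_mvic) {
          post <- map(1:3, function(r) {
            simulate_mvic_trial(subj, fatigue_state = config$post_mvic_fatigue,
                                config = config, rep_index = r,
                                time_point = "post", subject_id = sid,
                                leg = leg)
          })
          trials <- c(trials, post)
        }
      }
    }
    list(trials = trials, truth = truths, subjects = subjects, config = config)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (tr in out$trials) {
      m <- trial_meta(tr)
      fn <- sprintf("%s_%s_%s%s_rep%d.csv", m$subject_id, m$leg, m$trial_type,
                    if (m$trial_type == "EQI") sprintf("_%g", m$load_condition)
                    else paste0("_", m$time_point), m$repetition)
      write_trial(tr, file.path(dir, fn))
    }
    truth_json <- map(out$truth, function(tt) {
      tt$phases <- as.list(as.data.frame(tt$phases))
      tt
    })
    jsonlite::write_json(truth_json, file.path(dir, "sim_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
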