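# Construct small hand-built trials for unit tests.

make_trial <- function(angle, torque = NULL, velocity = NULL, fs = 100,
                       type = "EQI", load = 120, rom_pf = 25, rom_df = -15,
                       subject_id = "t1", sex = "M", leg = "left",
                       repetition = 1L, load_condition = 75,
                       time_point = NA_character_) {
  n <- length(angle)
  if (is.null(torque)) torque <- rep(load, n)
  if (is.null(velocity)) velocity <- c(0, diff(angle)) * fs
  eqi_trial(
    time = (seq_len(n) - 1) / fs, angle = angle, velocity = velocity,
    torque = torque, subject_id = subject_id, sex = sex, leg = leg,
    trial_type = type,
    load_condition = if (type == "EQI") load_condition else NA_real_,
    repetition = repetition,
    prescribed_load = if (type == "EQI") load else NA_real_,
    sampling_rate = fs, rom_pf = rom_pf, rom_df = rom_df,
    time_point = time_point
  )
}

# an angle trace that rises to an apex and declines: the canonical EQI shape
ramp_decline_angle <- function(n_up = 101, apex = 20, n_down = 300,
                               final = -10) {
  c(seq(0, apex, length.out = n_up),
    seq(apex, final, length.out = n_down + 1)[-1])
}

# deterministic noiseless simulator variant used by exactness tests
noiseless_config <- function(...) {
  sim_config(measurement_noise_cv = 0, angle_resolution_deg = 0, ...)
}
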