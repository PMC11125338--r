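# small study configurations and hand-built recordings used across tests

tiny_config <- function(n_drivers = 2L, n_trials = 1L, n_tos = 2L) {
  cfg <- default_study_config()
  cfg$studies <- data.frame(study = 1L, n_drivers = n_drivers,
                            n_trials_per_driver = n_trials,
                            n_takeovers_per_trial = n_tos)
  cfg
}

# a recording built directly from vectors, for forcing exact feature values
make_recording <- function(steering = NULL, speed = NULL, accel = NULL,
                           brake = NULL, accpedal = NULL, gaze = NULL,
                           pd = NULL, hr = NULL, gsr = NULL,
                           rate_drive = 50, rate_eye = 50, rate_hr = 1,
                           rate_gsr = 4, t0 = -5, event_id = "ev1") {
  grid <- function(v, rate) {
    n <- length(v)
    list(t = t0 + (seq_len(n) - 1) / rate, value = v)
  }
  defaults <- function(v, rate, fill = 0) {
    if (is.null(v)) grid(rep(fill, round((20 - t0) * rate)), rate) else grid(v, rate)
  }
  structure(list(channels = list(
    steering_deg = defaults(steering, rate_drive),
    speed_kmh = defaults(speed, rate_drive, 50),
    accel_ms2 = defaults(accel, rate_drive),
    brake_pct = defaults(brake, rate_drive),
    accpedal_pct = defaults(accpedal, rate_drive),
    gaze_onroad = defaults(gaze, rate_eye, 1),
    pd_mm = defaults(pd, rate_eye, 3),
    hr_bpm = defaults(hr, rate_hr, 75),
    gsr_us = defaults(gsr, rate_gsr, 2)
  ), meta = list(event_id = event_id, tor_time = t0, avail_end = t0 + 5)),
  class = "to_recording")
}

onset_at <- function(time) {
  structure(list(onset = time + 5, time = time, action = "brake",
                 missed = FALSE), class = "to_onset")
}

# noise-free signal parameters: deterministic channels at their mean profiles
noiseless_params <- function() {
  p <- default_signal_params()
  p$steer_sd_base <- 0; p$steer_sd_amplitude <- 0; p$steer_sd_pre <- 0
  p$speed_noise_sd <- 0; p$speed_wander_sd <- 0
  p$accel_noise_sd <- 0; p$accel_wander_sd <- 0; p$accpedal_noise_sd <- 0
  p$eoff_pre <- 0; p$eoff_base <- 0; p$eoff_amplitude <- 0
  p$pd_noise_sd <- 0; p$pd_wander_sd <- 0; p$pd_missing_prob <- 0
  p$hr_noise_sd <- 0; p$hr_wander_sd <- 0; p$hr_missing_prob <- 0
  p$sc_noise_sd <- 0; p$scr_rate0 <- 0; p$scr_rate_inf <- 0
  p$sc_tonic_slope <- 0
  p$pd_between_sd <- 0; p$hr_between_sd <- 0; p$speed_between_sd <- 0
  p$sc_between_sd <- 0
  p$gradual_brake_prob <- 0
  p
}

# brute-force one-way repeated-measures sums of squares by explicit loops
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_f <- 0
  for (j in 1:k) ss_f <- ss_f + n * (mean(Y[, j]) - grand)^2
  ss_s <- 0
  for (i in 1:n) ss_s <- ss_s + k * (mean(Y[i, ]) - grand)^2
  ss_e <- 0
  for (i in 1:n) for (j in 1:k)
    ss_e <- ss_e + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + grand)^2
  F <- (ss_f / (k - 1)) / (ss_e / ((n - 1) * (k - 1)))
  list(F = F, ss_f = ss_f, ss_s = ss_s, ss_e = ss_e)
}

# paired t from explicit mean/sd/df formulas
oracle_paired_t <- function(x, y) {
  d <- x - y
  m <- mean(d); s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  t <- m / (s / sqrt(length(d)))
  list(t = t, p = 2 * pt(-abs(t), length(d) - 1))
}
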