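#' Default study configuration
#'
#' Returns the design of the two emulated driving-simulator studies: study 1
#' with 30 drivers x 4 trials x 4 takeovers (480 takeover attempts) and study 2
#' with 28 drivers x 2 trials x 4 takeovers (224 attempts), 704 in total. The
#' takeover request (TOR) is issued 5 s before automated driving becomes
#' unavailable. Channel sampling rates follow the study instrumentation:
#' driving channels and the eye tracker at 50 Hz, skin conductance at 4 Hz,
#' heart rate at 1 Hz.
#'
#' @param episode_duration Seconds of recording kept after takeover onset.
#'   Must cover the last analysis window (start 12 s + 5 s length); the default
#'   20 s leaves margin.
#' @param seed Default root seed stored with the configuration.
#' @return A list of class `to_study_config` with elements `studies` (data
#'   frame with columns `n_drivers`, `n_trials_per_driver`,
#'   `n_takeovers_per_trial`), `tor_lead_time`, `rate_drive`, `rate_eye`,
#'   `rate_gsr`, `rate_hr`, `episode_duration`, `pre_roll` (seconds recorded
#'   before takeover onset) and `seed`.
#' @export
#' @examples
#' cfg <- default_study_config()
#' n_events_configured(cfg)  # 704
default_study_config <- function(episode_duration = 20, seed = 1L) {
  cfg <- structure(list(
    studies = data.frame(
      study = c(1L, 2L),
      n_drivers = c(30L, 28L),
      n_trials_per_driver = c(4L, 2L),
      n_takeovers_per_trial = c(4L, 4L)
    ),
    tor_lead_time = 5,
    rate_drive = 50,
    rate_eye = 50,
    rate_gsr = 4,
    rate_hr = 1,
    episode_duration = episode_duration,
    # record from 5 s before the earliest possible TOR so the EDA tonic model
    # has context; TOR occurs at -reaction_time, at most tor_lead_time before 0
    pre_roll = 10,
    seed = as.integer(seed)
  ), class = "to_study_config")
  validate_study_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' @param cfg A `to_study_config` list.
#' @return `cfg`, invisibly, after checking invariants.
#' @export
validate_study_config <- function(cfg) {
  stopifnot(
    is.list(cfg),
    is.data.frame(cfg$studies),
    all(c("n_drivers", "n_trials_per_driver", "n_takeovers_per_trial") %in%
          names(cfg$studies))
  )
  counts <- unlist(cfg$studies[c("n_drivers", "n_trials_per_driver",
                                 "n_takeovers_per_trial")])
  if (any(counts < 0)) stop("study counts must be >= 0", call. = FALSE)
  if (!isTRUE(cfg$tor_lead_time > 0)) stop("tor_lead_time must be > 0", call. = FALSE)
  rates <- c(cfg$rate_drive, cfg$rate_eye, cfg$rate_gsr, cfg$rate_hr)
  if (any(rates <= 0)) stop("sampling rates must be > 0", call. = FALSE)
  if (cfg$episode_duration < 17)
    stop("episode_duration must be >= 17 s to cover the 5 s window starting at 12 s",
         call. = FALSE)
  invisible(cfg)
}

#' Number of takeover events a configuration generates
#'
#' @param cfg A `to_study_config` list.
#' @return Integer, the sum over studies of drivers x trials x takeovers.
#' @export
n_events_configured <- function(cfg) {
  s <- cfg$studies
  sum(s$n_drivers * s$n_trials_per_driver * s$n_takeovers_per_trial)
}

#' Default signal-generation parameters
#'
#' Per-variable dynamics of the synthetic post-takeover profiles. Each mean
#' profile relaxes exponentially (speed: dip-and-recover) from a post-takeover
#' excursion toward its asymptote; decay time constants, excursion amplitudes
#' and noise scales are plausible values chosen to emulate the qualitative
#' shape of the study's published mean profiles: an immediate braking pulse,
#' speed dipping then recovering, winding and pupil diameter decaying within
#' seconds, and heart rate / skin conductance decaying slowly enough that they
#' do not settle within the 12 s analysis horizon.
#'
#' Units: steering in degrees, speed in km/h, acceleration in m/s^2, pedals in
#' percent, pupil diameter in mm, heart rate in bpm, skin conductance in
#' microsiemens; all time constants in seconds.
#'
#' @return A list of class `to_signal_params`. Components are documented in
#'   the source; the ones users typically vary are the per-variable
#'   `*_amplitude`, `*_tau` and `*_noise_sd` entries, `hr_missing_prob`, and
#'   the SCR train parameters `scr_rate0`, `scr_rate_inf`, `scr_rate_tau`,
#'   `scr_amp_mean`.
#' @export
default_signal_params <- function() {
  p <- list(
    # steering: zero-mean noise whose sd decays (winding is a windowed sd)
    steer_sd_base = 1.5, steer_sd_amplitude = 1.6, steer_tau = 2.0,
    steer_sd_pre = 0.3,
    # speed: dip-and-recover v(t) = base - depth * (t/t_dip) * exp(1 - t/t_dip)
    speed_base = 50, speed_dip_depth = 10, speed_dip_t = 1.5,
    speed_noise_sd = 0.5, speed_wander_sd = 1.0,
    # braking: most events are a short pulse, a fraction brake gradually for
    # the whole horizon (only those yield deceleration data in every window)
    gradual_brake_prob = 0.12,
    decel_base = 0.3, decel_amplitude = 2.2, decel_tau = 0.4,
    accel_noise_sd = 0.15, accel_wander_sd = 0.05,
    brake_pulse_peak = 60, brake_pulse_tau = 0.8,
    brake_gradual_base = 6, brake_gradual_amp = 25, brake_gradual_tau = 4,
    accpedal_level = 8, accpedal_tau = 3, accpedal_noise_sd = 1,
    # gaze: off-road probability decays after takeover
    eoff_pre = 0.75, eoff_base = 0.08, eoff_amplitude = 0.27, eoff_tau = 0.5,
    # pupil diameter
    pd_base = 3.0, pd_amplitude = 0.8, pd_tau = 1.6,
    pd_noise_sd = 0.05, pd_wander_sd = 0.10, pd_missing_prob = 0.03,
    # heart rate
    hr_base = 75, hr_amplitude = 10, hr_tau = 5,
    hr_noise_sd = 2.0, hr_wander_sd = 1.2, hr_missing_prob = 0.35,
    # skin conductance: tonic drift + Poisson SCR train (many small SCRs)
    sc_tonic_level = 2.0, sc_tonic_slope = -0.005, sc_noise_sd = 0.01,
    scr_rate0 = 1.4, scr_rate_inf = 0.05, scr_rate_tau = 8,
    scr_amp_mean = 0.15, scr_amp_cv = 0.3,
    scr_tau_rise = 0.7, scr_tau_decay = 2.0,
    # driver-level heterogeneity (cancels in within-subject contrasts)
    pd_between_sd = 0.3, hr_between_sd = 6, speed_between_sd = 1.5,
    sc_between_sd = 0.4,
    # reaction time between TOR and takeover onset, uniform on this range
    reaction_time_range = c(0.8, 3.0),
    # timescale of the slow AR(1) physiological wander
    wander_timescale = 5
  )
  class(p) <- "to_signal_params"
  p
}

#' Validate signal-generation parameters
#'
#' @param params A `to_signal_params` list.
#' @return `params` invisibly; errors on invalid values.
#' @export
validate_signal_params <- function(params) {
  taus <- c(params$steer_tau, params$speed_dip_t, params$decel_tau,
            params$eoff_tau, params$pd_tau, params$hr_tau, params$scr_rate_tau)
  if (any(taus < 0)) stop("decay time constants must be >= 0", call. = FALSE)
  sds <- c(params$speed_noise_sd, params$accel_noise_sd, params$pd_noise_sd,
           params$hr_noise_sd, params$sc_noise_sd)
  if (any(sds < 0)) stop("noise sds must be >= 0", call. = FALSE)
  probs <- c(params$gradual_brake_prob, params$eoff_pre, params$eoff_base,
             params$eoff_base + params$eoff_amplitude,
             params$hr_missing_prob, params$pd_missing_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (params$sc_tonic_level < 0) stop("skin conductance level must be >= 0", call. = FALSE)
  pd_range <- params$pd_base + c(0, params$pd_amplitude)
  if (any(pd_range < 1 | pd_range > 9))
    stop("pupil diameter must stay in a plausible 1-9 mm range", call. = FALSE)
  if (!(params$scr_tau_rise > 0 && params$scr_tau_rise < params$scr_tau_decay))
    stop("SCR kernel requires 0 < tau_rise < tau_decay", call. = FALSE)
  invisible(params)
}

#' The seven analysis variables
#'
#' @return Character vector of variable names in reporting order.
#' @export
to_variables <- function() {
  c("winding", "speed", "deceleration", "eoff", "pd", "hr", "sc")
}

#' Read a pipeline configuration file
#'
#' Minimal `key = value` text format (one pair per line, `#` comments,
#' scalars only). Recognised keys: `seed`, `alpha`, `unit`
#' (`attempt`/`driver`), `episode_duration`, `gt_tolerance`,
#' `write_recordings` (true/false). Unknown keys raise a configuration error
#' before any computation.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values merged over defaults.
#' @export
read_pipeline_config <- function(path) {
  defaults <- list(seed = 1L, alpha = 0.05, unit = "attempt",
                   episode_duration = 20, gt_tolerance = 0.05,
                   write_recordings = FALSE)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config: malformed line (expected key = value): ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults))
      stop("config: unknown key '", key, "'", call. = FALSE)
    val <- gsub('^"|"$', "", val)
    out[[key]] <- switch(key,
      seed = as.integer(val),
      alpha = as.numeric(val),
      episode_duration = as.numeric(val),
      gt_tolerance = as.numeric(val),
      write_recordings = tolower(val) %in% c("true", "yes", "1"),
      unit = match.arg(val, c("attempt", "driver"))
    )
  }
  if (is.na(out$seed)) stop("config: seed must be an integer", call. = FALSE)
  if (!(out$alpha > 0 && out$alpha < 1)) stop("config: alpha must be in (0,1)", call. = FALSE)
  out
}
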