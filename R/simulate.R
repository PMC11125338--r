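#' @keywords internal
"_PACKAGE"

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stable per-event substream seed from the root seed and event coordinates,
# kept below 2^31 (R integers are 32-bit); doubles are exact here
event_seed <- function(root, study, driver, trial, index) {
  h <- (((study * 1009 + driver) * 131 + trial) * 131 + index) %% 1048573
  as.integer((root %% 65521 + 1) * 1048573 %% 2147483647 + h) %% 2147483647L
}

# slow AR(1) wander with stationary sd `sd` and correlation timescale `tau_c`
ar1_wander <- function(n, dt, sd, tau_c) {
  if (sd <= 0 || n == 0) return(numeric(n))
  rho <- exp(-dt / tau_c)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- rho * x[i] + innov[i + 1L]
  x
}

# deterministic mean profiles of the channels / windowed features, t relative
# to takeover onset (t = 0). These are shared by the generator and the
# ground-truth calculator so the two can never drift apart.
mean_profiles <- function(params) {
  p <- params
  kernel_gain <- function() {
    # integral of the unit-peak Bateman kernel
    tr <- p$scr_tau_rise; td <- p$scr_tau_decay
    tpk <- log(td / tr) * td * tr / (td - tr)
    peak <- exp(-tpk / td) - exp(-tpk / tr)
    (td - tr) / peak
  }
  list(
    # sd of the steering angle (winding is a windowed sd, so ground truth for
    # winding lives on the sd profile, not the mean)
    winding = function(t) ifelse(t < 0, p$steer_sd_pre,
                                 p$steer_sd_base + p$steer_sd_amplitude * exp(-t / p$steer_tau)),
    speed = function(t) ifelse(t < 0, p$speed_base,
                               p$speed_base - p$speed_dip_depth *
                                 (t / p$speed_dip_t) * exp(1 - t / p$speed_dip_t)),
    # positive deceleration magnitude of the gradual-braking profile
    deceleration = function(t) ifelse(t < 0, 0,
                                      p$decel_base + p$decel_amplitude * exp(-t / p$decel_tau)),
    eoff = function(t) ifelse(t < 0, p$eoff_pre,
                              p$eoff_base + p$eoff_amplitude * exp(-t / p$eoff_tau)),
    pd = function(t) ifelse(t < 0, p$pd_base + 0.3,
                            p$pd_base + p$pd_amplitude * exp(-t / p$pd_tau)),
    hr = function(t) ifelse(t < 0, p$hr_base,
                            p$hr_base + p$hr_amplitude * exp(-t / p$hr_tau)),
    scr_rate = function(t) ifelse(t < 0, p$scr_rate_inf,
                                  p$scr_rate_inf +
                                    (p$scr_rate0 - p$scr_rate_inf) * exp(-t / p$scr_rate_tau)),
    # expected phasic skin-conductance level for the Poisson SCR train
    sc = function(t) ifelse(t < 0, p$scr_rate_inf * p$scr_amp_mean * kernel_gain(),
                            (p$scr_rate_inf +
                               (p$scr_rate0 - p$scr_rate_inf) * exp(-t / p$scr_rate_tau)) *
                              p$scr_amp_mean * kernel_gain())
  )
}

#' Simulate the multichannel recording of one takeover event
#'
#' Generates the nine channels of a takeover episode on the time base
#' `t = 0` at takeover onset: steering as a zero-mean noise process whose sd
#' decays after the takeover, speed as a dip-and-recover profile, a braking
#' pulse (or, for a random subset of events, sustained gradual braking) with
#' the matching longitudinal deceleration, accelerator pedal ramp-in, gaze as
#' Bernoulli draws from a decaying off-road probability, pupil diameter and
#' heart rate as step-plus-exponential-decay profiles with slow physiological
#' wander (heart-rate samples dropped i.i.d. to mimic motion artifacts), and
#' skin conductance as tonic drift plus a Poisson train of skin-conductance
#' responses convolved with a biexponential kernel.
#'
#' @param event One-row data frame with columns `event_id`, `study`, `driver`,
#'   `trial`, `to_index`, `tor_time` (negative, seconds before onset),
#'   `avail_end`, `gradual_brake` (logical), and the per-driver offsets
#'   `off_speed`, `off_pd`, `off_hr`, `off_sc`.
#' @param params A `to_signal_params` list (see [default_signal_params()]).
#' @param seed Integer seed for this event's substream.
#' @param config A `to_study_config` list giving rates and durations.
#' @return A `to_recording`: list with `channels` (each a list with numeric
#'   `t` and `value`, `NA` marking missing samples) and `meta`.
#' @export
simulate_event_channels <- function(event, params, seed, config = default_study_config()) {
  validate_signal_params(params)
  p <- params
  prof <- mean_profiles(p)
  pre <- config$pre_roll
  dur <- config$episode_duration
  with_seed(seed, {
    dt_d <- 1 / config$rate_drive
    t_d <- seq(-pre, dur, by = dt_d)
    n_d <- length(t_d)
    post <- t_d >= 0

    steering <- stats::rnorm(n_d) * prof$winding(t_d)

    speed <- prof$speed(t_d) + event$off_speed +
      ar1_wander(n_d, dt_d, p$speed_wander_sd, p$wander_timescale) +
      stats::rnorm(n_d, 0, p$speed_noise_sd)

    if (isTRUE(event$gradual_brake)) {
      brake <- ifelse(post, p$brake_gradual_base +
                        p$brake_gradual_amp * exp(-t_d / p$brake_gradual_tau), 0)
      accel_mean <- ifelse(post, -prof$deceleration(t_d), 0)
    } else {
      brk <- p$brake_pulse_peak * exp(-t_d / p$brake_pulse_tau)
      brake <- ifelse(post & brk >= 1, brk, 0)
      accel_mean <- ifelse(post, -(p$decel_base + 4.2 * exp(-t_d / p$brake_pulse_tau)), 0)
    }
    accel <- accel_mean +
      ar1_wander(n_d, dt_d, p$accel_wander_sd, p$wander_timescale) +
      stats::rnorm(n_d, 0, p$accel_noise_sd)
    accpedal <- ifelse(post, p$accpedal_level * (1 - exp(-t_d / p$accpedal_tau)), 0)
    if (p$accpedal_noise_sd > 0)
      accpedal <- accpedal + ifelse(post, stats::rnorm(n_d, 0, p$accpedal_noise_sd), 0)
    accpedal <- pmin(pmax(accpedal, 0), 100)
    brake <- pmin(pmax(brake, 0), 100)

    dt_e <- 1 / config$rate_eye
    t_e <- seq(-pre, dur, by = dt_e)
    n_e <- length(t_e)
    p_off <- pmin(pmax(ifelse(t_e < 0, p$eoff_pre,
                              p$eoff_base + p$eoff_amplitude * exp(-t_e / p$eoff_tau)), 0), 1)
    gaze <- as.numeric(stats::runif(n_e) >= p_off)  # 1 = on-road
    pd <- prof$pd(t_e) + event$off_pd +
      ar1_wander(n_e, dt_e, p$pd_wander_sd, p$wander_timescale) +
      stats::rnorm(n_e, 0, p$pd_noise_sd)
    if (p$pd_missing_prob > 0)
      pd[stats::runif(n_e) < p$pd_missing_prob] <- NA_real_

    dt_h <- 1 / config$rate_hr
    t_h <- seq(-pre, dur, by = dt_h)
    n_h <- length(t_h)
    hr <- prof$hr(t_h) + event$off_hr +
      ar1_wander(n_h, dt_h, p$hr_wander_sd, p$wander_timescale) +
      stats::rnorm(n_h, 0, p$hr_noise_sd)
    if (p$hr_missing_prob > 0)
      hr[stats::runif(n_h) < p$hr_missing_prob] <- NA_real_

    dt_g <- 1 / config$rate_gsr
    t_g <- seq(-pre, dur, by = dt_g)
    n_g <- length(t_g)
    rate <- prof$scr_rate(t_g)
    n_scr <- stats::rpois(n_g, rate * dt_g)
    driver_imp <- numeric(n_g)
    idx <- which(n_scr > 0)
    if (length(idx)) {
      amps <- vapply(idx, function(i) {
        if (p$scr_amp_cv > 0) {
          sdlog <- sqrt(log(1 + p$scr_amp_cv^2))
          sum(stats::rlnorm(n_scr[i], log(p$scr_amp_mean) - sdlog^2 / 2, sdlog))
        } else p$scr_amp_mean * n_scr[i]
      }, numeric(1))
      driver_imp[idx] <- amps
    }
    kern <- bateman_kernel(list(tau_rise = p$scr_tau_rise, tau_decay = p$scr_tau_decay),
                           rate = config$rate_gsr)
    phasic <- stats::convolve(driver_imp, rev(kern$k), type = "open")[seq_len(n_g)]
    tonic <- pmax(p$sc_tonic_level + event$off_sc + p$sc_tonic_slope * (t_g + pre), 0)
    gsr <- pmax(tonic + phasic + stats::rnorm(n_g, 0, p$sc_noise_sd), 0)

    structure(list(
      channels = list(
        steering_deg = list(t = t_d, value = steering),
        speed_kmh    = list(t = t_d, value = speed),
        accel_ms2    = list(t = t_d, value = accel),
        brake_pct    = list(t = t_d, value = brake),
        accpedal_pct = list(t = t_d, value = accpedal),
        gaze_onroad  = list(t = t_e, value = gaze),
        pd_mm        = list(t = t_e, value = pd),
        hr_bpm       = list(t = t_h, value = hr),
        gsr_us       = list(t = t_g, value = gsr)
      ),
      meta = list(event_id = event$event_id, tor_time = event$tor_time,
                  avail_end = event$avail_end,
                  gradual_brake = isTRUE(event$gradual_brake))
    ), class = "to_recording")
  })
}

#' Generate a full synthetic takeover study
#'
#' Expands the study design into its takeover events (driver x trial x
#' takeover), draws per-driver offsets and reaction times, simulates every
#' event's multichannel recording, and attaches the analytic ground-truth
#' stabilization times implied by `params`. Deterministic given
#' `(config, params, seed)`; per-event substreams are derived by stable
#' hashing of the event coordinates, so regenerating any single event
#' reproduces its recording bit for bit.
#'
#' @param config A `to_study_config` (see [default_study_config()]).
#' @param params A `to_signal_params` (see [default_signal_params()]).
#' @param seed Root seed; overrides `config$seed` when given.
#' @param gt_tolerance Tolerance band fraction for the ground truth
#'   (see [ground_truth_for()]).
#' @return A `to_dataset`: list with `events` (data frame), `recordings`
#'   (list of `to_recording`, one per event), `ground_truth` (data frame),
#'   and `provenance`.
#' @export
#' @examples
#' cfg <- default_study_config()
#' cfg$studies <- data.frame(study = 1L, n_drivers = 1L,
#'                           n_trials_per_driver = 1L, n_takeovers_per_trial = 4L)
#' ds <- generate_study(cfg, default_signal_params(), seed = 1)
#' nrow(ds$events)  # 4
generate_study <- function(config = default_study_config(),
                           params = default_signal_params(),
                           seed = config$seed, gt_tolerance = 0.05) {
  validate_study_config(config)
  validate_signal_params(params)
  events <- expand_events(config, params, seed)
  if (nrow(events) == 0L) {
    warning("configuration yields zero takeover events; returning empty dataset")
    return(structure(list(events = events, recordings = list(),
                          ground_truth = ground_truth_for(params, gt_tolerance),
                          provenance = list(config = config, seed = seed)),
                     class = "to_dataset"))
  }
  recordings <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    simulate_event_channels(ev, params, seed = ev$seed, config = config)
  })
  names(recordings) <- events$event_id
  structure(list(events = events, recordings = recordings,
                 ground_truth = ground_truth_for(params, gt_tolerance),
                 provenance = list(config = config, seed = seed)),
            class = "to_dataset")
}

# expand the study design into one row per takeover event, with per-driver
# offsets and reaction times drawn from driver-/event-level substreams
expand_events <- function(config, params, seed) {
  s <- config$studies
  rows <- list()
  for (j in seq_len(nrow(s))) {
    st <- s$study[j]
    for (d in seq_len(s$n_drivers[j])) {
      dseed <- event_seed(seed, st, d, 0L, 0L)
      offs <- with_seed(dseed, stats::rnorm(4) *
                          c(params$speed_between_sd, params$pd_between_sd,
                            params$hr_between_sd, params$sc_between_sd))
      for (tr in seq_len(s$n_trials_per_driver[j])) {
        for (k in seq_len(s$n_takeovers_per_trial[j])) {
          es <- event_seed(seed, st, d, tr, k)
          draw <- with_seed(es + 7L, c(stats::runif(1), stats::runif(1)))
          rt <- params$reaction_time_range[1] +
            diff(params$reaction_time_range) * draw[1]
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = sprintf("s%d_d%02d_t%d_to%d", st, d, tr, k),
            study = st, driver = d, trial = tr, to_index = k,
            reaction_time = rt, tor_time = -rt,
            avail_end = -rt + config$tor_lead_time,
            gradual_brake = draw[2] < params$gradual_brake_prob,
            off_speed = offs[1], off_pd = offs[2], off_hr = offs[3],
            off_sc = max(offs[4], -0.8 * params$sc_tonic_level),
            seed = es, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(event_id = character(), study = integer(),
                      driver = integer(), trial = integer(),
                      to_index = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
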