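test_that("default configuration reproduces the two-study design", {
  cfg <- default_study_config()
  s <- cfg$studies
  counts <- s$n_drivers * s$n_trials_per_driver * s$n_takeovers_per_trial
  expect_equal(counts, c(480, 224))
  expect_equal(n_events_configured(cfg), 704)
  expect_equal(cfg$tor_lead_time, 5)
  expect_equal(cfg$rate_eye, 50)
  expect_equal(cfg$rate_gsr, 4)
  expect_equal(cfg$rate_hr, 1)
  expect_gte(cfg$episode_duration, 17)
})

test_that("event count equals the configured product for random small designs", {
  set.seed(11)
  for (i in 1:8) {
    cfg <- default_study_config()
    nd <- sample(0:3, 2, replace = TRUE)
    nt <- sample(1:3, 2, replace = TRUE)
    nk <- sample(1:4, 2, replace = TRUE)
    cfg$studies <- data.frame(study = 1:2, n_drivers = nd,
                              n_trials_per_driver = nt,
                              n_takeovers_per_trial = nk)
    expected <- sum(nd * nt * nk)
    if (expected == 0) {
      expect_warning(ds <- generate_study(cfg, seed = i), "zero")
    } else {
      ds <- generate_study(cfg, seed = i)
    }
    expect_equal(nrow(ds$events), expected)
    expect_length(ds$recordings, expected)
  }
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- tiny_config()
  a <- generate_study(cfg, seed = 5)
  b <- generate_study(cfg, seed = 5)
  expect_identical(a$events, b$events)
  expect_identical(a$recordings, b$recordings)
  c <- generate_study(cfg, seed = 6)
  expect_false(identical(a$recordings[[1]]$channels$steering_deg$value,
                         c$recordings[[1]]$channels$steering_deg$value))
})

test_that("channel timestamps are strictly increasing at the configured rates", {
  cfg <- tiny_config(1L, 1L, 1L)
  ds <- generate_study(cfg, seed = 2)
  rec <- ds$recordings[[1]]
  rates <- c(steering_deg = 50, speed_kmh = 50, gaze_onroad = 50,
             pd_mm = 50, hr_bpm = 1, gsr_us = 4)
  for (nm in names(rates)) {
    t <- rec$channels[[nm]]$t
    expect_true(all(diff(t) > 0), info = nm)
    expect_equal(stats::median(diff(t)), 1 / rates[[nm]],
                 tolerance = 0.01, info = nm)
    expect_lte(min(t), -cfg$tor_lead_time)
    expect_gte(max(t), 17)
  }
})

test_that("noise-free parameters yield the deterministic mean profiles", {
  cfg <- tiny_config(1L, 1L, 1L)
  p <- noiseless_params()
  ds <- generate_study(cfg, p, seed = 1)
  rec <- ds$recordings[[1]]
  ch <- rec$channels
  post <- ch$speed_kmh$t >= 0
  tt <- ch$speed_kmh$t[post]
  expect_equal(ch$steering_deg$value, rep(0, length(ch$steering_deg$t)))
  expect_equal(ch$speed_kmh$value[post],
               p$speed_base - p$speed_dip_depth * (tt / p$speed_dip_t) *
                 exp(1 - tt / p$speed_dip_t), tolerance = 1e-12)
  expect_true(all(ch$gaze_onroad$value == 1))  # off-road probability 0
  tp <- ch$pd_mm$t[ch$pd_mm$t >= 0]
  expect_equal(ch$pd_mm$value[ch$pd_mm$t >= 0],
               p$pd_base + p$pd_amplitude * exp(-tp / p$pd_tau), tolerance = 1e-12)
  expect_false(anyNA(ch$hr_bpm$value))
  # no SCRs, no slope: skin conductance constant at the tonic level
  expect_equal(ch$gsr_us$value,
               rep(p$sc_tonic_level, length(ch$gsr_us$t)), tolerance = 1e-12)
})

test_that("invalid parameters are rejected", {
  p <- default_signal_params()
  p$pd_tau <- -1
  expect_error(validate_signal_params(p), "time constants")
  p <- default_signal_params()
  p$hr_noise_sd <- -0.1
  expect_error(validate_signal_params(p), "noise sds")
  p <- default_signal_params()
  p$hr_missing_prob <- 1.2
  expect_error(validate_signal_params(p), "probabilities")
})

test_that("ground truth matches the closed form for exponential decay", {
  p <- default_signal_params()
  gt <- ground_truth_for(p, tolerance = 0.05)
  closed <- function(tau) tau * log(1 / 0.05)
  for (v in c("pd", "hr", "winding")) {
    tau <- switch(v, pd = p$pd_tau, hr = p$hr_tau, winding = p$steer_tau)
    expected <- closed(tau)
    row <- gt[gt$variable == v, ]
    if (expected > 17) {
      expect_false(row$stabilized_within_horizon, info = v)
    } else {
      expect_equal(row$time_s, expected, tolerance = 0.02, info = v)
    }
  }
})

test_that("zero time constants give zero ground-truth times; huge ones are flagged", {
  p <- default_signal_params()
  p$steer_tau <- 1e-9; p$pd_tau <- 1e-9; p$hr_tau <- 1e-9
  p$eoff_tau <- 1e-9; p$decel_tau <- 1e-9; p$speed_dip_t <- 1e-9
  p$scr_rate_tau <- 1e-9
  gt <- ground_truth_for(p, tolerance = 0.05, dt = 0.001)
  expect_true(all(gt$time_s < 0.01))
  p2 <- default_signal_params()
  p2$hr_tau <- 100
  gt2 <- ground_truth_for(p2, tolerance = 0.05)
  expect_false(gt2$stabilized_within_horizon[gt2$variable == "hr"])
})

test_that("ground-truth scan agrees with a brute-force scan oracle", {
  p <- default_signal_params()
  gt <- ground_truth_for(p, tolerance = 0.05, horizon = 17)
  prof_dev <- function(f, tt) abs(f(tt) - f(1e9))
  # independent oracle: evaluate the speed profile densely and find the band
  tt <- seq(0, 17, by = 0.005)
  dev <- abs((p$speed_dip_depth * (tt / p$speed_dip_t) * exp(1 - tt / p$speed_dip_t)))
  band <- 0.05 * p$speed_dip_depth
  t_oracle <- tt[max(which(dev > band)) + 1L]
  expect_equal(gt$time_s[gt$variable == "speed"], t_oracle, tolerance = 0.02)
})
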