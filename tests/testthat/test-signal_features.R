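test_that("window grids follow the every-other-second scheme", {
  g2 <- build_window_grid(2)
  expect_equal(g2$starts, seq(0, 12, 2))
  expect_length(g2$starts, 7)
  # 2 s windows tile: consecutive starts differ by the window length
  expect_true(all(diff(g2$starts) == g2$length))
  g5 <- build_window_grid(5)
  expect_length(g5$starts, 7)
  expect_true(all(diff(g5$starts) < g5$length))  # overlapping
  g0 <- build_window_grid(2, horizon = 0)
  expect_equal(g0$starts, 0)
  expect_error(build_window_grid(0), "length")
  expect_error(build_window_grid(2, step = 0), "step")
})

test_that("takeover onset follows the earliest-crossing rule", {
  rate <- 50
  t0 <- -5
  n <- 25 * rate
  tt <- t0 + (seq_len(n) - 1) / rate
  # steering crosses 2 deg at 1.2 s post-TOR, pedals untouched
  steer <- ifelse(tt >= t0 + 1.2, 2.5, 0.1)
  rec <- make_recording(steering = steer)
  on <- detect_takeover_onset(rec, tor_time = t0)
  expect_equal(on$onset, 1.2, tolerance = 1 / rate)
  expect_equal(on$action, "steering")
  expect_false(on$missed)

  # brake reaches 10% at 0.8 s, steering crosses at 1.0 s -> brake wins
  brake <- ifelse(tt >= t0 + 0.8, 15, 0)
  steer2 <- ifelse(tt >= t0 + 1.0, 3, 0)
  rec2 <- make_recording(steering = steer2, brake = brake)
  on2 <- detect_takeover_onset(rec2, tor_time = t0)
  expect_equal(on2$onset, 0.8, tolerance = 1 / rate)
  expect_equal(on2$action, "brake")

  # nothing crosses within the 5 s lead time -> missed
  rec3 <- make_recording()
  on3 <- detect_takeover_onset(rec3, tor_time = t0)
  expect_true(on3$missed)
  expect_true(is.na(on3$onset))

  # accelerator can also trigger
  acc <- ifelse(tt >= t0 + 2, 30, 0)
  rec4 <- make_recording(accpedal = acc)
  on4 <- detect_takeover_onset(rec4, tor_time = t0)
  expect_equal(on4$action, "accelerator")
})

test_that("windowed features match their definitions on constructed inputs", {
  rate <- 50
  grid <- build_window_grid(2)
  n <- 25 * rate
  # constant steering -> winding 0; gaze (on,on,on,off) pattern -> E-OFF 0.25
  gaze <- rep(c(1, 1, 1, 0), length.out = n)
  pd <- rep(3.0, n); pd[251:n] <- 3.0  # value at TO is 3.0
  rec <- make_recording(steering = rep(5, n), gaze = gaze, pd = pd)
  on <- onset_at(0)
  f <- compute_window_features(rec, on, grid,
                               variables = c("winding", "eoff", "pd"))
  expect_equal(f$value[f$variable == "winding"], rep(0, 7))
  expect_equal(f$value[f$variable == "eoff"], rep(0.25, 7))
  expect_equal(f$value[f$variable == "pd"], rep(0, 7))  # PD shift: baseline window is 0
})

test_that("PD is baseline-shifted by the value at takeover", {
  rate <- 50
  n <- 25 * rate
  tt <- -5 + (seq_len(n) - 1) / rate
  pd <- ifelse(tt < 0, 3.0, ifelse(tt < 2, 3.4, 3.6))
  pd[tt >= 0][1] <- 3.0  # first post-onset sample is the anchor
  rec <- make_recording(pd = pd)
  f <- compute_window_features(rec, onset_at(0), build_window_grid(2),
                               variables = "pd")
  v4 <- f$value[f$window_start_s == 4]
  expect_equal(v4, 0.6, tolerance = 1e-12)
})

test_that("windows with no eligible samples are missing, never zero", {
  n <- 25 * 50
  hr <- rep(NA_real_, 25)  # all heart-rate samples masked
  rec <- make_recording(hr = hr)
  f <- compute_window_features(rec, onset_at(0), build_window_grid(2),
                               variables = "hr")
  expect_true(all(f$is_missing))
  expect_true(all(is.na(f$value)))

  # deceleration requires accel < 0 while brake > 0
  accel <- rep(-1, n); brake <- rep(0, n)
  rec2 <- make_recording(accel = accel, brake = brake)
  f2 <- compute_window_features(rec2, onset_at(0), build_window_grid(2),
                                variables = "deceleration")
  expect_true(all(f2$is_missing))
  brake[251:350] <- 20  # recording starts at -5 s: these are the first 2 s post-onset
  rec3 <- make_recording(accel = accel, brake = brake)
  f3 <- compute_window_features(rec3, onset_at(0), build_window_grid(2),
                                variables = "deceleration")
  expect_equal(f3$value[f3$window_start_s == 0], 1)
  expect_true(all(f3$is_missing[f3$window_start_s > 0]))
})

test_that("winding equals a two-pass sd oracle and is translation invariant", {
  set.seed(21)
  n <- 25 * 50
  steer <- rnorm(n, sd = 3)
  rec <- make_recording(steering = steer)
  f <- compute_window_features(rec, onset_at(0), build_window_grid(2),
                               variables = "winding")
  # two-pass oracle on the first window's samples
  tt <- rec$channels$steering_deg$t
  x <- steer[tt >= 0 & tt < 2]
  m <- sum(x) / length(x)
  sd_oracle <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(f$value[f$window_start_s == 0], sd_oracle, tolerance = 1e-12)

  rec2 <- make_recording(steering = steer + 57.3)
  f2 <- compute_window_features(rec2, onset_at(0), build_window_grid(2),
                                variables = "winding")
  expect_equal(f2$value, f$value, tolerance = 1e-9)
  expect_true(all(f$value >= 0))
})

test_that("2 s windows tile: per-window sample counts sum over [0, 14)", {
  cfg <- tiny_config(1L, 1L, 1L)
  ds <- generate_study(cfg, seed = 9)
  rec <- ds$recordings[[1]]
  on <- detect_takeover_onset(rec, ds$events$tor_time[1], ds$events$avail_end[1])
  tt <- rec$channels$speed_kmh$t - on$time
  total <- sum(tt >= 0 & tt < 14)
  counts <- vapply(seq(0, 12, 2), function(s) sum(tt >= s & tt < s + 2), numeric(1))
  expect_equal(sum(counts), total)
})

test_that("E-OFF stays within [0, 1] on generated data", {
  cfg <- tiny_config()
  ds <- generate_study(cfg, seed = 3)
  feats <- compute_feature_table(ds, build_window_grid(2),
                                 variables = c("eoff", "winding"))
  eo <- feats$value[feats$variable == "eoff" & !feats$is_missing]
  expect_true(all(eo >= 0 & eo <= 1))
  wd <- feats$value[feats$variable == "winding" & !feats$is_missing]
  expect_true(all(wd >= 0))
})
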