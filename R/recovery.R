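#' Signal parameters for a parameter-recovery run
#'
#' Winding-focused settings with the steering-sd decay constant chosen so the
#' analytic ground-truth stabilization time equals `target_time` at the given
#' tolerance (`tau = target / log(1/tolerance)`), and an excursion amplitude
#' large relative to the windowed-sd sampling noise ("strong effect").
#' `target_time = 0` gives a stationary steering process.
#'
#' @param target_time Ground-truth stabilization time in seconds.
#' @param tolerance Ground-truth band fraction (default 0.05).
#' @return A `to_signal_params` list.
#' @export
recovery_params <- function(target_time, tolerance = 0.05) {
  p <- default_signal_params()
  if (target_time <= 0) {
    p$steer_tau <- 1e-6
    p$steer_sd_amplitude <- 0
  } else {
    p$steer_tau <- target_time / log(1 / tolerance)
    p$steer_sd_amplitude <- 1.0
  }
  p
}

#' Stationary (null) signal parameters
#'
#' All post-takeover excursions removed: every channel is a stationary noisy
#' process, so the true stabilization time of every variable is 0 s.
#'
#' @return A `to_signal_params` list.
#' @export
stationary_params <- function() {
  p <- default_signal_params()
  p$steer_sd_amplitude <- 0; p$steer_sd_pre <- p$steer_sd_base
  p$speed_dip_depth <- 0
  p$decel_amplitude <- 0
  p$eoff_amplitude <- 0; p$eoff_pre <- p$eoff_base
  p$pd_amplitude <- 0
  p$hr_amplitude <- 0
  p$scr_rate0 <- p$scr_rate_inf
  p$sc_tonic_slope <- 0
  p
}

# a 200-attempt single-study design (25 drivers x 2 trials x 4 takeovers)
recovery_config <- function(n_drivers = 25L, n_trials = 2L, n_tos = 4L) {
  cfg <- default_study_config()
  cfg$studies <- data.frame(study = 1L, n_drivers = n_drivers,
                            n_trials_per_driver = n_trials,
                            n_takeovers_per_trial = n_tos)
  cfg
}

#' Parameter-recovery simulation for the stabilization pipeline
#'
#' For each seed, generates a study with the given parameters, extracts the
#' requested variable's windowed features, runs the full stabilization
#' analysis, and compares the detected stabilization window with the analytic
#' ground truth. The detected time counts as recovered when it lies within
#' `slack_steps` grid steps of the window nearest the ground-truth time
#' (a never-stabilized result matches a ground truth beyond the horizon).
#'
#' @param params A `to_signal_params`.
#' @param variable Variable to analyze (default `"winding"`).
#' @param seeds Integer vector of replicate seeds.
#' @param config Study design (default: 200 attempts).
#' @param window_len Window length in seconds (default 2).
#' @param alpha Significance level (default 0.05).
#' @param slack_steps Allowed deviation in grid steps (default 1).
#' @param gt_tolerance Ground-truth band fraction (default 0.05).
#' @return List with `stabilized_at` (per seed, NA = not stabilized),
#'   `gt_time`, `gt_window`, `hits` (logical per seed), `hit_rate`.
#' @export
recovery_simulation <- function(params, variable = "winding", seeds = 1:20,
                                config = recovery_config(), window_len = 2,
                                alpha = 0.05, slack_steps = 1,
                                gt_tolerance = 0.05) {
  grid <- build_window_grid(window_len)
  horizon <- max(grid$starts) + window_len
  gt <- ground_truth_for(params, tolerance = gt_tolerance, horizon = horizon)
  gt_row <- gt[gt$variable == variable, ]
  gt_time <- gt_row$time_s
  gt_window <- if (is.na(gt_time)) NA_real_ else
    grid$starts[which.min(abs(grid$starts - gt_time))]
  stab <- vapply(seeds, function(s) {
    ds <- generate_study(config, params, seed = s)
    feats <- compute_feature_table(ds, grid, variables = variable)
    res <- analyze_variable(feats, variable, alpha = alpha)
    if (res$stabilized) res$stabilized_at else NA_real_
  }, numeric(1))
  hits <- if (is.na(gt_window)) {
    is.na(stab)
  } else {
    !is.na(stab) & abs(stab - gt_window) <= slack_steps * grid$step
  }
  list(stabilized_at = stab, gt_time = gt_time, gt_window = gt_window,
       hits = hits, hit_rate = mean(hits))
}
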