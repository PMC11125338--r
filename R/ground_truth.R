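#' Ground-truth stabilization times implied by generator parameters
#'
#' For each analysis variable, computes the earliest time after takeover onset
#' from which the noise-free mean profile of the windowed feature stays within
#' `tolerance * |excursion amplitude|` of its asymptote, by a dense numeric
#' scan of the analytic profile. A variable whose profile is still outside the
#' band at the analysis horizon is flagged as not stabilized within the
#' horizon.
#'
#' For a pure exponential excursion of amplitude `A` and time constant `tau`
#' the scan reproduces the closed form `tau * log(1 / tolerance)`.
#'
#' @param params A `to_signal_params` list.
#' @param tolerance Band half-width as a fraction of the excursion amplitude
#'   (default 0.05).
#' @param horizon Analysis horizon in seconds: last window start (12 s) plus
#'   window length. Default 17 covers the 5 s windows.
#' @param dt Scan resolution in seconds.
#' @return Data frame with columns `variable`, `time_s` (NA when never inside
#'   the band before `horizon`), and `stabilized_within_horizon`.
#' @export
ground_truth_for <- function(params, tolerance = 0.05, horizon = 17, dt = 0.01) {
  stopifnot(tolerance > 0)
  validate_signal_params(params)
  prof <- mean_profiles(params)
  p <- params
  amp <- list(
    winding = p$steer_sd_amplitude,
    speed = p$speed_dip_depth,  # maximal dip depth, attained at t = speed_dip_t
    deceleration = p$decel_amplitude,
    eoff = p$eoff_amplitude,
    pd = p$pd_amplitude,
    hr = p$hr_amplitude,
    sc = prof$sc(0) - prof$sc(Inf)
  )
  tt <- seq(0, horizon, by = dt)
  res <- lapply(to_variables(), function(v) {
    f <- prof[[v]]
    asymptote <- f(1e9)
    dev <- abs(f(tt) - asymptote)
    band <- tolerance * abs(amp[[v]])
    outside <- dev > band
    if (!any(outside)) {
      t_stab <- 0
    } else if (outside[length(tt)]) {
      t_stab <- NA_real_
    } else {
      t_stab <- tt[max(which(outside)) + 1L]
    }
    data.frame(variable = v, time_s = t_stab,
               stabilized_within_horizon = !is.na(t_stab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
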