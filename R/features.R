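#' Build the analysis window grid
#'
#' Windows of a fixed length start every `step` seconds from takeover onset up
#' to `horizon`; each window is the half-open interval `[start, start + length)`.
#' With the defaults (step 2 s, horizon 12 s) there are 7 windows: 2 s windows
#' tile without overlap, 5 s windows overlap.
#'
#' @param window_length Window length in seconds (the study uses 2 and 5).
#' @param step Start spacing in seconds (default 2).
#' @param horizon Last window start in seconds (default 12).
#' @return List of class `to_window_grid` with `starts`, `length`, `step`.
#' @export
#' @examples
#' build_window_grid(2)$starts  # 0 2 4 6 8 10 12
build_window_grid <- function(window_length, step = 2, horizon = 12) {
  if (!(window_length > 0)) stop("window length must be > 0", call. = FALSE)
  if (!(step > 0)) stop("window step must be > 0", call. = FALSE)
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  structure(list(starts = seq(0, horizon, by = step),
                 length = window_length, step = step),
            class = "to_window_grid")
}

#' Detect takeover onset from the driving channels
#'
#' The driver has taken over at the earliest post-TOR time at which the
#' steering wheel deviates more than 2 degrees from its angle at the TOR, the
#' brake pedal exceeds 10%, or the accelerator pedal exceeds its threshold
#' (default 10%, mirroring the brake). If no channel crosses its threshold
#' before automated driving becomes unavailable the takeover is missed.
#'
#' @param recording A `to_recording`.
#' @param tor_time TOR time on the recording's time base (seconds).
#' @param avail_end End of automation availability; defaults to
#'   `tor_time + 5`.
#' @param steer_threshold_deg,brake_threshold_pct,accpedal_threshold_pct
#'   Crossing thresholds.
#' @return List of class `to_onset`: `onset` (seconds after TOR, NA if
#'   missed), `time` (on the recording time base), `action` one of
#'   `"steering"`, `"brake"`, `"accelerator"` or NA, `missed`.
#' @export
detect_takeover_onset <- function(recording, tor_time,
                                  avail_end = tor_time + 5,
                                  steer_threshold_deg = 2,
                                  brake_threshold_pct = 10,
                                  accpedal_threshold_pct = 10) {
  ch <- recording$channels
  need <- c("steering_deg", "brake_pct", "accpedal_pct")
  miss <- setdiff(need, names(ch))
  if (length(miss))
    stop("onset detection requires channels: ", paste(miss, collapse = ", "),
         call. = FALSE)
  first_cross <- function(t, v, pred) {
    keep <- t >= tor_time & t < avail_end & !is.na(v)
    i <- which(keep & pred(v))
    if (length(i)) t[min(i)] else Inf
  }
  st <- ch$steering_deg
  ref_i <- which(st$t >= tor_time & !is.na(st$value))
  steer_ref <- if (length(ref_i)) st$value[min(ref_i)] else NA_real_
  t_steer <- if (is.na(steer_ref)) Inf else
    first_cross(st$t, st$value, function(v) abs(v - steer_ref) > steer_threshold_deg)
  t_brake <- first_cross(ch$brake_pct$t, ch$brake_pct$value,
                         function(v) v > brake_threshold_pct)
  t_acc <- first_cross(ch$accpedal_pct$t, ch$accpedal_pct$value,
                       function(v) v > accpedal_threshold_pct)
  times <- c(steering = t_steer, brake = t_brake, accelerator = t_acc)
  if (all(!is.finite(times))) {
    return(structure(list(onset = NA_real_, time = NA_real_,
                          action = NA_character_, missed = TRUE),
                     class = "to_onset"))
  }
  w <- which.min(times)
  structure(list(onset = times[[w]] - tor_time, time = times[[w]],
                 action = names(times)[w], missed = FALSE),
            class = "to_onset")
}

# samples of channel `ch` falling in [start, start+len) on the re-anchored
# time base (t = 0 at onset)
window_samples <- function(ch, onset_time, start, len) {
  t <- ch$t - onset_time
  sel <- t >= start & t < start + len
  ch$value[sel]
}

#' Compute the seven windowed variables for one takeover event
#'
#' The time base is re-anchored so that `t = 0` at the detected takeover
#' onset. Per window: winding is the sample standard deviation of the steering
#' angle (missing with fewer than 2 samples); speed is the mean speed;
#' deceleration is the mean deceleration magnitude over samples where the
#' longitudinal acceleration is negative while the brake is pressed (missing
#' when no sample qualifies); E-OFF is the fraction of gaze samples off the
#' road; PD is the mean pupil diameter after subtracting the first unmasked
#' pupil sample at or after onset; HR is the mean over unmasked heart-rate
#' samples; SC is the mean phasic skin conductance (clipped at 0). A window
#' with no eligible samples is missing, never zero.
#'
#' @param recording A `to_recording`.
#' @param onset A `to_onset` from [detect_takeover_onset()]; must not be
#'   missed.
#' @param grid A `to_window_grid`.
#' @param variables Which variables to compute (default all seven); computing
#'   `"sc"` triggers the EDA decomposition unless `eda` is supplied.
#' @param eda Optional precomputed `eda_decomposition` for this recording's
#'   `gsr_us` channel.
#' @param pd_baseline Optional externally supplied pupil baseline (mm), e.g. a
#'   per-driver value; default is the per-attempt value at onset.
#' @return Data frame (long form) with columns `event_id`, `variable`,
#'   `window_start_s`, `window_len_s`, `value`, `is_missing`.
#' @export
compute_window_features <- function(recording, onset, grid,
                                    variables = to_variables(), eda = NULL,
                                    pd_baseline = NULL) {
  if (isTRUE(onset$missed))
    stop("cannot compute features for a missed takeover", call. = FALSE)
  ch <- recording$channels
  t0 <- onset$time
  len <- grid$length
  ev <- recording$meta$event_id
  rows <- list()
  add <- function(variable, start, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      event_id = ev, variable = variable, window_start_s = start,
      window_len_s = len,
      value = if (is.na(value)) NA_real_ else as.numeric(value),
      is_missing = is.na(value), stringsAsFactors = FALSE)
  }
  if ("sc" %in% variables && is.null(eda)) {
    gsr_rate <- 1 / stats::median(diff(ch$gsr_us$t))
    eda <- decompose_eda(ch$gsr_us$value, rate = round(gsr_rate))
  }
  if ("pd" %in% variables && is.null(pd_baseline)) {
    tpd <- ch$pd_mm$t - t0
    i0 <- which(tpd >= 0 & !is.na(ch$pd_mm$value))
    pd_baseline <- if (length(i0)) ch$pd_mm$value[min(i0)] else NA_real_
  }
  for (start in grid$starts) {
    if ("winding" %in% variables) {
      v <- window_samples(ch$steering_deg, t0, start, len)
      v <- v[!is.na(v)]
      add("winding", start, if (length(v) >= 2) stats::sd(v) else NA_real_)
    }
    if ("speed" %in% variables) {
      v <- window_samples(ch$speed_kmh, t0, start, len)
      v <- v[!is.na(v)]
      add("speed", start, if (length(v)) mean(v) else NA_real_)
    }
    if ("deceleration" %in% variables) {
      a <- window_samples(ch$accel_ms2, t0, start, len)
      b <- window_samples(ch$brake_pct, t0, start, len)
      m <- min(length(a), length(b))
      if (m) {
        a <- a[seq_len(m)]; b <- b[seq_len(m)]
        elig <- !is.na(a) & !is.na(b) & a < 0 & b > 0
        add("deceleration", start, if (any(elig)) mean(-a[elig]) else NA_real_)
      } else add("deceleration", start, NA_real_)
    }
    if ("eoff" %in% variables) {
      g <- window_samples(ch$gaze_onroad, t0, start, len)
      g <- g[!is.na(g)]
      add("eoff", start, if (length(g)) mean(g == 0) else NA_real_)
    }
    if ("pd" %in% variables) {
      v <- window_samples(ch$pd_mm, t0, start, len)
      v <- v[!is.na(v)]
      add("pd", start, if (length(v) && !is.na(pd_baseline))
        mean(v) - pd_baseline else NA_real_)
    }
    if ("hr" %in% variables) {
      v <- window_samples(ch$hr_bpm, t0, start, len)
      v <- v[!is.na(v)]
      add("hr", start, if (length(v)) mean(v) else NA_real_)
    }
    if ("sc" %in% variables) {
      ph <- list(t = ch$gsr_us$t, value = eda$phasic)
      v <- window_samples(ph, t0, start, len)
      v <- v[!is.na(v)]
      add("sc", start, if (length(v)) max(mean(v), 0) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Compute the window-feature table for a whole dataset
#'
#' Runs onset detection and [compute_window_features()] over every event of a
#' synthetic (or loaded) dataset, for one window grid. Events with a missed
#' takeover are excluded and listed in the `excluded` attribute.
#'
#' @param dataset A `to_dataset` from [generate_study()].
#' @param grid A `to_window_grid`.
#' @param variables Variables to compute (default all seven).
#' @return Long-form feature data frame as in [compute_window_features()],
#'   with attributes `excluded` (character vector of event ids) and
#'   `window_len_s`.
#' @export
compute_feature_table <- function(dataset, grid, variables = to_variables()) {
  out <- vector("list", nrow(dataset$events))
  excluded <- character()
  for (i in seq_len(nrow(dataset$events))) {
    ev <- dataset$events[i, ]
    rec <- dataset$recordings[[ev$event_id]]
    onset <- detect_takeover_onset(rec, tor_time = ev$tor_time,
                                   avail_end = ev$avail_end)
    if (onset$missed) {
      excluded <- c(excluded, ev$event_id)
      next
    }
    out[[i]] <- compute_window_features(rec, onset, grid, variables = variables)
  }
  tab <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(tab, "excluded") <- excluded
  attr(tab, "window_len_s") <- grid$length
  tab
}
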