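# Channel schemas: one CSV per channel, columns t,value; empty value = missing.
# Metadata in metadata.csv (key,value). All analysis timestamps are seconds
# relative to takeover onset (or an arbitrary anchor carried in metadata).

.to_channels <- c("steering_deg", "speed_kmh", "accel_ms2", "brake_pct",
                  "accpedal_pct", "gaze_onroad", "pd_mm", "hr_bpm", "gsr_us")

#' Write a multichannel recording to a directory
#'
#' One `t,value` CSV per channel (missing samples as empty cells) plus a
#' `metadata.csv` with the event id and event-log times. Round-trips
#' losslessly through [read_recording()], including missingness.
#'
#' @param recording A `to_recording`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(recording$channels)) {
    ch <- recording$channels[[nm]]
    df <- data.frame(t = formatC(ch$t, digits = 10, format = "g"),
                     value = ifelse(is.na(ch$value), "",
                                    formatC(ch$value, digits = 10, format = "g")))
    utils::write.csv(df, file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- recording$meta
  md <- data.frame(key = names(meta),
                   value = vapply(meta, function(x) as.character(x), character(1)))
  utils::write.csv(md, file.path(path, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a multichannel recording from a directory
#'
#' Loads the per-channel CSVs written by [write_recording()]. Missing values
#' (empty cells) become NA; readers never impute. Unknown extra columns are
#' ignored with a message. Missing mandatory channels and non-monotone
#' timestamps are errors.
#'
#' @param path Directory containing the channel CSVs.
#' @param channels Channel set to require (default: the nine study channels).
#' @return A `to_recording`.
#' @export
read_recording <- function(path, channels = .to_channels) {
  if (!dir.exists(path)) stop("recording directory not found: ", path, call. = FALSE)
  out <- list()
  for (nm in channels) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f))
      stop("schema error: mandatory channel '", nm, "' missing from ", path,
           call. = FALSE)
    df <- utils::read.csv(f, colClasses = "character")
    if (!all(c("t", "value") %in% names(df)))
      stop("schema error: channel '", nm, "' lacks t,value columns", call. = FALSE)
    extra <- setdiff(names(df), c("t", "value"))
    if (length(extra))
      message("read_recording: ignoring extra columns in ", nm, ": ",
              paste(extra, collapse = ", "))
    t <- as.numeric(df$t)
    v <- suppressWarnings(as.numeric(df$value))
    v[df$value == ""] <- NA_real_
    if (nrow(df) == 0) message("read_recording: channel '", nm, "' is empty")
    if (any(diff(t) <= 0)) {
      bad <- min(which(diff(t) <= 0)) + 1L
      stop("data error: non-monotone timestamps in channel '", nm,
           "' at row ", bad, call. = FALSE)
    }
    out[[nm]] <- list(t = t, value = v)
  }
  meta <- list()
  mf <- file.path(path, "metadata.csv")
  if (file.exists(mf)) {
    md <- utils::read.csv(mf, colClasses = "character")
    meta <- as.list(md$value)
    names(meta) <- md$key
    for (k in c("tor_time", "avail_end"))
      if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
    if (!is.null(meta$gradual_brake)) meta$gradual_brake <- meta$gradual_brake == "TRUE"
  }
  structure(list(channels = out, meta = meta), class = "to_recording")
}

#' Write a window-feature table to CSV
#'
#' Long-form schema `event_id,variable,window_start_s,window_len_s,value,is_missing`
#' in that column order; missing values are empty cells with `is_missing = 1`.
#'
#' @param table Feature data frame (see [compute_window_features()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("event_id", "variable", "window_start_s", "window_len_s",
            "value", "is_missing")
  if (is.null(table) || nrow(table) == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  df <- table[, cols]
  df$value <- ifelse(df$is_missing, "", formatC(df$value, digits = 10, format = "g"))
  df$is_missing <- as.integer(df$is_missing)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a window-feature table from CSV
#'
#' @param path File written by [write_feature_table()].
#' @return Feature data frame with NA values where `is_missing = 1`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(event_id = "character",
                                             variable = "character",
                                             value = "character"))
  if (nrow(df) == 0) {
    return(data.frame(event_id = character(), variable = character(),
                      window_start_s = numeric(), window_len_s = numeric(),
                      value = numeric(), is_missing = logical(),
                      stringsAsFactors = FALSE))
  }
  val <- suppressWarnings(as.numeric(df$value))
  val[df$value == ""] <- NA_real_
  data.frame(event_id = df$event_id, variable = df$variable,
             window_start_s = df$window_start_s,
             window_len_s = df$window_len_s,
             value = val, is_missing = df$is_missing == 1,
             stringsAsFactors = FALSE)
}

#' Write the event log
#'
#' @param events Event data frame from [generate_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  cols <- intersect(c("event_id", "study", "driver", "trial", "to_index",
                      "tor_time", "avail_end", "reaction_time", "gradual_brake"),
                    names(events))
  utils::write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the ground-truth table
#'
#' @param gt Ground-truth data frame from [ground_truth_for()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.csv(gt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
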