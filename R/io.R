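# Plain-text (CSV) readers and writers for LFP traces, tracking data,
# choice sequences and event catalogs.

#' Write / read an LFP trace as CSV
#'
#' Two columns: `time_s`, `value`. Metadata (sample rate, channel, subject,
#' session) is stored in `#`-prefixed header comment lines so a single file
#' round-trips to an identical object.
#'
#' @param lfp A `raw_lfp` object.
#' @param path File path.
#' @return `write_lfp_csv` returns `path` invisibly; `read_lfp_csv` returns
#'   a `raw_lfp`.
#' @export
write_lfp_csv <- function(lfp, path) {
  stopifnot(inherits(lfp, "raw_lfp"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sample_rate: %.10g", lfp$sample_rate),
               sprintf("# channel: %s", lfp$channel),
               sprintf("# subject_id: %s", lfp$subject_id),
               sprintf("# session_id: %s", lfp$session_id)), con)
  n <- length(lfp$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / lfp$sample_rate,
                   value = lfp$samples)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Parse "# key: value" comment headers from the top of a CSV file.
read_csv_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  meta <- read_csv_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  fs <- if (!is.null(meta$sample_rate)) as.numeric(meta$sample_rate) else {
    1 / stats::median(diff(df$time_s))
  }
  raw_lfp(df$value, fs,
          channel = meta$channel %||% "unknown",
          subject_id = meta$subject_id %||% "unknown",
          session_id = meta$session_id %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a tracking trace as CSV
#'
#' Columns `time_s`, `x_cm`, `y_cm`; frame rate and arena dimensions in
#' `#` header comments.
#'
#' @param track A `tracking_trace`.
#' @param path File path.
#' @return `write_tracking_csv` returns `path` invisibly;
#'   `read_tracking_csv` a `tracking_trace`.
#' @export
write_tracking_csv <- function(track, path) {
  stopifnot(inherits(track, "tracking_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_rate: %.10g", track$frame_rate),
               sprintf("# arena_width: %.10g", track$arena_width),
               sprintf("# arena_length: %.10g", track$arena_length)), con)
  utils::write.csv(data.frame(time_s = track$times, x_cm = track$x,
                              y_cm = track$y), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @export
read_tracking_csv <- function(path) {
  meta <- read_csv_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  fr <- if (!is.null(meta$frame_rate)) as.numeric(meta$frame_rate) else {
    1 / stats::median(diff(df$time_s))
  }
  tracking_trace(df$time_s, df$x_cm, df$y_cm, frame_rate = fr,
                 arena_width = as.numeric(meta$arena_width %||% "20"),
                 arena_length = as.numeric(meta$arena_length %||% "40"))
}

#' Write / read a T-maze choice table as CSV
#'
#' Columns `trial`, `first_arm`, `second_arm`, `alternated`.
#'
#' @param choices Data frame as produced by [generate_alternation()].
#' @param path File path.
#' @return `write_choices_csv` returns `path` invisibly; `read_choices_csv`
#'   the data frame.
#' @export
write_choices_csv <- function(choices, path) {
  utils::write.csv(choices, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices_csv
#' @export
read_choices_csv <- function(path) {
  df <- utils::read.csv(path)
  df$alternated <- as.logical(df$alternated)
  df
}

#' Write an SWR event catalog as CSV
#'
#' One row per event (`start_s`, `end_s`, `duration_ms`, `peak_z`,
#' `peak_time_s`); the analyzed duration, incidence and period label go in
#' `#` header comments.
#'
#' @param catalog An `swr_catalog`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_swr_csv <- function(catalog, path) {
  stopifnot(inherits(catalog, "swr_catalog"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# analyzed_duration_s: %.10g",
                       catalog$analyzed_duration_s),
               sprintf("# incidence_hz: %.10g", catalog$incidence_hz),
               sprintf("# period_label: %s", catalog$period_label)), con)
  utils::write.csv(catalog$events, con, row.names = FALSE)
  invisible(path)
}
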