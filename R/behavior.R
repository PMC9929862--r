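# Behavioral measures: speed, movement/stationary epochs, open-field
# mobility and periphery statistics, T-maze spontaneous alternation.

#' Construct a tracking trace
#'
#' @param times Frame times in seconds, strictly increasing.
#' @param x,y Positions in cm.
#' @param frame_rate Frame rate in Hz.
#' @param arena_width,arena_length Arena dimensions in cm.
#' @param tol Out-of-bounds tolerance in cm for tracking jitter.
#' @return An object of class `tracking_trace`.
#' @export
tracking_trace <- function(times, x, y, frame_rate = 25, arena_width = 20,
                           arena_length = 40, tol = 0.5) {
  if (length(times) != length(x) || length(x) != length(y)) {
    stop("times, x, y must have equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(x < -tol | x > arena_width + tol) ||
      any(y < -tol | y > arena_length + tol)) {
    stop("positions fall outside the arena beyond the ", tol, " cm tolerance")
  }
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), frame_rate = frame_rate,
                 arena_width = arena_width, arena_length = arena_length),
            class = "tracking_trace")
}

#' @export
print.tracking_trace <- function(x, ...) {
  cat(sprintf("<tracking_trace> %d frames @ %g Hz in %g x %g cm arena\n",
              length(x$times), x$frame_rate, x$arena_width, x$arena_length))
  invisible(x)
}

#' Frame-by-frame movement speed
#'
#' Euclidean displacement between consecutive frames times the frame rate,
#' optionally smoothed by a centered moving average to suppress tracking
#' jitter. The first value is duplicated so the series aligns 1:1 with
#' frames.
#'
#' @param track A [tracking_trace()] object.
#' @param smooth_window_s Moving-average window in seconds (0 disables).
#' @return Speed series in cm/s, one value per frame.
#' @export
compute_speed <- function(track, smooth_window_s = 0.2) {
  stopifnot(inherits(track, "tracking_trace"))
  if (length(track$times) < 2) stop("need at least 2 frames")
  disp <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  speed <- c(disp[1], disp) * track$frame_rate
  if (smooth_window_s > 0) {
    k <- round(smooth_window_s * track$frame_rate)
    if (k > 1) speed <- moving_average(speed, k)
  }
  speed
}

#' Segment a speed series into movement and stationary epochs
#'
#' Maximal runs with speed at or above `threshold` lasting at least `min_dur_s`
#' become movement epochs; maximal sub-threshold runs of the same minimum
#' duration become stationary epochs; shorter runs belong to no epoch.
#' A speed of exactly `threshold` counts as movement.
#'
#' @param speed Speed series (cm/s) on the frame clock.
#' @param frame_rate Frame rate in Hz.
#' @param threshold Movement threshold, cm/s (default 5).
#' @param min_dur_s Minimum epoch duration, seconds (default 1).
#' @return An `epoch_set`: data frame with `start_s`, `end_s`, `state`
#'   (`"movement"`/`"stationary"`), frame rate stored as an attribute.
#' @export
segment_epochs <- function(speed, frame_rate = 25, threshold = 5,
                           min_dur_s = 1) {
  moving <- speed >= threshold
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_dur_s * frame_rate
  ep <- data.frame(
    start_s = (starts[keep] - 1) / frame_rate,
    end_s = ends[keep] / frame_rate,
    state = ifelse(r$values[keep], "movement", "stationary"),
    stringsAsFactors = FALSE)
  structure(ep, frame_rate = frame_rate, threshold = threshold,
            class = c("epoch_set", "data.frame"))
}

#' Equal-area periphery band depth for a rectangular arena
#'
#' Depth `d` of the wall band such that the band and the remaining center
#' have equal area: `(W - 2d)(L - 2d) = W*L/2`, taking the root below
#' `min(W, L)/2`.
#'
#' @param arena_width,arena_length Arena dimensions in cm.
#' @return Band depth in cm.
#' @examples
#' periphery_depth(20, 40)  # (30 - sqrt(500)) / 2
#' @export
periphery_depth <- function(arena_width, arena_length) {
  W <- arena_width
  L <- arena_length
  disc <- (W + L)^2 - 2 * W * L
  d <- ((W + L) - sqrt(disc)) / 4
  if (!is.finite(d) || d <= 0 || d >= min(W, L) / 2) {
    stop("arena too small for an equal-area periphery band")
  }
  d
}

#' Classify frames as periphery or center
#'
#' The periphery is the equal-area band nearest the walls (the half of the
#' environment closest to the walls); the center is its complement.
#'
#' @param track A [tracking_trace()] object.
#' @return Character vector, `"periphery"` or `"center"`, per frame.
#' @export
classify_region <- function(track) {
  stopifnot(inherits(track, "tracking_trace"))
  d <- periphery_depth(track$arena_width, track$arena_length)
  per <- track$x < d | track$x > track$arena_width - d |
    track$y < d | track$y > track$arena_length - d
  ifelse(per, "periphery", "center")
}

#' Open-field mobility statistics
#'
#' Time spent mobile (as a percentage of total time), median running speed
#' during movement, and the same quantities split by periphery/center, plus
#' periphery occupancy. Medians are computed over movement-epoch frames
#' only. Regions with zero occupancy yield `NA` (undefined), never 0.
#'
#' @param track A [tracking_trace()] object.
#' @param speed Speed series from [compute_speed()].
#' @param epochs An `epoch_set` from [segment_epochs()].
#' @param regions Per-frame labels from [classify_region()] (computed if
#'   omitted).
#' @return A list of class `mobility_stats`.
#' @export
mobility_statistics <- function(track, speed, epochs,
                                regions = classify_region(track)) {
  stopifnot(inherits(track, "tracking_trace"), inherits(epochs, "epoch_set"))
  n <- length(track$times)
  fr <- track$frame_rate
  frame_t <- (seq_len(n) - 1) / fr
  mov <- epochs[epochs$state == "movement", , drop = FALSE]
  in_mov <- rep(FALSE, n)
  for (k in seq_len(nrow(mov))) {
    in_mov[frame_t >= mov$start_s[k] & frame_t < mov$end_s[k]] <- TRUE
  }
  total_s <- n / fr
  mobile_s <- sum(mov$end_s - mov$start_s)
  per <- regions == "periphery"
  pct_or_na <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  med_or_na <- function(v) if (length(v) > 0) stats::median(v) else NA_real_
  structure(list(
    pct_time_mobile = 100 * mobile_s / total_s,
    median_speed_mobile = med_or_na(speed[in_mov]),
    pct_mobile_periphery = pct_or_na(sum(in_mov & per), sum(per)),
    pct_mobile_center = pct_or_na(sum(in_mov & !per), sum(!per)),
    median_speed_periphery = med_or_na(speed[in_mov & per]),
    median_speed_center = med_or_na(speed[in_mov & !per]),
    periphery_occupancy = mean(per)),
    class = "mobility_stats")
}

#' @export
print.mobility_stats <- function(x, ...) {
  cat(sprintf(
    "<mobility_stats> %.1f%% mobile; median mobile speed %.1f cm/s; periphery occupancy %.2f\n",
    x$pct_time_mobile, x$median_speed_mobile, x$periphery_occupancy))
  invisible(x)
}

#' Spontaneous-alternation rate
#'
#' Fraction of completed trials on which the second arm choice differs from
#' the first. Trials with a missing second choice are excluded from the
#' denominator.
#'
#' @param choices Data frame with columns `first_arm` and `second_arm`
#'   (values `"L"`/`"R"`; `NA` second choice = incomplete trial).
#' @return A list of class `alternation_record` with `trials` (completed
#'   trials), `n_trials` and `alternation_rate`.
#' @export
alternation_rate <- function(choices) {
  stopifnot(is.data.frame(choices),
            all(c("first_arm", "second_arm") %in% names(choices)))
  ok_arm <- function(a) is.na(a) | a %in% c("L", "R")
  if (!all(ok_arm(choices$first_arm)) || !all(ok_arm(choices$second_arm))) {
    stop("arm labels must be 'L' or 'R'")
  }
  done <- choices[!is.na(choices$first_arm) & !is.na(choices$second_arm), ,
                  drop = FALSE]
  if (nrow(done) < 1) stop("need at least one completed trial")
  structure(list(trials = done, n_trials = nrow(done),
                 alternation_rate = mean(done$first_arm != done$second_arm)),
            class = "alternation_record")
}

#' @export
print.alternation_record <- function(x, ...) {
  cat(sprintf("<alternation_record> %d trials, alternation rate %.3f\n",
              x$n_trials, x$alternation_rate))
  invisible(x)
}
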