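# Sharp-wave ripple detection: ripple-band envelope extraction, event
# detection with merge/duration/peak rules, incidence rates and
# baseline-normalized changes.

#' Z-scored ripple-band envelope
#'
#' Band-pass filters the pre-processed signal in the ripple band (default
#' 150-250 Hz; with a 512 Hz recording and a 160 Hz acquisition low-pass,
#' real ripple energy sits in 150-160 Hz, but the detector is agnostic),
#' extracts the Hilbert envelope, smooths it with a Gaussian kernel
#' (default FWHM 15 ms) and z-scores over unmasked samples.
#'
#' @param clean A `clean_lfp` object from [preprocess_lfp()].
#' @param band_lo,band_hi Band edges in Hz; `band_hi` defaults to just below
#'   Nyquist, capped at 250 Hz.
#' @param smooth_ms Gaussian smoothing FWHM in ms.
#' @return Numeric z-scored envelope with attributes `sample_rate` and
#'   `mask`.
#' @export
ripple_envelope <- function(clean, band_lo = 150, band_hi = NULL,
                            smooth_ms = 15) {
  stopifnot(inherits(clean, "clean_lfp"))
  fs <- clean$sample_rate
  if (is.null(band_hi)) band_hi <- min(250, fs / 2 - 2)
  if (band_hi > fs / 2) stop("band_hi must not exceed Nyquist")
  if (mean(clean$artifact_mask) >= 0.5) {
    stop("more than half of the recording is masked; envelope z-scores ",
         "would be meaningless")
  }
  xf <- fir_zerophase(clean$samples,
                      design_fir(400, c(band_lo, band_hi), fs, "pass"))
  env <- Mod(hilbert_analytic(xf))
  env <- gaussian_smooth(env, fwhm_to_sigma(smooth_ms / 1000) * fs)
  z <- zscore_masked(env, clean$artifact_mask)
  attr(z, "sample_rate") <- fs
  attr(z, "mask") <- clean$artifact_mask
  z
}

#' Detect sharp-wave ripple events in a z-scored envelope
#'
#' Candidate events are maximal contiguous regions with envelope `Z >= 0`
#' that last at least `min_dur_ms` and contain a sample with
#' `Z >= peak_z`. Candidates separated by at most `merge_gap_ms` are merged
#' (the merged event spans the gap), merged events with duration
#' `>= max_dur_ms` are discarded, and events overlapping the artifact mask
#' are discarded with their duration removed from the analyzed time.
#'
#' @param envelope Z-scored envelope from [ripple_envelope()], or any numeric
#'   series with `sample_rate` given.
#' @param sample_rate Sampling rate in Hz (taken from the envelope attribute
#'   if present).
#' @param min_dur_ms Minimum candidate duration, ms (default 40).
#' @param peak_z Peak threshold in z-units (default 3).
#' @param merge_gap_ms Maximum gap between candidates to merge, ms
#'   (default 40).
#' @param max_dur_ms Durations at or above this are discarded, ms
#'   (default 500).
#' @param mask Optional logical artifact mask (taken from the envelope
#'   attribute if present).
#' @param period_label Label stored on the catalog
#'   (`"baseline"`, `"consolidation"`, `"other"`).
#' @return An `swr_catalog`: data frame `events` (`start_s`, `end_s`,
#'   `duration_ms`, `peak_z`, `peak_time_s`), `analyzed_duration_s`
#'   (unmasked time), `incidence_hz`, `period_label`; the mask and sample
#'   rate ride along for period-restricted rates.
#' @export
detect_swr_events <- function(envelope, sample_rate = NULL, min_dur_ms = 40,
                              peak_z = 3, merge_gap_ms = 40,
                              max_dur_ms = 500, mask = NULL,
                              period_label = "other") {
  fs <- if (!is.null(sample_rate)) sample_rate else attr(envelope, "sample_rate")
  if (is.null(fs)) stop("sample_rate must be supplied")
  if (is.null(mask)) mask <- attr(envelope, "mask")
  z <- as.numeric(envelope)
  n <- length(z)
  if (is.null(mask)) mask <- rep(FALSE, n)

  r <- rle(z >= 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)
  # candidates: >= min_dur regions with a qualifying peak
  cand <- matrix(integer(0), ncol = 2)
  for (k in pos) {
    if (r$lengths[k] < min_dur_ms / 1000 * fs) next
    if (max(z[starts[k]:ends[k]]) < peak_z) next
    cand <- rbind(cand, c(starts[k], ends[k]))
  }
  # merge candidates separated by <= merge_gap_ms
  if (nrow(cand) > 1) {
    merged <- cand[1, , drop = FALSE]
    for (k in 2:nrow(cand)) {
      gap <- (cand[k, 1] - merged[nrow(merged), 2] - 1) / fs * 1000
      if (gap <= merge_gap_ms) {
        merged[nrow(merged), 2] <- cand[k, 2]
      } else {
        merged <- rbind(merged, cand[k, , drop = FALSE])
      }
    }
    cand <- merged
  }
  events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       duration_ms = numeric(0), peak_z = numeric(0),
                       peak_time_s = numeric(0))
  for (k in seq_len(nrow(cand))) {
    i0 <- cand[k, 1]
    i1 <- cand[k, 2]
    dur_ms <- (i1 - i0 + 1) / fs * 1000
    if (dur_ms >= max_dur_ms) next
    if (any(mask[i0:i1])) next
    ipk <- i0 - 1L + which.max(z[i0:i1])
    events <- rbind(events, data.frame(
      start_s = (i0 - 1) / fs, end_s = i1 / fs, duration_ms = dur_ms,
      peak_z = z[ipk], peak_time_s = (ipk - 0.5) / fs))
  }
  analyzed <- sum(!mask) / fs
  structure(list(events = events, analyzed_duration_s = analyzed,
                 incidence_hz = nrow(events) / analyzed,
                 period_label = period_label, sample_rate = fs, mask = mask,
                 settings = list(min_dur_ms = min_dur_ms, peak_z = peak_z,
                                 merge_gap_ms = merge_gap_ms,
                                 max_dur_ms = max_dur_ms)),
            class = "swr_catalog")
}

#' Detect ripples directly from a pre-processed LFP
#'
#' Convenience composition of [ripple_envelope()] and [detect_swr_events()].
#'
#' @param clean A `clean_lfp` object.
#' @param band_lo,band_hi,smooth_ms See [ripple_envelope()].
#' @param ... Passed to [detect_swr_events()].
#' @return An `swr_catalog`.
#' @export
detect_swr <- function(clean, band_lo = 150, band_hi = NULL, smooth_ms = 15,
                       ...) {
  env <- ripple_envelope(clean, band_lo = band_lo, band_hi = band_hi,
                         smooth_ms = smooth_ms)
  detect_swr_events(env, ...)
}

#' @export
print.swr_catalog <- function(x, ...) {
  cat(sprintf(
    "<swr_catalog> %d events in %.1f unmasked s (%.3f Hz), period '%s'\n",
    nrow(x$events), x$analyzed_duration_s, x$incidence_hz, x$period_label))
  invisible(x)
}

#' @export
plot.swr_catalog <- function(x, ...) {
  if (!nrow(x$events)) {
    graphics::plot.new()
    graphics::title("no SWR events")
    return(invisible(x))
  }
  graphics::plot(x$events$peak_time_s, x$events$peak_z,
                 xlab = "time (s)", ylab = "peak z", pch = 16, ...)
  invisible(x)
}

#' SWR incidence rate within a period
#'
#' Events with `peak_time_s` inside the period divided by the unmasked
#' seconds in the period.
#'
#' @param catalog An `swr_catalog`.
#' @param period `c(start_s, end_s)`, or `NULL` for the whole recording.
#' @return Events per second (`NA` if the period holds no unmasked time).
#' @export
incidence_rate <- function(catalog, period = NULL) {
  stopifnot(inherits(catalog, "swr_catalog"))
  if (is.null(period)) return(catalog$incidence_hz)
  fs <- catalog$sample_rate
  i0 <- max(1L, floor(period[1] * fs) + 1L)
  i1 <- min(length(catalog$mask), ceiling(period[2] * fs))
  unmasked_s <- sum(!catalog$mask[i0:i1]) / fs
  if (unmasked_s <= 0) return(NA_real_)
  k <- sum(catalog$events$peak_time_s >= period[1] &
             catalog$events$peak_time_s < period[2])
  k / unmasked_s
}

#' Change in SWR incidence normalized to baseline
#'
#' Relative change `(consolidation - baseline) / baseline`: 0 means no
#' change, +0.5 a 50% increase. Undefined (`NA`) when the baseline rate is
#' zero, never infinite. Set `ratio = TRUE` for the plain ratio instead.
#'
#' @param baseline,consolidation `swr_catalog` objects for the two periods.
#' @param ratio Report `consolidation / baseline` instead of the relative
#'   change.
#' @return Dimensionless change (or `NA`).
#' @export
normalized_change <- function(baseline, consolidation, ratio = FALSE) {
  stopifnot(inherits(baseline, "swr_catalog"),
            inherits(consolidation, "swr_catalog"))
  b <- baseline$incidence_hz
  cc <- consolidation$incidence_hz
  if (!is.finite(b) || b <= 0) return(NA_real_)
  if (ratio) cc / b else (cc - b) / b
}

#' Mean event features of an SWR catalog
#'
#' @param catalog An `swr_catalog`.
#' @return List with `mean_peak_z`, `mean_duration_ms`, `n_events`
#'   (`NA` features for an empty catalog).
#' @export
event_features <- function(catalog) {
  stopifnot(inherits(catalog, "swr_catalog"))
  ev <- catalog$events
  if (!nrow(ev)) {
    return(list(mean_peak_z = NA_real_, mean_duration_ms = NA_real_,
                n_events = 0L))
  }
  list(mean_peak_z = mean(ev$peak_z),
       mean_duration_ms = mean(ev$duration_ms),
       n_events = nrow(ev))
}
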