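# Theta-gamma phase-amplitude coupling: filter-Hilbert phase/amplitude
# extraction, 20-bin phase-amplitude distributions, resultant vector length,
# comodulograms, and illustrative Morlet cross-coherence images.

#' Band-limited instantaneous phase and amplitude
#'
#' Zero-phase FIR band-pass followed by the Hilbert analytic signal. The
#' filter order is scaled down to `floor(length/3)` (rounded to even) when
#' the series is too short for the default 400 taps, so short epochs remain
#' analyzable.
#'
#' @param samples Real numeric series.
#' @param band Length-2 band edges in Hz, ascending, inside (0, Nyquist).
#' @param sample_rate Sampling rate, Hz.
#' @param order Target FIR order (default 400).
#' @return List with `phase` (radians, wrapped to (-pi, pi]), `amplitude`
#'   (envelope, a.u.) and the `order` actually used.
#' @examples
#' fs <- 512; t <- seq(0, 4, by = 1 / fs)
#' a <- analytic_signal(sin(2 * pi * 8 * t), c(6, 12), fs)
#' range(a$amplitude[500:1000])
#' @export
analytic_signal <- function(samples, band, sample_rate, order = 400) {
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("band edges must be ascending (lo < hi)")
  }
  n <- length(samples)
  use_order <- min(order, floor((n - 1) / 3))
  use_order <- use_order - (use_order %% 2)
  if (use_order < 8) stop("series too short for band-pass filtering")
  h <- design_fir(use_order, band, sample_rate, type = "pass")
  xf <- fir_zerophase(samples, h)
  a <- hilbert_analytic(xf)
  list(phase = Arg(a), amplitude = Mod(a), order = use_order)
}

#' Phase-binned amplitude distribution
#'
#' Mean amplitude of the fast signal in each of `n_bins` evenly spaced phase
#' bins of the slow signal, normalized to a probability distribution
#' (weights sum to 1), making the downstream resultant vector length
#' amplitude-scale invariant.
#'
#' @param phase Phase series in radians, wrapped to (-pi, pi].
#' @param amplitude Amplitude series aligned with `phase`.
#' @param mask Optional logical series; `TRUE` samples are excluded.
#' @param n_bins Number of phase bins (default 20).
#' @return A `phase_amp_distribution`: `bin_centers`, `mean_amp`, `weights`,
#'   `n_samples`; or a `rejected_epoch` sentinel if any bin is empty.
#' @export
phase_amplitude_distribution <- function(phase, amplitude, mask = NULL,
                                         n_bins = 20) {
  if (length(phase) != length(amplitude)) {
    stop("phase and amplitude must align")
  }
  keep <- if (is.null(mask)) rep(TRUE, length(phase)) else !mask
  ph <- phase[keep]
  am <- amplitude[keep]
  width <- 2 * pi / n_bins
  idx <- ceiling((ph + pi) / width)
  idx[idx < 1L] <- 1L      # phase exactly -pi
  idx[idx > n_bins] <- n_bins
  cnt <- tabulate(idx, nbins = n_bins)
  if (any(cnt == 0)) {
    return(reject_epoch("empty phase bin"))
  }
  sums <- unname(vapply(split(am, factor(idx, levels = seq_len(n_bins))), sum,
                        numeric(1)))
  mean_amp <- sums / cnt
  centers <- -pi + (seq_len(n_bins) - 0.5) * width
  structure(list(bin_centers = centers, mean_amp = mean_amp,
                 weights = mean_amp / sum(mean_amp),
                 n_samples = length(ph)),
            class = "phase_amp_distribution")
}

#' Resultant vector length of a phase-amplitude distribution
#'
#' Magnitude of the weighted circular mean
#' `| sum_j w_j exp(i * theta_j) |`, in `[0, 1]`: 0 for a uniform
#' distribution, 1 when all amplitude concentrates in one phase bin.
#'
#' @param dist A `phase_amp_distribution`.
#' @return Dimensionless coupling strength in `[0, 1]`.
#' @export
resultant_vector_length <- function(dist) {
  stopifnot(inherits(dist, "phase_amp_distribution"))
  Mod(sum(dist$weights * exp(1i * dist$bin_centers)))
}

#' Phase-amplitude coupling across epochs
#'
#' Band-passes the continuous cleaned signal in the phase and amplitude
#' bands (filtering the whole session avoids epoch-edge transients), then
#' computes the resultant vector length of the 20-bin phase-amplitude
#' distribution within each epoch and averages across epochs.
#'
#' @param clean A `clean_lfp` object.
#' @param epochs An `epoch_set`, a two-column matrix/data frame of
#'   `start_s`/`end_s`, or `NULL` for the whole session. If an `epoch_set`,
#'   only epochs matching `state` are used.
#' @param phase_band Slow (phase) band in Hz, default theta 6-12.
#' @param amp_band Fast (amplitude) band in Hz, default gamma 60-120.
#' @param state Epoch state to analyze when `epochs` is an `epoch_set`.
#' @param n_bins Number of phase bins.
#' @return A `pac_result`: `rvl_per_epoch`, `mean_rvl` (`NA` when no epoch
#'   is usable), bands, and counts of used/rejected epochs.
#' @export
pac_for_epochs <- function(clean, epochs = NULL, phase_band = c(6, 12),
                           amp_band = c(60, 120), state = "movement",
                           n_bins = 20) {
  stopifnot(inherits(clean, "clean_lfp"))
  fs <- clean$sample_rate
  iv <- epochs_to_intervals(epochs, length(clean$samples) / fs, state)
  slow <- analytic_signal(clean$samples, phase_band, fs)
  fast <- analytic_signal(clean$samples, amp_band, fs)
  rvl <- numeric(0)
  rejected <- 0L
  for (k in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv[k, 1] * fs) + 1L)
    i1 <- min(length(clean$samples), ceiling(iv[k, 2] * fs))
    if (i1 <= i0) next
    idx <- i0:i1
    d <- phase_amplitude_distribution(slow$phase[idx], fast$amplitude[idx],
                                      mask = clean$artifact_mask[idx],
                                      n_bins = n_bins)
    if (is_rejected(d)) {
      rejected <- rejected + 1L
      next
    }
    rvl <- c(rvl, resultant_vector_length(d))
  }
  structure(list(phase_band = phase_band, amp_band = amp_band,
                 rvl_per_epoch = rvl,
                 mean_rvl = if (length(rvl)) mean(rvl) else NA_real_,
                 n_epochs_used = length(rvl), n_epochs_rejected = rejected),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf(
    "<pac_result> phase %g-%g Hz x amp %g-%g Hz: mean RVL %.4f over %d epoch(s)\n",
    x$phase_band[1], x$phase_band[2], x$amp_band[1], x$amp_band[2],
    x$mean_rvl, x$n_epochs_used))
  invisible(x)
}

# Normalize the many accepted epoch representations to a start/end matrix.
epochs_to_intervals <- function(epochs, session_dur_s, state = NULL) {
  if (is.null(epochs)) {
    return(matrix(c(0, session_dur_s), ncol = 2,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  }
  if (inherits(epochs, "epoch_set")) {
    e <- epochs
    if (!is.null(state)) e <- e[e$state == state, , drop = FALSE]
    return(cbind(start_s = e$start_s, end_s = e$end_s))
  }
  e <- as.matrix(epochs)
  if (ncol(e) < 2) stop("epochs must provide start and end columns")
  cbind(start_s = e[, 1], end_s = e[, 2])
}

#' Comodulogram over grids of phase and amplitude bands
#'
#' Resultant vector length for every (phase band, amplitude band) pair.
#' Each distinct band is filtered once over the continuous signal, then
#' binned per epoch, so the cost is linear in the number of distinct bands.
#'
#' @param clean A `clean_lfp` object.
#' @param epochs Epochs as in [pac_for_epochs()].
#' @param phase_grid,amp_grid Two-column matrices (or lists of length-2
#'   vectors) of band edges in Hz. Defaults: phase bands of width 4 Hz
#'   centered 2-20 Hz in 2 Hz steps; amplitude bands of width 20 Hz
#'   centered 40-150 Hz in 10 Hz steps.
#' @param state,n_bins As in [pac_for_epochs()].
#' @return A `comodulogram`: `phase_bands`, `amp_bands`, `rvl_matrix`
#'   (rows = amplitude bands, cols = phase bands).
#' @export
comodulogram <- function(clean, epochs = NULL, phase_grid = NULL,
                         amp_grid = NULL, state = "movement", n_bins = 20) {
  stopifnot(inherits(clean, "clean_lfp"))
  fs <- clean$sample_rate
  if (is.null(phase_grid)) {
    ctr <- seq(4, 20, by = 2)
    phase_grid <- cbind(ctr - 2, ctr + 2)
  }
  if (is.null(amp_grid)) {
    ctr <- seq(40, min(150, fs / 2 - 15), by = 10)
    amp_grid <- cbind(ctr - 10, ctr + 10)
  }
  pg <- band_matrix(phase_grid)
  ag <- band_matrix(amp_grid)
  iv <- epochs_to_intervals(epochs, length(clean$samples) / fs, state)
  phases <- lapply(seq_len(nrow(pg)), function(i) {
    analytic_signal(clean$samples, pg[i, ], fs)$phase
  })
  amps <- lapply(seq_len(nrow(ag)), function(j) {
    analytic_signal(clean$samples, ag[j, ], fs)$amplitude
  })
  m <- matrix(NA_real_, nrow = nrow(ag), ncol = nrow(pg))
  for (i in seq_len(nrow(pg))) {
    for (j in seq_len(nrow(ag))) {
      rvl <- numeric(0)
      for (k in seq_len(nrow(iv))) {
        i0 <- max(1L, floor(iv[k, 1] * fs) + 1L)
        i1 <- min(length(clean$samples), ceiling(iv[k, 2] * fs))
        if (i1 <= i0) next
        idx <- i0:i1
        d <- phase_amplitude_distribution(phases[[i]][idx], amps[[j]][idx],
                                          mask = clean$artifact_mask[idx],
                                          n_bins = n_bins)
        if (!is_rejected(d)) rvl <- c(rvl, resultant_vector_length(d))
      }
      m[j, i] <- if (length(rvl)) mean(rvl) else NA_real_
    }
  }
  structure(list(phase_bands = pg, amp_bands = ag, rvl_matrix = m),
            class = "comodulogram")
}

band_matrix <- function(g) {
  if (is.list(g)) g <- do.call(rbind, g)
  g <- as.matrix(g)
  if (ncol(g) != 2 || any(g[, 1] >= g[, 2])) {
    stop("band grid must be two ascending columns (lo, hi)")
  }
  unname(g)
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d amplitude x %d phase bands, max RVL %.4f\n",
              nrow(x$rvl_matrix), ncol(x$rvl_matrix),
              max(x$rvl_matrix, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  pc <- rowMeans(x$phase_bands)
  ac <- rowMeans(x$amp_bands)
  graphics::image(pc, ac, t(x$rvl_matrix), xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Morlet wavelet power time series
#'
#' Convolves the signal with a complex Morlet wavelet of `n_cycles` cycles
#' (`sigma_t = n_cycles / (2 pi f)`) and returns squared magnitude.
#'
#' @param samples Real series.
#' @param freq Center frequency, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @param n_cycles Wavelet width in cycles (default 5).
#' @return Power time series, same length as `samples`.
#' @export
morlet_power <- function(samples, freq, sample_rate, n_cycles = 5) {
  sig_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sig_t * sample_rate)
  tt <- seq(-half, half) / sample_rate
  w <- exp(-tt^2 / (2 * sig_t^2)) * exp(1i * 2 * pi * freq * tt)
  w <- w / sum(Mod(w))
  n <- length(samples)
  nf <- stats::nextn(n + length(w), c(2, 3, 5))
  conv <- stats::fft(stats::fft(c(samples, numeric(nf - n))) *
                       stats::fft(c(w, numeric(nf - length(w)))),
                     inverse = TRUE) / nf
  Mod(conv[(half + 1):(half + n)])^2
}

#' Cross-coherence between raw LFP and band-limited power time series
#'
#' For each frequency on `freq_grid`, computes the Morlet power time series
#' of the cleaned signal, then the magnitude-squared coherence between the
#' raw signal and that power series over low frequencies, averaged across
#' epochs. High coherence of gamma-power rows at the theta frequency is the
#' signature of theta-gamma coupling.
#'
#' @param clean A `clean_lfp` object.
#' @param epochs Epochs as in [pac_for_epochs()].
#' @param freq_grid Wavelet center frequencies in Hz.
#' @param n_cycles Morlet wavelet cycles (default 5).
#' @param coh_freqs Coherence frequency grid in Hz (default 0.5-20 in 0.5
#'   steps).
#' @param spans Smoothing spans passed to [stats::spec.pgram()] (coherence
#'   needs cross-spectral smoothing).
#' @param state Epoch state when `epochs` is an `epoch_set`.
#' @return A `crosscoherence`: `freq_grid`, `coh_freqs`, `coherence` matrix
#'   (rows = wavelet frequencies), `n_epochs_used`.
#' @export
wavelet_crosscoherence <- function(clean, epochs = NULL,
                                   freq_grid = seq(20, 140, by = 10),
                                   n_cycles = 5,
                                   coh_freqs = seq(0.5, 20, by = 0.5),
                                   spans = 11, state = "movement") {
  stopifnot(inherits(clean, "clean_lfp"))
  fs <- clean$sample_rate
  iv <- epochs_to_intervals(epochs, length(clean$samples) / fs, state)
  acc <- matrix(0, nrow = length(freq_grid), ncol = length(coh_freqs))
  used <- 0L
  power_series <- lapply(freq_grid, function(f) {
    morlet_power(clean$samples, f, fs, n_cycles)
  })
  for (k in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv[k, 1] * fs) + 1L)
    i1 <- min(length(clean$samples), ceiling(iv[k, 2] * fs))
    # epoch must hold >= n_cycles of the slowest wavelet frequency
    if ((i1 - i0 + 1) / fs < n_cycles / min(freq_grid)) next
    idx <- i0:i1
    ep <- matrix(0, nrow = length(freq_grid), ncol = length(coh_freqs))
    for (r in seq_along(freq_grid)) {
      sp <- stats::spec.pgram(
        stats::ts(cbind(clean$samples[idx], power_series[[r]][idx]),
                  frequency = fs),
        spans = spans, taper = 0.1, detrend = TRUE, plot = FALSE)
      ep[r, ] <- stats::approx(sp$freq, sp$coh, xout = coh_freqs,
                               rule = 2)$y
    }
    acc <- acc + ep
    used <- used + 1L
  }
  if (used == 0) stop("no epoch long enough for the requested wavelets")
  structure(list(freq_grid = freq_grid, coh_freqs = coh_freqs,
                 coherence = acc / used, n_epochs_used = used),
            class = "crosscoherence")
}

#' @export
print.crosscoherence <- function(x, ...) {
  cat(sprintf(
    "<crosscoherence> %d wavelet freqs x %d coherence freqs, %d epoch(s)\n",
    length(x$freq_grid), length(x$coh_freqs), x$n_epochs_used))
  invisible(x)
}

#' @export
plot.crosscoherence <- function(x, ...) {
  graphics::image(x$coh_freqs, x$freq_grid, t(x$coherence),
                  xlab = "coherence frequency (Hz)",
                  ylab = "wavelet frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
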