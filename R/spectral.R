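# Epoch-wise power spectra and theta-band summaries.

#' Power spectrum of a single epoch
#'
#' Linearly detrends the epoch and computes a one-sided magnitude-squared
#' FFT normalized to power spectral density (units z^2/Hz), so the integral
#' of the unsmoothed spectrum over frequency equals the epoch variance
#' (Parseval). No taper is applied. Epochs shorter than `min_dur_s` or with
#' at least `max_masked_frac` masked samples are rejected (returns a
#' `rejected_epoch` sentinel carrying the reason).
#'
#' @param clean A `clean_lfp` object from [preprocess_lfp()].
#' @param epoch Numeric `c(start_s, end_s)` within the session.
#' @param min_dur_s Minimum usable epoch duration (s).
#' @param max_masked_frac Maximum tolerated masked fraction.
#' @return A `power_spectrum` (list with `freqs`, `power`,
#'   `n_epochs_averaged`, `smoothing_fwhm`), or a `rejected_epoch` sentinel.
#' @export
epoch_spectrum <- function(clean, epoch, min_dur_s = 1, max_masked_frac = 0.2) {
  stopifnot(inherits(clean, "clean_lfp"), length(epoch) == 2)
  fs <- clean$sample_rate
  i0 <- max(1L, floor(epoch[1] * fs) + 1L)
  i1 <- min(length(clean$samples), ceiling(epoch[2] * fs))
  if (i1 - i0 < 8) return(reject_epoch("empty epoch"))
  if ((i1 - i0 + 1) / fs < min_dur_s) {
    return(reject_epoch(sprintf("epoch shorter than %g s", min_dur_s)))
  }
  if (mean(clean$artifact_mask[i0:i1]) >= max_masked_frac) {
    return(reject_epoch(sprintf("masked fraction >= %g", max_masked_frac)))
  }
  x <- clean$samples[i0:i1]
  n <- length(x)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  x <- fit$residuals
  nh <- floor(n / 2)
  P <- Mod(stats::fft(x))^2 / (n * fs)
  freqs <- (0:nh) * fs / n
  power <- P[1:(nh + 1)]
  # one-sided density: double interior bins (not DC, not Nyquist for even n)
  hi <- if (n %% 2 == 0) nh else nh + 1
  if (hi >= 2) power[2:hi] <- 2 * power[2:hi]
  structure(list(freqs = freqs, power = power, n_epochs_averaged = 1L,
                 smoothing_fwhm = 0), class = "power_spectrum")
}

# Sentinel for skipped epochs; carries the reason for the skip.
reject_epoch <- function(reason) {
  structure(list(reason = reason), class = "rejected_epoch")
}

is_rejected <- function(x) is.null(x) || inherits(x, "rejected_epoch")

#' Smooth and average epoch spectra
#'
#' Each spectrum is interpolated onto a fixed frequency grid, smoothed with
#' a Gaussian kernel of the given FWHM, and the smoothed spectra are averaged
#' with equal weights across epochs.
#'
#' @param spectra List of `power_spectrum` objects (rejected-epoch sentinels
#'   and `NULL`s are dropped).
#' @param fwhm Gaussian kernel full width at half maximum in Hz (0 disables
#'   smoothing).
#' @param grid_step Common frequency-grid step in Hz.
#' @return A `power_spectrum` with `n_epochs_averaged` set.
#' @export
average_and_smooth <- function(spectra, fwhm = 2, grid_step = 0.25) {
  if (inherits(spectra, "power_spectrum")) spectra <- list(spectra)
  spectra <- Filter(Negate(is_rejected), spectra)
  if (!length(spectra)) stop("no usable spectra to average")
  fmax <- min(vapply(spectra, function(s) max(s$freqs), numeric(1)))
  grid <- seq(0, fmax, by = grid_step)
  sig <- fwhm_to_sigma(fwhm) / grid_step
  acc <- matrix(0, nrow = length(grid), ncol = length(spectra))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    y <- stats::approx(s$freqs, s$power, xout = grid, rule = 2)$y
    if (fwhm > 0) y <- gaussian_smooth(y, sig)
    acc[, k] <- y
  }
  structure(list(freqs = grid, power = rowMeans(acc),
                 n_epochs_averaged = length(spectra),
                 smoothing_fwhm = fwhm), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins, 0-%.1f Hz, %d epoch(s), smoothing FWHM %g Hz\n",
    length(x$freqs), max(x$freqs), x$n_epochs_averaged, x$smoothing_fwhm))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(0, 50), log = "y", ...) {
  sel <- x$freqs >= xlim[1] & x$freqs <= xlim[2] & x$power > 0
  graphics::plot(x$freqs[sel], x$power[sel], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "power (z²/Hz)", ...)
  invisible(x)
}

#' Theta-band summary of a power spectrum
#'
#' Peak frequency/power are the argmax over the theta band; integrated power
#' is the trapezoidal integral over the band.
#'
#' @param spec A `power_spectrum`.
#' @param band Theta band in Hz (default 6-12).
#' @return A list of class `theta_summary` with `peak_freq`, `peak_power`,
#'   `integrated_power`.
#' @export
theta_summary <- function(spec, band = c(6, 12)) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (min(spec$freqs) > band[1] || max(spec$freqs) < band[2]) {
    stop("spectrum grid does not cover the ", band[1], "-", band[2],
         " Hz band")
  }
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  f <- spec$freqs[sel]
  p <- spec$power[sel]
  i <- which.max(p)
  structure(list(peak_freq = f[i], peak_power = p[i],
                 integrated_power = trapz(f, p), band = band),
            class = "theta_summary")
}

#' @export
print.theta_summary <- function(x, ...) {
  cat(sprintf(
    "<theta_summary> peak %.2f Hz (power %.3g), integrated %.3g over %g-%g Hz\n",
    x$peak_freq, x$peak_power, x$integrated_power, x$band[1], x$band[2]))
  invisible(x)
}
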