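# Shared DSP helpers: FIR design/application, Hilbert transform, Gaussian
# smoothing, masked z-scoring. All filtering is zero-phase (phase distortion
# would corrupt downstream phase-amplitude coupling estimates).

#' Design a windowed (Hamming) linear-phase FIR filter
#'
#' Thin wrapper around [signal::fir1()] that validates band edges against the
#' Nyquist frequency and returns the tap vector.
#'
#' @param order Filter order (number of taps minus one). Even orders give
#'   type-I filters, required for high-pass designs.
#' @param band Cutoff (scalar, Hz) for `"low"`/`"high"`, or length-2 band
#'   edges (Hz) for `"pass"`.
#' @param sample_rate Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`.
#' @return Numeric vector of `order + 1` filter taps.
#' @keywords internal
design_fir <- function(order, band, sample_rate, type = c("pass", "high", "low")) {
  type <- match.arg(type)
  nyq <- sample_rate / 2
  if (any(!is.finite(band)) || any(band <= 0) || any(band >= nyq)) {
    stop("band edges must lie strictly inside (0, ", nyq, ") Hz")
  }
  if (type == "pass") {
    if (length(band) != 2 || band[1] >= band[2]) {
      stop("band-pass requires ascending band edges (lo < hi)")
    }
  } else if (length(band) != 1) {
    stop("high/low-pass take a single cutoff")
  }
  if (order %% 2 != 0) order <- order + 1  # force type-I (odd tap count)
  h <- signal::fir1(order, band / nyq, type = type)
  if (type == "high") {
    # The windowed design leaks at DC when the transition band is wider than
    # the cutoff (inevitable for a 1 Hz cutoff at moderate orders). Null DC
    # exactly by subtracting a window-shaped lowpass scaled to the leak; the
    # correction is symmetric (still zero-phase) and confined to the window
    # main lobe, leaving the passband untouched.
    w <- signal::hamming(length(h))
    h <- h - sum(h) * w / sum(w)
  }
  h
}

#' Apply an FIR filter with zero phase
#'
#' Applies a symmetric (linear-phase) FIR filter forward and backward by FFT
#' convolution, giving exactly zero phase and squared magnitude response
#' (equivalent to `filtfilt`). Edges are padded by odd reflection over one
#' filter length to suppress boundary transients.
#'
#' @param x Numeric series.
#' @param h FIR taps (odd length, symmetric).
#' @param passes 1 applies the filter once with group-delay compensation;
#'   2 (default) applies it forward-backward.
#' @return Filtered series, same length as `x`.
#' @keywords internal
fir_zerophase <- function(x, h, passes = 2) {
  n <- length(x)
  L <- length(h)
  if (n <= 3 * (L - 1)) {
    stop("series of length ", n, " is too short for a ", L - 1,
         "-order FIR filter; need more than ", 3 * (L - 1), " samples")
  }
  # odd (point-symmetric) reflection padding, one filter length each side
  pre <- 2 * x[1] - x[(L + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - L)]
  xp <- c(pre, x, post)
  np <- length(xp)
  nf <- stats::nextn(np + L, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(nf - L)))
  X <- stats::fft(c(xp, numeric(nf - np)))
  if (passes == 2) {
    # H * Conj(H) is the transform of the (centered) autocorrelation of h:
    # zero-phase, no delay to compensate
    y <- Re(stats::fft(X * (H * Conj(H)), inverse = TRUE)) / nf
    y[(L + 1):(L + n)]
  } else {
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nf
    delay <- (L - 1) / 2
    y[(L + 1 + delay):(L + n + delay)]
  }
}

#' Analytic signal via the Hilbert transform
#'
#' @param x Real numeric series.
#' @return Complex analytic series `x + i * H(x)`.
#' @keywords internal
hilbert_analytic <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- 1
  if (n %% 2 == 0) {
    w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * w, inverse = TRUE) / n
}

#' Convert a Gaussian kernel FWHM to its standard deviation
#' @param fwhm Full width at half maximum (any unit).
#' @return Standard deviation in the same unit.
#' @keywords internal
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Smooth a series with a normalized Gaussian kernel
#'
#' Edge frames are handled by renormalizing the truncated kernel, so the
#' smoother is exactly mean-preserving for constant inputs everywhere.
#'
#' @param x Numeric series.
#' @param sigma Kernel standard deviation in samples.
#' @return Smoothed series, same length.
#' @keywords internal
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  y <- stats::filter(c(rep(x[1], half), x, rep(x[n], half)), k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Centered moving average with edge renormalization
#' @keywords internal
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1) return(x)
  if (width %% 2 == 0) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(x)
  y <- stats::filter(c(rep(x[1], half), x, rep(x[n], half)),
                     rep(1 / width, width), sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Z-score a series over unmasked samples
#'
#' Masked samples do not contribute to the mean/SD and are set to 0 in the
#' output (they stay excluded from analyses through the mask itself).
#'
#' @param x Numeric series.
#' @param mask Logical series, `TRUE` = excluded.
#' @return Z-scored series.
#' @keywords internal
zscore_masked <- function(x, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(x))
  good <- x[!mask]
  if (length(good) < 2) stop("not enough unmasked samples to z-score")
  s <- stats::sd(good)
  if (s == 0) stop("cannot z-score a constant series")
  z <- (x - mean(good)) / s
  z[mask] <- 0
  z
}

#' Trapezoidal integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Evaluate with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state,
#' so generators are reproducible without clobbering the session stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# interval helpers: intervals are 2-column matrices [start, end) in seconds
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & a_end > b_start
}
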