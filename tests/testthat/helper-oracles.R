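# Independent reference implementations (oracles) and small construction
# helpers shared across test files.

# Brute-force SWR event scan: walks the envelope sample by sample, collects
# all Z >= 0 regions, applies the candidate (duration, peak), merge, discard
# and mask rules with straight-line logic. Deliberately written with a
# different mechanism than the package detector.
oracle_swr <- function(z, fs, min_dur_ms = 40, peak_z = 3, merge_gap_ms = 40,
                       max_dur_ms = 500, mask = NULL) {
  n <- length(z)
  if (is.null(mask)) mask <- rep(FALSE, n)
  regions <- list()
  i <- 1L
  while (i <= n) {
    if (z[i] >= 0) {
      j <- i
      while (j < n && z[j + 1L] >= 0) j <- j + 1L
      regions[[length(regions) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cand <- Filter(function(r) {
    len <- r[2] - r[1] + 1L
    len >= min_dur_ms / 1000 * fs && max(z[r[1]:r[2]]) >= peak_z
  }, regions)
  merged <- list()
  for (r in cand) {
    m <- length(merged)
    if (m > 0 && (r[1] - merged[[m]][2] - 1) / fs * 1000 <= merge_gap_ms) {
      merged[[m]][2] <- r[2]
    } else {
      merged[[m + 1L]] <- r
    }
  }
  keep <- list()
  for (r in merged) {
    dur_ms <- (r[2] - r[1] + 1L) / fs * 1000
    if (dur_ms >= max_dur_ms) next
    if (any(mask[r[1]:r[2]])) next
    keep[[length(keep) + 1L]] <- r
  }
  if (!length(keep)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), peak_z = numeric(0),
                      peak_time_s = numeric(0)))
  }
  do.call(rbind, lapply(keep, function(r) {
    ipk <- r[1] - 1L + which.max(z[r[1]:r[2]])
    data.frame(start_s = (r[1] - 1) / fs, end_s = r[2] / fs,
               duration_ms = (r[2] - r[1] + 1L) / fs * 1000,
               peak_z = z[ipk], peak_time_s = (ipk - 0.5) / fs)
  }))
}

# Brute-force resultant vector length straight from raw (phase, amplitude)
# samples: per-bin complex sum without going through the package's
# distribution object.
oracle_rvl <- function(phase, amplitude, n_bins = 20) {
  width <- 2 * pi / n_bins
  idx <- ceiling((phase + pi) / width)
  idx[idx < 1] <- 1
  idx[idx > n_bins] <- n_bins
  centers <- -pi + (seq_len(n_bins) - 0.5) * width
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    sel <- idx == j
    if (!any(sel)) return(NA_real_)
    means[j] <- mean(amplitude[sel])
  }
  Mod(sum(means * exp(1i * centers))) / sum(means)
}

# Wrap a plain numeric series as a clean_lfp with no masked samples, for
# tests that need full control over the signal handed to analysis stages.
fake_clean <- function(samples, sample_rate, mask = NULL) {
  n <- length(samples)
  if (is.null(mask)) mask <- rep(FALSE, n)
  structure(list(samples = as.numeric(samples), artifact_mask = mask,
                 sample_rate = sample_rate, channel = "HPC",
                 subject_id = "test", session_id = "test",
                 provenance = list(masked_fraction = mean(mask))),
            class = "clean_lfp")
}

# Minimal event catalog with a given incidence, for arithmetic-only tests.
fake_catalog <- function(incidence_hz, period_label = "other") {
  structure(list(events = data.frame(), analyzed_duration_s = 1,
                 incidence_hz = incidence_hz, period_label = period_label,
                 sample_rate = 512, mask = logical(0), settings = list()),
            class = "swr_catalog")
}

# Random envelope with event-scale autocorrelation: smoothed noise plus a
# few smoothed spikes, so Z >= 0 regions last tens of ms and peaks above 3
# actually occur. Used to exercise the detector and its oracle.
random_envelope <- function(n, fs) {
  s <- gaussian_smooth_ref(rnorm(n), 0.010 * fs)
  z <- (s - mean(s)) / sd(s) * 1.7 - 0.3
  spikes <- numeric(n)
  for (k in seq_len(rpois(1, n / fs))) {
    spikes[sample.int(n, 1)] <- runif(1, 3, 8)
  }
  z + gaussian_smooth_ref(spikes, 0.008 * fs) * (0.008 * fs * sqrt(2 * pi))
}

# Local copy of a Gaussian smoother so helpers do not depend on package
# internals.
gaussian_smooth_ref <- function(x, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  y <- stats::filter(c(rep(x[1], half), x, rep(x[n], half)), k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

# A synthetic envelope with rectangular super-threshold bumps at the given
# start/end times (seconds); background well below zero.
bump_envelope <- function(duration_s, fs, bumps, peak = 4) {
  z <- rep(-1, round(duration_s * fs))
  for (b in bumps) {
    i0 <- round(b[1] * fs) + 1L
    i1 <- round(b[2] * fs)
    z[i0:i1] <- peak
  }
  z
}
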