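# Synthetic-data generators. These emulate the statistical structure the
# analysis pipeline assumes -- 1/f background with a theta rhythm, theta-phase
# modulated gamma, Poisson-embedded ripple-band bursts, sparse impulsive
# artifacts, two-state open-field trajectories, Bernoulli T-maze choices --
# and return full ground truth so every downstream stage can be validated
# against known answers.

#' Parameters for synthetic LFP generation
#'
#' The generated signal is
#' `noise + theta + gamma_amp * (1 + m * cos(theta_phase - pref)) * gamma carrier`
#' plus Gaussian-windowed ripple-band bursts at Poisson times and impulsive
#' artifacts. The linear `1 + m*cos` envelope makes the coupling ground truth
#' invertible: with 20 even phase bins the resultant vector length of the
#' noise-free amplitude distribution is exactly `m/2`.
#'
#' @param duration_s Session length in seconds.
#' @param sample_rate Sampling rate, Hz (recording standard: 512).
#' @param theta_freq,theta_amp Theta oscillation frequency (Hz, in the 6-12 Hz
#'   band) and amplitude (a.u.).
#' @param gamma_freq,gamma_amp Gamma carrier frequency (Hz, in the 60-120 Hz
#'   band) and baseline envelope amplitude (a.u.).
#' @param coupling_depth Theta-phase modulation depth `m` of the gamma
#'   envelope, in `[0, 1]`; 0 = no coupling.
#' @param coupling_pref_phase Theta phase (radians) at which the gamma
#'   envelope peaks.
#' @param noise_exponent Spectral exponent `alpha` of the `1/f^alpha`
#'   background.
#' @param noise_amp Standard deviation of the background noise (a.u.).
#' @param ripple_rate Poisson rate of ripple bursts, events/s.
#' @param ripple_freq Ripple carrier frequency, Hz. Default 155: the
#'   acquisition chain is band-limited to 160 Hz, so detectable ripple energy
#'   sits just above the 150 Hz detection-band floor.
#' @param ripple_dur_ms Nominal ripple duration (ms); the burst is a sinusoid
#'   under a Gaussian window with `sigma = dur/6`, ground-truth interval
#'   `+/- 3 sigma`.
#' @param ripple_amp_sd Ripple peak amplitude in multiples of the ripple-band
#'   (150 Hz-Nyquist) SD of the background signal.
#' @param artifact_rate Poisson rate of impulsive artifacts, events/s.
#' @param artifact_amp_sd Artifact amplitude in multiples of the artifact-free
#'   signal SD.
#' @param artifact_len_range Integer range of artifact run lengths in samples.
#' @param seed Integer seed; identical `(params, seed)` give byte-identical
#'   output.
#' @return An object of class `synth_lfp_params`.
#' @seealso [generate_lfp()]
#' @export
synth_lfp_params <- function(duration_s = 600, sample_rate = 512,
                             theta_freq = 8, theta_amp = 0.5,
                             gamma_freq = 80, gamma_amp = 0.2,
                             coupling_depth = 0.5, coupling_pref_phase = 0,
                             noise_exponent = 1, noise_amp = 1,
                             ripple_rate = 0.2, ripple_freq = 155,
                             ripple_dur_ms = 60, ripple_amp_sd = 6,
                             artifact_rate = 0.02, artifact_amp_sd = 25,
                             artifact_len_range = c(1, 4), seed = NULL) {
  p <- list(duration_s = duration_s, sample_rate = sample_rate,
            theta_freq = theta_freq, theta_amp = theta_amp,
            gamma_freq = gamma_freq, gamma_amp = gamma_amp,
            coupling_depth = coupling_depth,
            coupling_pref_phase = coupling_pref_phase,
            noise_exponent = noise_exponent, noise_amp = noise_amp,
            ripple_rate = ripple_rate, ripple_freq = ripple_freq,
            ripple_dur_ms = ripple_dur_ms, ripple_amp_sd = ripple_amp_sd,
            artifact_rate = artifact_rate, artifact_amp_sd = artifact_amp_sd,
            artifact_len_range = as.integer(artifact_len_range), seed = seed)
  if (p$duration_s <= 0) stop("duration_s must be positive")
  if (p$sample_rate <= 0) stop("sample_rate must be positive")
  if (p$coupling_depth < 0 || p$coupling_depth > 1) {
    stop("coupling_depth must lie in [0, 1]")
  }
  if (p$ripple_freq >= p$sample_rate / 2) {
    stop("ripple_freq (", p$ripple_freq, " Hz) must be below the Nyquist ",
         "frequency (", p$sample_rate / 2, " Hz)")
  }
  if (p$ripple_rate < 0 || p$artifact_rate < 0) stop("rates must be >= 0")
  if (p$noise_amp < 0 || p$theta_amp < 0 || p$gamma_amp < 0) {
    stop("amplitudes must be >= 0")
  }
  class(p) <- "synth_lfp_params"
  p
}

# 1/f^alpha Gaussian noise with unit SD, via random spectral phases.
# Returns the series and the per-bin spectral amplitudes actually used so
# callers can compute exact band SDs.
one_over_f_noise <- function(n, sample_rate, alpha) {
  nhalf <- floor(n / 2)
  freqs <- (1:nhalf) * sample_rate / n
  amp <- freqs^(-alpha / 2)
  ph <- stats::runif(nhalf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(length.out = n)
  full[2:(nhalf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nhalf + 1] <- complex(real = amp[nhalf] * cos(ph[nhalf]))
    full[(nhalf + 2):n] <- Conj(spec[(nhalf - 1):1])
  } else {
    full[(nhalf + 2):n] <- Conj(spec[nhalf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  sc <- stats::sd(x)
  list(x = x / sc, amp = amp, scale = sc, freqs = freqs)
}

#' Generate a synthetic LFP session with ground truth
#'
#' @param params A [synth_lfp_params()] object.
#' @param channel,subject_id,session_id Labels attached to the output.
#' @return A list with elements `lfp` (a [raw_lfp()] object) and `truth`, a
#'   list holding `ripple_intervals` (two-column matrix of start/end seconds,
#'   non-overlapping), `ripple_times`, `artifact_indices`,
#'   `true_coupling_depth`, `true_theta_freq`, `theta_phase` and the
#'   band-noise SD used to scale ripples.
#' @examples
#' p <- synth_lfp_params(duration_s = 10, ripple_rate = 0.5, seed = 1)
#' sim <- generate_lfp(p)
#' nrow(sim$truth$ripple_intervals)
#' @export
generate_lfp <- function(params, channel = "HPC", subject_id = "synthetic",
                         session_id = "s1") {
  stopifnot(inherits(params, "synth_lfp_params"))
  p <- params
  fs <- p$sample_rate
  n <- round(p$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  with_seed(p$seed, {
    theta_phase <- 2 * pi * p$theta_freq * tt
    x <- p$theta_amp * cos(theta_phase)
    env <- p$gamma_amp *
      (1 + p$coupling_depth * cos(theta_phase - p$coupling_pref_phase))
    x <- x + env * cos(2 * pi * p$gamma_freq * tt)

    band_sd <- 0
    if (p$noise_amp > 0) {
      nz <- one_over_f_noise(n, fs, p$noise_exponent)
      x <- x + p$noise_amp * nz$x
      # exact ripple-band SD of the generated background (150 Hz - Nyquist)
      inband <- nz$freqs >= 150 & nz$freqs < fs / 2
      band_sd <- p$noise_amp *
        sqrt(2 * sum(nz$amp[inband]^2)) / (nz$scale * n)
    }

    ripple_intervals <- matrix(numeric(0), ncol = 2,
                               dimnames = list(NULL, c("start_s", "end_s")))
    ripple_times <- numeric(0)
    if (p$ripple_rate > 0) {
      sig <- (p$ripple_dur_ms / 1000) / 6
      margin <- 4 * sig
      span <- p$duration_s - 2 * margin
      if (span > 0) {
        n_ev <- stats::rpois(1, p$ripple_rate * span)
        amp <- if (band_sd > 0) p$ripple_amp_sd * band_sd else p$ripple_amp_sd
        centers <- numeric(0)
        for (k in seq_len(n_ev)) {
          for (try in 1:200) {  # dart-throwing: keep count, forbid overlap
            tc <- stats::runif(1, margin, p$duration_s - margin)
            if (!length(centers) || all(abs(centers - tc) > 6 * sig)) {
              centers <- c(centers, tc)
              break
            }
          }
        }
        centers <- sort(centers)
        for (tc in centers) {
          i0 <- max(1L, floor((tc - 4 * sig) * fs))
          i1 <- min(n, ceiling((tc + 4 * sig) * fs))
          idx <- i0:i1
          dt <- tt[idx] - tc
          x[idx] <- x[idx] +
            amp * exp(-dt^2 / (2 * sig^2)) * sin(2 * pi * p$ripple_freq * dt)
        }
        if (length(centers)) {
          ripple_intervals <- cbind(start_s = centers - 3 * sig,
                                    end_s = centers + 3 * sig)
          ripple_times <- centers
        }
      }
    }

    artifact_indices <- integer(0)
    if (p$artifact_rate > 0) {
      n_art <- stats::rpois(1, p$artifact_rate * p$duration_s)
      if (n_art > 0) {
        base_sd <- stats::sd(x)
        lens <- sample(p$artifact_len_range[1]:p$artifact_len_range[2],
                       n_art, replace = TRUE)
        starts <- sample.int(n, n_art)
        signs <- sample(c(-1, 1), n_art, replace = TRUE)
        for (k in seq_len(n_art)) {
          idx <- starts[k]:min(n, starts[k] + lens[k] - 1L)
          x[idx] <- x[idx] + signs[k] * p$artifact_amp_sd * base_sd
          artifact_indices <- c(artifact_indices, idx)
        }
        artifact_indices <- sort(unique(artifact_indices))
      }
    }

    lfp <- raw_lfp(x, sample_rate = fs, channel = channel,
                   subject_id = subject_id, session_id = session_id)
    truth <- list(ripple_intervals = ripple_intervals,
                  ripple_times = ripple_times,
                  artifact_indices = artifact_indices,
                  true_coupling_depth = p$coupling_depth,
                  true_theta_freq = p$theta_freq,
                  theta_phase = NULL,
                  band_noise_sd = band_sd,
                  params = p)
    list(lfp = lfp, truth = truth)
  })
}

#' Parameters for synthetic open-field tracking
#'
#' Two-state (mobile/stationary) trajectory in a rectangular arena: mobility
#' is drawn per 1-s block, mobile frames take fixed-length steps around a
#' persistent random-walk heading (deflected off walls, so the animal never
#' leaves the arena and mobile frame speeds never fall below threshold), and
#' a wall-attraction term of weight `thigmotaxis_weight` biases the heading
#' toward the nearest wall.
#'
#' @param arena_width,arena_length Arena dimensions in cm (open-field
#'   standard: 20 x 40).
#' @param frame_rate Tracking rate, Hz (video standard: 25).
#' @param mean_speed Mean frame speed during mobile blocks, cm/s.
#' @param p_move Probability that a 1-s block is mobile.
#' @param thigmotaxis_weight Wall-attraction weight in `[0, 1]`.
#' @param duration_s Session length, seconds.
#' @param seed Integer seed.
#' @return An object of class `synth_behavior_params`.
#' @export
synth_behavior_params <- function(arena_width = 20, arena_length = 40,
                                  frame_rate = 25, mean_speed = 12,
                                  p_move = 0.5, thigmotaxis_weight = 0.5,
                                  duration_s = 300, seed = NULL) {
  p <- list(arena_width = arena_width, arena_length = arena_length,
            frame_rate = frame_rate, mean_speed = mean_speed,
            p_move = p_move, thigmotaxis_weight = thigmotaxis_weight,
            duration_s = duration_s, seed = seed)
  if (p$arena_width <= 0 || p$arena_length <= 0) {
    stop("arena dimensions must be positive")
  }
  if (p$p_move < 0 || p$p_move > 1) stop("p_move must lie in [0, 1]")
  if (p$thigmotaxis_weight < 0 || p$thigmotaxis_weight > 1) {
    stop("thigmotaxis_weight must lie in [0, 1]")
  }
  if (p$duration_s <= 0) stop("duration_s must be positive")
  class(p) <- "synth_behavior_params"
  p
}

#' Generate a synthetic open-field trajectory with ground truth
#'
#' @param params A [synth_behavior_params()] object.
#' @return A list with `track` (a [tracking_trace()] object) and `truth`
#'   (list with `mobile_intervals`, a two-column matrix of seconds, and the
#'   design parameters).
#' @export
generate_tracking <- function(params) {
  stopifnot(inherits(params, "synth_behavior_params"))
  p <- params
  fr <- p$frame_rate
  n <- round(p$duration_s * fr)
  W <- p$arena_width
  L <- p$arena_length
  with_seed(p$seed, {
    n_blocks <- ceiling(n / fr)
    mobile_block <- stats::runif(n_blocks) < p$p_move
    xs <- numeric(n)
    ys <- numeric(n)
    pos <- c(W / 2, L / 2)
    heading <- stats::runif(1, 0, 2 * pi)
    w <- p$thigmotaxis_weight
    pad <- 0.25  # keep a small margin off the walls
    for (i in seq_len(n)) {
      blk <- ((i - 1) %/% fr) + 1
      if (mobile_block[blk]) {
        heading <- heading + stats::rnorm(1, 0, 0.45)
        step_len <- max(5.5, stats::rnorm(1, p$mean_speed, 2)) / fr
        dir <- c(cos(heading), sin(heading))
        if (w > 0) {
          # pull toward the nearest wall point
          dw <- c(ifelse(pos[1] < W / 2, -1, 1) *
                    (1 - min(pos[1], W - pos[1]) / (W / 2)),
                  ifelse(pos[2] < L / 2, -1, 1) *
                    (1 - min(pos[2], L - pos[2]) / (L / 2)))
          to_wall <- if (abs(dw[1]) >= abs(dw[2])) {
            c(sign(ifelse(pos[1] < W / 2, -1, 1)), 0)
          } else {
            c(0, sign(ifelse(pos[2] < L / 2, -1, 1)))
          }
          v <- (1 - w) * dir + w * to_wall
          nv <- sqrt(sum(v^2))
          if (nv > 1e-9) dir <- v / nv
        }
        cand <- pos + step_len * dir
        tries <- 0
        while ((cand[1] < pad || cand[1] > W - pad ||
                cand[2] < pad || cand[2] > L - pad) && tries < 40) {
          # deflect off the wall: full step length preserved
          if (cand[1] < pad || cand[1] > W - pad) dir[1] <- -dir[1]
          if (cand[2] < pad || cand[2] > L - pad) dir[2] <- -dir[2]
          dir <- dir + stats::rnorm(2, 0, 0.15)
          dir <- dir / sqrt(sum(dir^2))
          cand <- pos + step_len * dir
          tries <- tries + 1
        }
        if (tries < 40) {
          heading <- atan2(dir[2], dir[1])
          pos <- cand
        }
      } else {
        jit <- stats::rnorm(2, 0, 0.02)
        cand <- pmin(pmax(pos + jit, pad), c(W, L) - pad)
        pos <- cand
      }
      xs[i] <- pos[1]
      ys[i] <- pos[2]
    }
    runs <- rle(mobile_block)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- which(runs$values)
    mobile_intervals <- cbind(start_s = (starts[keep] - 1),
                              end_s = pmin(ends[keep], n / fr))
    track <- tracking_trace(times = (seq_len(n) - 1) / fr, x = xs, y = ys,
                            frame_rate = fr, arena_width = W, arena_length = L)
    list(track = track,
         truth = list(mobile_intervals = mobile_intervals, params = p))
  })
}

#' Generate Bernoulli spontaneous-alternation choices
#'
#' Each T-maze trial consists of a first free arm choice and a second run in
#' which the animal alternates (chooses the other arm) with probability
#' `p_alt`; chance level is 0.5.
#'
#' @param p_alt Per-trial alternation probability in `[0, 1]`.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed.
#' @return A data frame with columns `trial`, `first_arm`, `second_arm`,
#'   `alternated`.
#' @examples
#' ch <- generate_alternation(0.8, 20, seed = 1)
#' mean(ch$alternated)
#' @export
generate_alternation <- function(p_alt, n_trials, seed = NULL) {
  if (p_alt < 0 || p_alt > 1) stop("p_alt must lie in [0, 1]")
  if (n_trials < 1) stop("n_trials must be >= 1")
  with_seed(seed, {
    first <- sample(c("L", "R"), n_trials, replace = TRUE)
    alt <- stats::runif(n_trials) < p_alt
    second <- ifelse(alt, ifelse(first == "L", "R", "L"), first)
    data.frame(trial = seq_len(n_trials), first_arm = first,
               second_arm = second, alternated = alt,
               stringsAsFactors = FALSE)
  })
}
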