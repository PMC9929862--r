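# Phase-amplitude coupling.

test_that("analytic signal recovers envelope and phase ramp of a sine", {
  fs <- 512
  t <- (0:(8 * fs - 1)) / fs
  a <- analytic_signal(sin(2 * pi * 8 * t), c(6, 12), fs)
  core <- (2 * fs):(6 * fs)
  expect_true(all(a$amplitude[core] > 0.95 & a$amplitude[core] < 1.05))
  dph <- diff(a$phase[core])
  dph <- dph[dph > 0]  # drop wrap-arounds
  expect_lt(abs(median(dph) - 2 * pi * 8 / fs) / (2 * pi * 8 / fs), 0.01)
})

test_that("DC input has near-zero band-passed envelope", {
  fs <- 512
  a <- analytic_signal(rep(1, 4 * fs), c(6, 12), fs)
  expect_lt(max(a$amplitude), 1e-3)
})

test_that("amplitude is linear in input scale", {
  fs <- 512
  set.seed(1)
  x <- rnorm(4 * fs)
  a1 <- analytic_signal(x, c(60, 120), fs)
  a3 <- analytic_signal(3 * x, c(60, 120), fs)
  expect_equal(a3$amplitude, 3 * a1$amplitude, tolerance = 1e-9)
})

test_that("the filter order adapts to short epochs", {
  fs <- 512
  a <- analytic_signal(rnorm(300), c(6, 12), fs)
  expect_lt(a$order, 100)
  expect_error(analytic_signal(rnorm(20), c(6, 12), fs), "too short")
})

test_that("constant amplitude gives uniform weights", {
  set.seed(2)
  ph <- runif(10000, -pi, pi)
  d <- phase_amplitude_distribution(ph, rep(7, 10000))
  expect_equal(d$weights, rep(1 / 20, 20), tolerance = 1e-12)
})

test_that("1 + cos(phase) amplitude gives weights proportional to 1 + cos(center)", {
  set.seed(3)
  ph <- runif(2e5, -pi, pi)
  d <- phase_amplitude_distribution(ph, 1 + cos(ph))
  expected <- (1 + cos(d$bin_centers))
  expected <- expected / sum(expected)
  expect_equal(d$weights, expected, tolerance = 0.01)
})

test_that("random masking of half the samples barely moves the weights", {
  set.seed(4)
  n <- 2e5
  ph <- runif(n, -pi, pi)
  am <- 1 + cos(ph)
  d_full <- phase_amplitude_distribution(ph, am)
  d_half <- phase_amplitude_distribution(ph, am, mask = runif(n) < 0.5)
  expect_true(all(abs(d_full$weights - d_half$weights) < 0.005))
})

test_that("an empty phase bin rejects the epoch", {
  ph <- runif(100, 0, 1)  # covers only a couple of bins
  d <- phase_amplitude_distribution(ph, rep(1, 100))
  expect_s3_class(d, "rejected_epoch")
})

test_that("RVL endpoints are exact", {
  mk <- function(w) {
    centers <- -pi + (1:20 - 0.5) * (2 * pi / 20)
    structure(list(bin_centers = centers, mean_amp = w, weights = w / sum(w),
                   n_samples = 100L), class = "phase_amp_distribution")
  }
  expect_lt(resultant_vector_length(mk(rep(1, 20))), 1e-12)
  one <- rep(1e-12, 20); one[7] <- 1
  expect_equal(resultant_vector_length(mk(one)), 1, tolerance = 1e-9)
})

test_that("1 + cos envelope has RVL exactly 0.5 on even bins", {
  centers <- -pi + (1:20 - 0.5) * (2 * pi / 20)
  ph <- rep(centers, each = 50)
  d <- phase_amplitude_distribution(ph, 1 + cos(ph))
  expect_equal(resultant_vector_length(d), 0.5, tolerance = 1e-12)
})

test_that("RVL matches a brute-force oracle on random instances", {
  set.seed(5)
  for (k in 1:100) {
    n <- sample(200:500, 1)
    ph <- runif(n, -pi, pi)
    am <- rexp(n)
    d <- phase_amplitude_distribution(ph, am)
    ref <- oracle_rvl(ph, am)
    if (inherits(d, "rejected_epoch")) {
      expect_true(is.na(ref))
    } else {
      expect_equal(resultant_vector_length(d), ref, tolerance = 1e-9)
    }
  }
})

test_that("RVL is near zero under phase-amplitude shuffling", {
  set.seed(6)
  rvls <- vapply(1:20, function(k) {
    ph <- runif(20000, -pi, pi)
    am <- rexp(20000)
    resultant_vector_length(phase_amplitude_distribution(ph, sample(am)))
  }, numeric(1))
  expect_lt(mean(rvls), 0.02)
})

test_that("a single epoch's mean RVL is that epoch's RVL", {
  p <- synth_lfp_params(duration_s = 20, artifact_rate = 0, ripple_rate = 0,
                        seed = 7)
  clean <- preprocess_lfp(generate_lfp(p)$lfp)
  r <- pac_for_epochs(clean, cbind(2, 18))
  expect_length(r$rvl_per_epoch, 1)
  expect_equal(r$mean_rvl, r$rvl_per_epoch[1])
})

test_that("stronger designed coupling gives larger RVL at common seeds", {
  mean_rvl <- function(m, s) {
    p <- synth_lfp_params(duration_s = 40, coupling_depth = m,
                          artifact_rate = 0, ripple_rate = 0, seed = s)
    clean <- preprocess_lfp(generate_lfp(p)$lfp)
    pac_for_epochs(clean, NULL)$mean_rvl
  }
  lo <- mean(vapply(1:5, function(s) mean_rvl(0.2, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) mean_rvl(0.8, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("no usable epoch yields an NA mean", {
  p <- synth_lfp_params(duration_s = 20, artifact_rate = 0, ripple_rate = 0,
                        seed = 8)
  clean <- preprocess_lfp(generate_lfp(p)$lfp)
  r <- pac_for_epochs(clean, cbind(5, 5.001))  # sub-sample epoch
  expect_true(is.na(r$mean_rvl))
})

test_that("comodulogram has grid shape and localizes designed coupling", {
  p <- synth_lfp_params(duration_s = 60, coupling_depth = 0.8,
                        artifact_rate = 0, ripple_rate = 0, seed = 9)
  clean <- preprocess_lfp(generate_lfp(p)$lfp)
  pg <- cbind(c(2, 6, 12), c(6, 10, 16))
  ag <- cbind(c(30, 50, 70, 90), c(50, 70, 90, 110))
  cm <- comodulogram(clean, NULL, phase_grid = pg, amp_grid = ag)
  expect_equal(dim(cm$rvl_matrix), c(4, 3))
  best <- which(cm$rvl_matrix == max(cm$rvl_matrix), arr.ind = TRUE)
  expect_equal(unname(best[1, ]), c(3, 2))  # amp band 70-90, phase band 6-10
})

test_that("all-noise comodulogram stays small", {
  p <- synth_lfp_params(duration_s = 60, theta_amp = 0, gamma_amp = 0,
                        artifact_rate = 0, ripple_rate = 0, seed = 10)
  clean <- preprocess_lfp(generate_lfp(p)$lfp)
  cm <- comodulogram(clean, NULL, phase_grid = cbind(c(4, 8), c(8, 12)),
                     amp_grid = cbind(c(60, 100), c(80, 120)))
  expect_lt(max(cm$rvl_matrix), 0.05)
})

test_that("cross-coherence is bounded and shows coupling at theta", {
  mkclean <- function(m) {
    p <- synth_lfp_params(duration_s = 30, coupling_depth = m,
                          artifact_rate = 0, ripple_rate = 0, seed = 11)
    preprocess_lfp(generate_lfp(p)$lfp)
  }
  cc1 <- wavelet_crosscoherence(mkclean(0.9), NULL,
                                freq_grid = c(60, 80, 100))
  cc0 <- wavelet_crosscoherence(mkclean(0), NULL,
                                freq_grid = c(60, 80, 100))
  expect_true(all(cc1$coherence >= 0 & cc1$coherence <= 1))
  theta_col <- which.min(abs(cc1$coh_freqs - 8))
  gamma_row <- which(cc1$freq_grid == 80)
  expect_gt(cc1$coherence[gamma_row, theta_col],
            cc0$coherence[gamma_row, theta_col])
})

test_that("white-noise cross-coherence is small", {
  set.seed(12)
  clean <- fake_clean(rnorm(30 * 512), 512)
  cc <- wavelet_crosscoherence(clean, NULL, freq_grid = c(80, 100))
  expect_lt(mean(cc$coherence), 0.1)
})

test_that("epochs shorter than five slowest cycles are skipped", {
  set.seed(13)
  clean <- fake_clean(rnorm(30 * 512), 512)
  expect_error(wavelet_crosscoherence(clean, cbind(0, 0.1),
                                      freq_grid = c(20, 40)),
               "no epoch long enough")
})
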