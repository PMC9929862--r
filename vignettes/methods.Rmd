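---
title: "Methods: LFP and behavior phenotyping with phenolfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LFP and behavior phenotyping with phenolfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolfp)
```

phenolfp implements an analysis pipeline for local field potential (LFP)
recordings from hippocampus (HPC) and medial prefrontal cortex (mPFC)
together with concurrent rodent behavior, plus a synthetic-data generator
with full ground truth so every stage can be validated against known
answers. This vignette walks through the methods in pipeline order.

## Synthetic data with ground truth

`generate_lfp()` builds a surrogate LFP from interpretable components:
a theta oscillation, a gamma oscillation whose amplitude is modulated by
theta phase with a chosen coupling depth, 1/f^α background noise with an
exactly calibrated ripple-band standard deviation, transient ~155 Hz
ripple bursts placed by a Poisson process (non-overlapping), and sparse
impulsive artifacts. The returned ground truth (ripple intervals, artifact
indices, the designed coupling depth and theta frequency) is fully
determined by the parameter object and its seed.

```{r synth}
p <- synth_lfp_params(duration_s = 60, coupling_depth = 0.5,
                      ripple_rate = 0.2, seed = 1)
sim <- generate_lfp(p)
str(sim$truth, max.level = 1)
```

`generate_tracking()` produces open-field positions from a two-state
(mobile/stationary) model with a wall-attraction (thigmotaxis) weight, and
`generate_alternation()` produces T-maze choice records under a Bernoulli
alternation probability.

## Pre-processing

`preprocess_lfp()` applies, in order:

1. **Artifact detection** with the generalized extreme Studentized deviate
   (GESD) test, run on 60 s chunks so local outliers are judged against
   local statistics.
2. **Gap repair**: masked runs of at most 5 samples are replaced by linear
   interpolation between flanking samples; longer runs stay masked and are
   excluded from every downstream computation.
3. **High-pass filtering** at 1 Hz with a 400th-order windowed FIR filter,
   applied forward and backward (zero phase). The windowed design leaks at
   DC when the transition band is wider than the cutoff, so the taps are
   corrected to an exact DC null; DC attenuation exceeds 40 dB.
4. **Z-scoring** over unmasked samples.

Zero-phase filtering matters because any phase distortion would corrupt
the phase-amplitude coupling estimates downstream.

## Behavior

Speed is computed from 25 Hz tracking as displacement times frame rate
with a short moving-average smoother. `segment_epochs()` splits the
session into movement (≥ 1 s of continuous ≥ 5 cm/s) and stationary
(≥ 1 s of continuous < 5 cm/s) epochs; shorter runs belong to no epoch.
`periphery_depth()` solves the equal-area quadratic so the periphery
(wall-adjacent band) and center of the arena have identical areas, and
`mobility_statistics()` reports mobility and speed split by region —
empty regions yield `NA`, never a silent zero. `alternation_rate()`
scores T-maze alternation over completed trials only.

## Spectra and theta

`epoch_spectrum()` computes a detrended periodogram per epoch, refusing
epochs that are too short or too contaminated (returned as tagged
rejections, not errors). `average_and_smooth()` interpolates epoch
spectra onto a common grid, averages, and applies a Gaussian smoother
specified by its full width at half maximum (FWHM); `theta_summary()`
reports the 6–12 Hz peak frequency and integrated power.

## Phase-amplitude coupling

`pac_for_epochs()` implements filter–Hilbert coupling estimation: the
signal is band-pass filtered in the theta (phase) and gamma (amplitude)
bands, Hilbert-transformed, and the amplitude is averaged in 20 equal
phase bins. The normalized bin weights give the resultant vector length
(RVL), the magnitude of the weighted circular mean; an amplitude profile
of 1 + cos(phase) yields RVL = 0.5 exactly. `comodulogram()` scans a grid
of phase and amplitude bands, and `wavelet_crosscoherence()` provides a
Morlet-based cross-frequency view.

```{r pac}
clean <- preprocess_lfp(sim$lfp)
pac <- pac_for_epochs(clean, NULL)
pac$mean_rvl
```

## Sharp-wave ripples

`ripple_envelope()` band-pass filters the cleaned signal above 150 Hz,
takes the Hilbert envelope, smooths it with a 15 ms FWHM Gaussian, and
z-scores it. `detect_swr_events()` then defines events as maximal Z ≥ 0
regions lasting ≥ 40 ms that contain a peak with Z ≥ 3; candidates
separated by ≤ 40 ms are merged, merged events lasting ≥ 500 ms are
discarded, and events overlapping the artifact mask are discarded with
their time removed from the analyzed duration. `incidence_rate()` and
`normalized_change()` summarize rates per rest period and their change
relative to baseline.

Because the envelope is z-scored per session, the detection threshold
adapts to the session's ripple content; on noisy recordings this
compresses differences in true event rates, which is worth keeping in
mind when designing studies around incidence changes.

## Estimation statistics

The estimation layer reports effect sizes with uncertainty rather than
bare p-values:

- `bootstrap_mean_difference()`: BCa (bias-corrected and accelerated)
  bootstrap confidence interval for a two-group mean difference.
- `permutation_test()`: exact (exhaustive) when the number of group
  assignments is small enough, Monte-Carlo with an add-one estimator
  otherwise.
- `pearson_correlation()` and `compare_slopes_lr()`: correlations and a
  likelihood-ratio test for equality of regression slopes across groups.
- `wilcoxon_vs_chance()`: signed-rank test of alternation rates against
  the 0.5 chance level, exact where feasible.

## End-to-end workflows

`simulate_tmaze_cohort()` / `run_tmaze_analysis()` build and analyze a
two-group cohort with baseline and consolidation rest periods plus T-maze
choices: per-subject alternation rate, baseline SWR incidence, and
normalized SWR change, with BCa intervals and permutation tests per
measure. `simulate_openfield_cohort()` / `run_openfield_analysis()` do
the same for open-field sessions: mobility statistics, state-split theta
and PAC summaries, group comparisons, and per-group correlations of
electrophysiology with behavior including slope comparisons.

```{r workflow, eval = FALSE}
cohort <- simulate_tmaze_cohort(n_per_group = 7, seed = 1)
analysis <- run_tmaze_analysis(cohort, seed = 1)
analysis$comparisons
```

## Data interchange

Plain-text CSV round-trips are provided for LFP traces, tracking,
T-maze choices, and detected event catalogs (`write_lfp_csv()`,
`read_lfp_csv()`, and friends), with recording metadata carried in
commented header lines.
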