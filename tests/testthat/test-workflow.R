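# End-to-end cohort workflows. Cohorts here are deliberately small/short to
# keep runtime bounded; the full-scale effect-recovery runs live in the
# acceptance suite.

test_that("empty cohorts error with no partial output", {
  expect_error(run_tmaze_analysis(list()), "empty cohort")
  expect_error(run_openfield_analysis(list()), "empty cohort")
})

test_that("T-maze analysis is deterministic given seeds", {
  coh <- simulate_tmaze_cohort(n_per_group = 3, seed = 2, period_s = 60,
                               n_trials = 8)
  r1 <- run_tmaze_analysis(coh, n_boot = 300, n_perm = 300, seed = 1)
  r2 <- run_tmaze_analysis(coh, n_boot = 300, n_perm = 300, seed = 1)
  expect_identical(r1$subjects, r2$subjects)
  expect_identical(r1$comparisons, r2$comparisons)
})

test_that("null T-maze cohorts produce no spurious group effects", {
  # At n = 4/group the permutation test is exact (C(8,4) = 70 arrangements,
  # smallest two-sided p ~ 0.029), so under a true null at most a couple of
  # the 18 seed x measure p-values should dip below 0.05. BCa interval
  # coverage itself is calibrated at realistic n elsewhere; here we only
  # require structural sanity of the intervals.
  null_group <- list(ripple_rate_baseline = 0.2,
                     ripple_rate_consolidation = 0.2, p_alt = 0.6)
  ps <- c()
  for (s in 1:6) {
    coh <- simulate_tmaze_cohort(n_per_group = 4, seed = s, period_s = 60,
                                 n_trials = 10, group_a = null_group,
                                 group_b = null_group)
    res <- run_tmaze_analysis(coh, n_boot = 1000, n_perm = 500, seed = 1)
    ps <- c(ps, res$comparisons$perm_p)
    expect_true(all(res$comparisons$ci_low <= res$comparisons$mean_diff &
                      res$comparisons$mean_diff <= res$comparisons$ci_high))
  }
  expect_lte(sum(ps < 0.05), 2)
})

test_that("an injected consolidation ripple-rate increase is detected", {
  # Same SWR design as the full-scale cohort (n = 7/group, 300 s periods,
  # consolidation rate 0.2 -> 0.5 in group b; the session-wise z-scoring
  # adapts the detection threshold to ripple content, so the realized
  # normalized change is ~0.38 with subject SD ~0.11). Require detection in
  # at least 2 of 3 seeds.
  hits <- 0
  for (s in 1:3) {
    coh <- simulate_tmaze_cohort(
      n_per_group = 7, seed = s, period_s = 300, n_trials = 10,
      group_a = list(ripple_rate_baseline = 0.2,
                     ripple_rate_consolidation = 0.2, p_alt = 0.6),
      group_b = list(ripple_rate_baseline = 0.2,
                     ripple_rate_consolidation = 0.5, p_alt = 0.6))
    res <- run_tmaze_analysis(coh, n_boot = 500, n_perm = 2000, seed = 1)
    row <- res$comparisons[res$comparisons$measure == "normalized_swr_change", ]
    if (row$mean_b > row$mean_a && row$perm_p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("subjects tables carry traceable keys", {
  coh <- simulate_openfield_cohort(n_per_group = 3, seed = 4, session_s = 60)
  res <- run_openfield_analysis(coh, n_boot = 300, n_perm = 300, seed = 1)
  expect_setequal(res$subjects$subject, sprintf("s%02d", 1:6))
  expect_true(all(res$subjects$session == "novel"))
  expect_true(all(c("a", "b") %in% res$subjects$group))
  expect_identical(
    res$subjects,
    run_openfield_analysis(coh, n_boot = 300, n_perm = 300, seed = 1)$subjects)
})

test_that("group thigmotaxis difference orders periphery occupancy", {
  coh <- simulate_openfield_cohort(
    n_per_group = 3, seed = 5, session_s = 120,
    group_a = list(coupling_depth = 0.5, p_move = 0.7,
                   thigmotaxis_weight = 0.1, mean_speed = 12),
    group_b = list(coupling_depth = 0.5, p_move = 0.7,
                   thigmotaxis_weight = 0.9, mean_speed = 12))
  res <- run_openfield_analysis(coh, n_boot = 300, n_perm = 300, seed = 1)
  row <- res$comparisons[res$comparisons$measure == "periphery_occupancy", ]
  expect_gt(row$mean_b, row$mean_a)
})

test_that("a designed PAC-mobility correlation survives the pipeline", {
  # 12 subjects whose coupling depth is correlated (r = 0.8 by design) with
  # their mobility; the pipeline's r between movement RVL and periphery
  # mobility should land near the design value.
  set.seed(6)
  n <- 12
  zc <- rnorm(n)
  zm <- 0.8 * zc + sqrt(1 - 0.64) * rnorm(n)
  depth <- pmin(0.95, pmax(0.05, 0.5 + 0.28 * zc))
  pmove <- pmin(0.9, pmax(0.15, 0.5 + 0.2 * zm))
  cohort <- lapply(seq_len(n), function(i) {
    lp <- synth_lfp_params(duration_s = 120, coupling_depth = depth[i],
                           ripple_rate = 0, seed = 100 + i)
    bp <- synth_behavior_params(duration_s = 120, p_move = pmove[i],
                                seed = 200 + i)
    list(subject_id = sprintf("s%02d", i), group = "a",
         sessions = list(novel = list(lfp = generate_lfp(lp),
                                      tracking = generate_tracking(bp))))
  })
  res <- run_openfield_analysis(cohort, n_boot = 300, n_perm = 300, seed = 1)
  row <- res$correlations[res$correlations$x == "rvl_movement" &
                            res$correlations$y == "pct_mobile_periphery", ]
  expect_equal(nrow(row), 1)
  expect_lt(abs(row$r - 0.8), 0.25)
})
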