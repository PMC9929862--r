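# End-to-end workflow drivers: simulate two-group cohorts and run the
# T-maze (SWR/alternation) and open-field (mobility/theta/PAC) analyses,
# producing tidy per-subject tables and group comparisons.

#' Simulate a two-group T-maze cohort
#'
#' Each subject gets a baseline and a consolidation rest-period LFP plus a
#' block of T-maze choices. Group-level effects are injected through the
#' per-group parameter lists; within a group all subjects share the same
#' generative parameters (between-subject variation is estimation noise).
#'
#' @param n_per_group Subjects per group.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param period_s Duration of each rest period in seconds.
#' @param n_trials T-maze trials per subject.
#' @param group_a,group_b Per-group settings: lists with elements
#'   `ripple_rate_baseline`, `ripple_rate_consolidation`, `p_alt`, plus any
#'   overrides for [synth_lfp_params()].
#' @return A cohort manifest: list of subject records with `subject_id`,
#'   `group`, `lfp` (list of `raw_lfp` per period), `truth`, `choices`.
#' @export
simulate_tmaze_cohort <- function(n_per_group = 7, seed = 1, period_s = 300,
                                  n_trials = 10,
                                  group_a = list(ripple_rate_baseline = 0.2,
                                                 ripple_rate_consolidation = 0.2,
                                                 p_alt = 0.8),
                                  group_b = list(ripple_rate_baseline = 0.2,
                                                 ripple_rate_consolidation = 0.5,
                                                 p_alt = 0.5)) {
  groups <- list(a = group_a, b = group_b)
  cohort <- list()
  sid <- 0L
  for (g in names(groups)) {
    gs <- groups[[g]]
    for (i in seq_len(n_per_group)) {
      sid <- sid + 1L
      subj_seed <- (seed * 1000L + sid * 7L) %% .Machine$integer.max
      base_over <- gs[!names(gs) %in%
                        c("ripple_rate_baseline",
                          "ripple_rate_consolidation", "p_alt")]
      mk <- function(rate, s_off, label) {
        p <- do.call(synth_lfp_params,
                     c(list(duration_s = period_s, ripple_rate = rate,
                            seed = subj_seed + s_off), base_over))
        generate_lfp(p, channel = "mPFC",
                     subject_id = sprintf("s%02d", sid), session_id = label)
      }
      cohort[[sid]] <- list(
        subject_id = sprintf("s%02d", sid), group = g,
        sessions = list(
          baseline = mk(gs$ripple_rate_baseline, 1L, "baseline"),
          consolidation = mk(gs$ripple_rate_consolidation, 2L,
                             "consolidation")),
        choices = generate_alternation(gs$p_alt, n_trials,
                                       seed = subj_seed + 3L))
    }
  }
  structure(cohort, class = "tmaze_cohort", seed = seed)
}

#' Run the T-maze analysis on a cohort
#'
#' Per subject: alternation rate, baseline SWR incidence, and the
#' consolidation change normalized to baseline. Group comparisons use the
#' BCa bootstrap mean difference and a permutation test; per-group
#' alternation is additionally tested against the 0.5 chance level by the
#' Wilcoxon signed-rank test when the group is large enough.
#'
#' @param cohort A cohort from [simulate_tmaze_cohort()], or any list of
#'   subject records of the same shape (user data can be assembled with
#'   [raw_lfp()] and a choices data frame).
#' @param n_boot,n_perm Resampling sizes (defaults 5000).
#' @param seed Seed for the resampling layer.
#' @param ... Passed to [preprocess_lfp()].
#' @return A list of class `tmaze_analysis`: `subjects` (tidy data frame),
#'   `comparisons` (one row per measure), `alternation_vs_chance`.
#' @export
run_tmaze_analysis <- function(cohort, n_boot = 5000, n_perm = 5000,
                               seed = 1, ...) {
  if (!length(cohort)) stop("empty cohort")
  rows <- lapply(cohort, function(subj) {
    cats <- lapply(subj$sessions, function(ses) {
      detect_swr(preprocess_lfp(ses$lfp, ...))
    })
    data.frame(
      subject = subj$subject_id, group = subj$group,
      alternation_rate = alternation_rate(subj$choices)$alternation_rate,
      baseline_incidence_hz = cats$baseline$incidence_hz,
      consolidation_incidence_hz = cats$consolidation$incidence_hz,
      normalized_swr_change = normalized_change(cats$baseline,
                                                cats$consolidation),
      stringsAsFactors = FALSE)
  })
  subjects <- do.call(rbind, rows)
  measures <- c("alternation_rate", "baseline_incidence_hz",
                "normalized_swr_change")
  comparisons <- do.call(rbind, lapply(measures, function(m) {
    va <- subjects[[m]][subjects$group == "a"]
    vb <- subjects[[m]][subjects$group == "b"]
    est <- bootstrap_mean_difference(va, vb, n_boot = n_boot, seed = seed)
    perm <- permutation_test(va, vb, n_perm = n_perm, seed = seed)
    data.frame(measure = m, mean_a = mean(va), mean_b = mean(vb),
               mean_diff = est$mean_diff, ci_low = est$ci_low,
               ci_high = est$ci_high, perm_p = perm$p,
               stringsAsFactors = FALSE)
  }))
  chance <- lapply(split(subjects$alternation_rate, subjects$group),
                   function(v) {
                     if (sum(v != 0.5) >= 5) wilcoxon_vs_chance(v, 0.5)
                     else list(V = NA_real_, p = NA_real_, n_used = sum(v != 0.5),
                               method = "too few non-tied values")
                   })
  structure(list(subjects = subjects, comparisons = comparisons,
                 alternation_vs_chance = chance),
            class = "tmaze_analysis")
}

#' @export
print.tmaze_analysis <- function(x, ...) {
  cat("<tmaze_analysis>\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Simulate a two-group open-field cohort
#'
#' Each subject gets concurrent LFP and tracking for each requested session
#' (e.g. novel/familiar). Group effects are injected via the per-group
#' parameter lists.
#'
#' @param n_per_group Subjects per group.
#' @param seed Master seed.
#' @param session_s Session duration, seconds.
#' @param sessions Session labels (default `"novel"` only; add
#'   `"familiar"` for the two-visit design).
#' @param group_a,group_b Lists with `coupling_depth`, `p_move`,
#'   `thigmotaxis_weight`, `mean_speed`, plus overrides for
#'   [synth_lfp_params()].
#' @return A cohort manifest of class `openfield_cohort`.
#' @export
simulate_openfield_cohort <- function(n_per_group = 7, seed = 1,
                                      session_s = 180,
                                      sessions = "novel",
                                      group_a = list(coupling_depth = 0.6,
                                                     p_move = 0.5,
                                                     thigmotaxis_weight = 0.5,
                                                     mean_speed = 12),
                                      group_b = list(coupling_depth = 0.3,
                                                     p_move = 0.35,
                                                     thigmotaxis_weight = 0.7,
                                                     mean_speed = 10)) {
  groups <- list(a = group_a, b = group_b)
  cohort <- list()
  sid <- 0L
  for (g in names(groups)) {
    gs <- groups[[g]]
    for (i in seq_len(n_per_group)) {
      sid <- sid + 1L
      subj_seed <- (seed * 1000L + sid * 11L) %% .Machine$integer.max
      behav_names <- c("p_move", "thigmotaxis_weight", "mean_speed")
      lfp_over <- gs[!names(gs) %in% behav_names]
      ses <- list()
      for (k in seq_along(sessions)) {
        lp <- do.call(synth_lfp_params,
                      c(list(duration_s = session_s, ripple_rate = 0,
                             seed = subj_seed + 10L * k), lfp_over))
        bp <- do.call(synth_behavior_params,
                      c(list(duration_s = session_s,
                             seed = subj_seed + 10L * k + 1L),
                        gs[names(gs) %in% behav_names]))
        ses[[sessions[k]]] <- list(lfp = generate_lfp(lp, channel = "HPC",
                                                      subject_id = sprintf("s%02d", sid),
                                                      session_id = sessions[k]),
                                   tracking = generate_tracking(bp))
      }
      cohort[[sid]] <- list(subject_id = sprintf("s%02d", sid), group = g,
                            sessions = ses)
    }
  }
  structure(cohort, class = "openfield_cohort", seed = seed)
}

#' Run the open-field analysis on a cohort
#'
#' Per subject and session: mobility statistics, theta summaries and
#' theta-gamma PAC split by movement/stationary state; group comparisons of
#' every measure; per-group Pearson correlations of theta power and PAC
#' with periphery occupancy and periphery mobility, with likelihood-ratio
#' slope comparisons between groups.
#'
#' @param cohort A cohort from [simulate_openfield_cohort()] or an
#'   equivalently shaped list.
#' @param n_boot,n_perm Resampling sizes.
#' @param seed Seed for the resampling layer.
#' @param states Epoch states to analyze.
#' @param ... Passed to [preprocess_lfp()].
#' @return A list of class `openfield_analysis`: `subjects`, `comparisons`,
#'   `correlations`, `slope_comparisons`.
#' @export
run_openfield_analysis <- function(cohort, n_boot = 5000, n_perm = 5000,
                                   seed = 1,
                                   states = c("movement", "stationary"),
                                   ...) {
  if (!length(cohort)) stop("empty cohort")
  rows <- list()
  for (subj in cohort) {
    for (ses_name in names(subj$sessions)) {
      ses <- subj$sessions[[ses_name]]
      clean <- preprocess_lfp(ses$lfp$lfp, ...)
      track <- ses$tracking$track
      speed <- compute_speed(track)
      epochs <- segment_epochs(speed, track$frame_rate)
      mob <- mobility_statistics(track, speed, epochs)
      row <- data.frame(subject = subj$subject_id, group = subj$group,
                        session = ses_name,
                        pct_time_mobile = mob$pct_time_mobile,
                        median_speed_mobile = mob$median_speed_mobile,
                        pct_mobile_periphery = mob$pct_mobile_periphery,
                        pct_mobile_center = mob$pct_mobile_center,
                        periphery_occupancy = mob$periphery_occupancy,
                        stringsAsFactors = FALSE)
      for (st in states) {
        iv <- epochs[epochs$state == st, , drop = FALSE]
        specs <- lapply(seq_len(nrow(iv)), function(k) {
          epoch_spectrum(clean, c(iv$start_s[k], iv$end_s[k]))
        })
        usable <- Filter(Negate(is_rejected), specs)
        if (length(usable)) {
          th <- theta_summary(average_and_smooth(usable))
          row[[paste0("theta_peak_", st)]] <- th$peak_freq
          row[[paste0("theta_power_", st)]] <- th$integrated_power
        } else {
          row[[paste0("theta_peak_", st)]] <- NA_real_
          row[[paste0("theta_power_", st)]] <- NA_real_
        }
        pac <- pac_for_epochs(clean, epochs, state = st)
        row[[paste0("rvl_", st)]] <- pac$mean_rvl
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  subjects <- do.call(rbind, rows)
  num_measures <- setdiff(names(subjects), c("subject", "group", "session"))
  comparisons <- list()
  for (ses_name in unique(subjects$session)) {
    ss <- subjects[subjects$session == ses_name, , drop = FALSE]
    for (m in num_measures) {
      va <- ss[[m]][ss$group == "a"]
      vb <- ss[[m]][ss$group == "b"]
      va <- va[is.finite(va)]
      vb <- vb[is.finite(vb)]
      if (length(va) < 3 || length(vb) < 3) next
      est <- bootstrap_mean_difference(va, vb, n_boot = n_boot, seed = seed)
      perm <- permutation_test(va, vb, n_perm = n_perm, seed = seed)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        session = ses_name, measure = m, mean_a = mean(va),
        mean_b = mean(vb), mean_diff = est$mean_diff, ci_low = est$ci_low,
        ci_high = est$ci_high, perm_p = perm$p, stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL
  # behavior-electrophysiology correlations per group, + slope comparisons
  xvars <- c("theta_power_movement", "rvl_movement", "rvl_stationary")
  yvars <- c("periphery_occupancy", "pct_mobile_periphery")
  correlations <- list()
  slope_comparisons <- list()
  for (ses_name in unique(subjects$session)) {
    ss <- subjects[subjects$session == ses_name, , drop = FALSE]
    for (xv in xvars) {
      for (yv in yvars) {
        ok_groups <- TRUE
        for (g in c("a", "b")) {
          sg <- ss[ss$group == g, , drop = FALSE]
          keep <- is.finite(sg[[xv]]) & is.finite(sg[[yv]])
          if (sum(keep) < 3 || stats::sd(sg[[xv]][keep]) == 0) {
            ok_groups <- FALSE
            next
          }
          pc <- pearson_correlation(sg[[xv]][keep], sg[[yv]][keep])
          correlations[[length(correlations) + 1L]] <- data.frame(
            session = ses_name, group = g, x = xv, y = yv, r = pc$r,
            p = pc$p, n = pc$n, stringsAsFactors = FALSE)
        }
        if (ok_groups) {
          sa <- ss[ss$group == "a", , drop = FALSE]
          sb <- ss[ss$group == "b", , drop = FALSE]
          ka <- is.finite(sa[[xv]]) & is.finite(sa[[yv]])
          kb <- is.finite(sb[[xv]]) & is.finite(sb[[yv]])
          cmp <- compare_slopes_lr(sa[[xv]][ka], sa[[yv]][ka],
                                   sb[[xv]][kb], sb[[yv]][kb])
          slope_comparisons[[length(slope_comparisons) + 1L]] <- data.frame(
            session = ses_name, x = xv, y = yv,
            slope_a = cmp$per_group$slope[1], slope_b = cmp$per_group$slope[2],
            lr_statistic = cmp$lr_statistic, lr_p = cmp$lr_p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(
    subjects = subjects, comparisons = comparisons,
    correlations = if (length(correlations)) do.call(rbind, correlations) else NULL,
    slope_comparisons = if (length(slope_comparisons)) {
      do.call(rbind, slope_comparisons)
    } else NULL),
    class = "openfield_analysis")
}

#' @export
print.openfield_analysis <- function(x, ...) {
  cat("<openfield_analysis>\n")
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}
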