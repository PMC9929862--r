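# Estimation-statistics layer: BCa bootstrap mean differences, permutation
# tests, Pearson correlation, regression slope comparison by likelihood
# ratio, Wilcoxon signed-rank against chance.

#' Bootstrap mean difference with BCa confidence interval
#'
#' Point estimate `mean(group_b) - mean(group_a)` with a bootstrap sampling
#' distribution from independent within-group resampling and a 95%
#' bias-corrected and accelerated (BCa) interval: the bias term comes from
#' the bootstrap distribution, the acceleration from a jackknife over all
#' observations. With `paired = TRUE`, pairs are resampled jointly.
#' Quantiles use the type-7 interpolation rule.
#'
#' @param group_a,group_b Numeric vectors (n >= 3 each; equal length if
#'   paired).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed recorded in the result.
#' @param conf Confidence level (default 0.95).
#' @param paired Treat observations as pairs.
#' @return An `estimation_result`: `mean_diff`, `ci_low`, `ci_high`,
#'   `boot_distribution`, `n_boot`, `bias_z0`, `acceleration`, `conf`,
#'   `paired`, `seed`, `degenerate` flag, and `ci_ordered` (FALSE flags the
#'   rare BCa pathology where the interval fails to bracket the estimate;
#'   it is reported, never silently reordered).
#' @examples
#' r <- bootstrap_mean_difference(rnorm(10), rnorm(10, 1), n_boot = 500,
#'                                seed = 1)
#' c(r$mean_diff, r$ci_low, r$ci_high)
#' @export
bootstrap_mean_difference <- function(group_a, group_b, n_boot = 5000,
                                      seed = NULL, conf = 0.95,
                                      paired = FALSE) {
  a <- as.numeric(group_a[is.finite(group_a)])
  b <- as.numeric(group_b[is.finite(group_b)])
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  if (paired && length(a) != length(b)) stop("paired groups must align")
  obs <- mean(b) - mean(a)
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  boot <- with_seed(seed, {
    if (paired) {
      d <- b - a
      idx <- matrix(sample.int(length(d), n_boot * length(d), replace = TRUE),
                    nrow = length(d))
      colMeans(matrix(d[idx], nrow = length(d)))
    } else {
      ia <- matrix(sample.int(length(a), n_boot * length(a), replace = TRUE),
                   nrow = length(a))
      ib <- matrix(sample.int(length(b), n_boot * length(b), replace = TRUE),
                   nrow = length(b))
      colMeans(matrix(b[ib], nrow = length(b))) -
        colMeans(matrix(a[ia], nrow = length(a)))
    }
  })
  alpha <- (1 - conf) / 2
  if (degenerate) {
    lo <- hi <- obs
    z0 <- a_acc <- 0
  } else {
    # bias correction: half-weight on ties for robustness
    p0 <- (sum(boot < obs) + 0.5 * sum(boot == obs)) / length(boot)
    p0 <- min(max(p0, 1 / (length(boot) + 1)),
              1 - 1 / (length(boot) + 1))
    z0 <- stats::qnorm(p0)
    # acceleration: jackknife of the statistic over every observation
    if (paired) {
      d <- b - a
      jk <- vapply(seq_along(d), function(i) mean(d[-i]), numeric(1))
    } else {
      jk <- c(vapply(seq_along(a), function(i) mean(b) - mean(a[-i]),
                     numeric(1)),
              vapply(seq_along(b), function(i) mean(b[-i]) - mean(a),
                     numeric(1)))
    }
    u <- mean(jk) - jk
    denom <- sum(u^2)^1.5
    a_acc <- if (denom > 0) sum(u^3) / (6 * denom) else 0
    zl <- stats::qnorm(alpha)
    zu <- stats::qnorm(1 - alpha)
    adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a_acc * (z0 + z)))
    lo <- stats::quantile(boot, adj(zl), names = FALSE, type = 7)
    hi <- stats::quantile(boot, adj(zu), names = FALSE, type = 7)
  }
  structure(list(mean_diff = obs, ci_low = lo, ci_high = hi,
                 boot_distribution = boot, n_boot = n_boot, bias_z0 = z0,
                 acceleration = a_acc, conf = conf, paired = paired,
                 seed = seed, degenerate = degenerate,
                 ci_ordered = lo <= obs && obs <= hi),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    "<estimation_result> mean difference %.4g, %g%% BCa CI [%.4g, %.4g]%s\n",
    x$mean_diff, 100 * x$conf, x$ci_low, x$ci_high,
    if (!x$ci_ordered) " [WARNING: CI does not bracket the estimate]" else ""))
  if (x$degenerate) cat("  (degenerate: both groups constant)\n")
  invisible(x)
}

#' @export
plot.estimation_result <- function(x, ...) {
  graphics::hist(x$boot_distribution, breaks = 50, main = "",
                 xlab = "bootstrap mean difference", ...)
  graphics::abline(v = c(x$ci_low, x$mean_diff, x$ci_high),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Two-sided permutation test on a difference in group means
#'
#' Proportion of label reshuffles whose absolute mean difference is at least
#' the observed one. When the number of distinct group assignments is at
#' most `n_perm` the null distribution is enumerated exhaustively (exact
#' p); otherwise `n_perm` random reshuffles are drawn and the add-one
#' estimator `(k + 1) / (n_perm + 1)` is reported, which never returns 0.
#'
#' @param group_a,group_b Numeric vectors (total n >= 4).
#' @param n_perm Number of reshuffles (default 5000).
#' @param seed Integer seed for the random reshuffles.
#' @return List with `p`, `observed` (mean difference), `exhaustive`,
#'   `n_perm_used`.
#' @examples
#' permutation_test(c(1, 2), c(10, 11))$p  # exact: 2/6
#' @export
permutation_test <- function(group_a, group_b, n_perm = 5000, seed = NULL) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  na <- length(a)
  nb <- length(b)
  if (na + nb < 4) stop("need at least 4 observations in total")
  pool <- c(a, b)
  n <- na + nb
  obs <- mean(b) - mean(a)
  tol <- 1e-12 * max(1, abs(obs))
  n_comb <- choose(n, na)
  if (n_comb <= n_perm) {
    idx <- utils::combn(n, na)
    tot <- sum(pool)
    diffs <- apply(idx, 2, function(i) {
      (tot - sum(pool[i])) / nb - sum(pool[i]) / na
    })
    p <- mean(abs(diffs) >= abs(obs) - tol)
    list(p = p, observed = obs, exhaustive = TRUE, n_perm_used = n_comb)
  } else {
    k <- with_seed(seed, {
      hits <- 0L
      tot <- sum(pool)
      for (r in seq_len(n_perm)) {
        i <- sample.int(n, na)
        sa <- sum(pool[i])
        if (abs((tot - sa) / nb - sa / na) >= abs(obs) - tol) {
          hits <- hits + 1L
        }
      }
      hits
    })
    list(p = (k + 1) / (n_perm + 1), observed = obs, exhaustive = FALSE,
         n_perm_used = n_perm)
  }
}

#' Pearson correlation with exact-t p value
#'
#' @param x,y Numeric vectors (n >= 3, finite).
#' @return List with `r`, `p`, `n` (`NA` values when either input has zero
#'   variance).
#' @export
pearson_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need n >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare regression slopes between two groups by likelihood ratio
#'
#' Fits (i) a pooled model with a common slope and group-specific intercepts
#' and (ii) a model with group-specific slopes, by least squares with
#' Gaussian likelihood (error variance profiled out), and compares them with
#' a likelihood-ratio test on 1 degree of freedom. Per-group slope,
#' intercept and Pearson correlation are reported alongside.
#'
#' @param x_a,y_a,x_b,y_b Per-group predictor/response vectors (n >= 3
#'   each).
#' @return A `regression_comparison`: per-group coefficient table,
#'   log-likelihoods, `lr_statistic`, `lr_p`.
#' @export
compare_slopes_lr <- function(x_a, y_a, x_b, y_b) {
  if (length(x_a) != length(y_a) || length(x_b) != length(y_b)) {
    stop("x and y must align within each group")
  }
  if (length(x_a) < 3 || length(x_b) < 3) stop("each group needs n >= 3")
  if (stats::sd(x_a) == 0 || stats::sd(x_b) == 0) {
    stop("degenerate design: a group has constant x")
  }
  df <- data.frame(x = c(x_a, x_b), y = c(y_a, y_b),
                   g = factor(rep(c("a", "b"), c(length(x_a), length(x_b)))))
  m0 <- stats::lm(y ~ x + g, data = df)
  m1 <- stats::lm(y ~ x * g, data = df)
  rss0 <- sum(stats::residuals(m0)^2)
  rss1 <- sum(stats::residuals(m1)^2)
  eps <- .Machine$double.eps * nrow(df) * max(1, stats::var(df$y))
  if (rss1 < eps && rss0 < eps) {
    lr <- 0  # both models fit perfectly (e.g. both groups on one line)
  } else if (rss1 < eps) {
    lr <- Inf
  } else {
    lr <- nrow(df) * log(rss0 / rss1)
  }
  lr <- max(0, lr)
  per_group <- do.call(rbind, lapply(
    list(a = list(x_a, y_a), b = list(x_b, y_b)),
    function(gr) {
      fit <- stats::lm(gr[[2]] ~ gr[[1]])
      r <- if (stats::sd(gr[[2]]) > 0) {
        pearson_correlation(gr[[1]], gr[[2]])
      } else {
        list(r = NA_real_, p = NA_real_)
      }
      data.frame(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 pearson_r = r$r, r_p = r$p, n = length(gr[[1]]))
    }))
  structure(list(per_group = per_group,
                 loglik_common_slope = as.numeric(stats::logLik(m0)),
                 loglik_group_slopes = as.numeric(stats::logLik(m1)),
                 lr_statistic = lr,
                 lr_p = stats::pchisq(lr, df = 1, lower.tail = FALSE)),
            class = "regression_comparison")
}

#' @export
print.regression_comparison <- function(x, ...) {
  cat("<regression_comparison>\n")
  print(x$per_group)
  cat(sprintf("  LR statistic %.4g (df = 1), p = %.4g\n",
              x$lr_statistic, x$lr_p))
  invisible(x)
}

#' Wilcoxon signed-rank test against a reference value
#'
#' Tests whether values are symmetric around `mu0` (e.g. alternation rates
#' against the 0.5 chance level). Exact null distribution for n <= 25
#' without ties in the absolute deviations (delegated to
#' [stats::wilcox.test()]); with ties and n <= 14 the exact distribution is
#' enumerated over all sign patterns of the tied ranks; otherwise the
#' normal approximation with tie correction is used. Values exactly equal
#' to `mu0` are dropped first.
#'
#' @param values Numeric vector (n >= 5 after dropping exact ties with
#'   `mu0`).
#' @param mu0 Reference value (default 0.5).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `V` (signed-rank statistic), `p`, `n_used`, `method`.
#' @examples
#' wilcoxon_vs_chance(c(0.6, 0.7, 0.8), alternative = "greater",
#'                    min_n = 3)$p  # exact 1/8
#' @export
wilcoxon_vs_chance <- function(values, mu0 = 0.5,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               min_n = 5) {
  alternative <- match.arg(alternative)
  d <- values[is.finite(values)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(V = NA_real_, p = NA_real_, n_used = 0L,
                method = "undefined (all values tie the reference)"))
  }
  if (n < min_n) stop("need at least ", min_n, " non-tied values")
  ranks <- rank(abs(d))
  V <- sum(ranks[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= 25) {
    wt <- stats::wilcox.test(values[is.finite(values)], mu = mu0,
                             alternative = alternative, exact = TRUE)
    return(list(V = unname(wt$statistic), p = wt$p.value, n_used = n,
                method = "exact signed-rank"))
  }
  if (has_ties && n <= 14) {
    # enumerate all 2^n sign patterns of the tied ranks
    stats_all <- 0
    for (i in seq_len(n)) {
      stats_all <- as.vector(outer(stats_all, c(0, ranks[i]), "+"))
    }
    p <- switch(alternative,
                greater = mean(stats_all >= V),
                less = mean(stats_all <= V),
                two.sided = min(1, 2 * min(mean(stats_all >= V),
                                           mean(stats_all <= V))))
    return(list(V = V, p = p, n_used = n,
                method = "exact signed-rank (tie enumeration)"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values[is.finite(values)], mu = mu0,
                       alternative = alternative, exact = FALSE,
                       correct = TRUE))
  list(V = unname(wt$statistic), p = wt$p.value, n_used = n,
       method = "normal approximation")
}
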