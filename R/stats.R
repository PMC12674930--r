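#' Aggregate per-fold test accuracies
#'
#' Computes the cross-testing aggregate: mean test accuracy
#' \eqn{\bar t = \frac1k \sum_i t_i}, sample standard deviation (n-1
#' denominator), standard error \eqn{SE = \sigma_t / \sqrt k}, and the
#' two-sided Student-t confidence interval with \eqn{k - 1} degrees of
#' freedom. Averaging across k held-out folds shrinks the uncertainty of
#' the performance estimate by \eqn{\sqrt k} relative to a single fold.
#'
#' @param t_values numeric vector of per-fold test accuracies (length >= 2).
#' @param confidence confidence level for the interval (default 0.95).
#' @return list(mean, sd, se, ci, df, level, k).
#' @examples
#' aggregateTestStats(c(0.79, 0.71, 0.69, 0.82))
#' @export
aggregateTestStats <- function(t_values, confidence = 0.95) {
  k <- length(t_values)
  if (k < 2L) stop("insufficient folds: need >= 2 test accuracies")
  m <- mean(t_values)
  s <- stats::sd(t_values)
  se <- s / sqrt(k)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = k - 1L)
  list(mean = m, sd = s, se = se, ci = c(m - tq * se, m + tq * se),
       df = k - 1L, level = confidence, k = k)
}

#' Pooled-SD Cohen's d
#'
#' Standardized mean difference between two groups using the pooled standard
#' deviation \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}};
#' with equal group sizes this reduces to \eqn{\sqrt{(s_1^2+s_2^2)/2}}.
#' Antisymmetric in group order: \code{cohensD(a, b) == -cohensD(b, a)}.
#'
#' @param mean1,sd1,n1 summary of group 1 (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 summary of group 2.
#' @return the effect size d.
#' @examples
#' cohensD(0.811, 0.008, 4, 0.750, 0.061, 4)  # ~1.40
#' @export
cohensD <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("negative SD")
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("degenerate groups: zero pooled SD")
  (mean1 - mean2) / pooled
}

#' Compare partitioning schemes on per-fold accuracies
#'
#' Given per-fold test accuracies obtained under two or more partitioning
#' schemes (e.g. image-, patient- and dataset-level folds), performs a
#' one-way fixed-effects ANOVA on the raw accuracies, estimates variance
#' components by the balanced method of moments (treatment component
#' \eqn{(MS_{between} - MS_{within}) / n} per group, truncated at zero;
#' residual component \eqn{MS_{within}}), runs Tukey HSD post-hoc
#' comparisons on studentized-range quantiles, and reports all pairwise
#' pooled-SD Cohen's d effect sizes.
#'
#' When every accuracy is identical the between- and within-group sums of
#' squares are both zero; F and all d are reported as 0 rather than NaN.
#'
#' @param accuracies_by_scheme named list: scheme -> numeric vector of
#'   per-fold accuracies (each length >= 2).
#' @return list of class \code{partition_comparison} with elements
#'   \code{anova} (F, p, df), \code{variance_components} (treatment,
#'   residual, treatment_truncated), \code{tukey} (data.frame of pairwise
#'   mean differences, CIs, adjusted p), \code{effect_sizes} (data.frame of
#'   pairwise Cohen's d), \code{groups} (per-scheme mean, sd, n) and
#'   \code{balanced}.
#' @export
comparePartitionings <- function(accuracies_by_scheme) {
  schemes <- names(accuracies_by_scheme)
  if (length(schemes) < 2L) stop("need >= 2 schemes")
  ns <- lengths(accuracies_by_scheme)
  if (any(ns < 2L)) stop("every scheme needs >= 2 fold accuracies")
  balanced <- length(unique(ns)) == 1L
  df <- data.frame(
    accuracy = unlist(accuracies_by_scheme, use.names = FALSE),
    scheme = factor(rep(schemes, ns), levels = schemes))
  fit <- stats::aov(accuracy ~ scheme, data = df)
  at <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      # constant data triggers a "perfect fit" warning; handled below
      if (grepl("perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  msb <- at["scheme", "Mean Sq"]
  msw <- at["Residuals", "Mean Sq"]
  ssb <- at["scheme", "Sum Sq"]
  sst <- ssb + at["Residuals", "Sum Sq"]
  # constant data: both sums of squares vanish; define F = 0, not 0/0
  degenerate <- ssb <= 1e-12 * max(sst, 1)
  Fstat <- if (degenerate) 0 else at["scheme", "F value"]
  pval <- if (degenerate) 1 else at["scheme", "Pr(>F)"]
  # balanced method-of-moments; for unbalanced designs use the average n
  n0 <- if (balanced) ns[1] else mean(ns)
  treatment_raw <- (msb - msw) / n0
  tk <- stats::TukeyHSD(fit)$scheme
  tukey <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"],
    lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE)
  groups <- data.frame(
    scheme = schemes,
    mean = vapply(accuracies_by_scheme, mean, 0),
    sd = vapply(accuracies_by_scheme, stats::sd, 0),
    n = as.integer(ns), row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(schemes, 2)
  d <- apply(pairs, 2, function(p) {
    g1 <- groups[groups$scheme == p[1], ]
    g2 <- groups[groups$scheme == p[2], ]
    pooled <- sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) /
                     (g1$n + g2$n - 2))
    if (pooled == 0) {
      if (g1$mean == g2$mean) 0 else Inf * sign(g1$mean - g2$mean)
    } else (g1$mean - g2$mean) / pooled
  })
  effect_sizes <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], d = d,
    stringsAsFactors = FALSE)
  structure(list(
    anova = list(F = Fstat, p = pval,
                 df = c(between = unname(at["scheme", "Df"]),
                        within = unname(at["Residuals", "Df"]))),
    variance_components = list(
      treatment = max(treatment_raw, 0), residual = msw,
      treatment_truncated = treatment_raw < 0),
    tukey = tukey, effect_sizes = effect_sizes, groups = groups,
    balanced = balanced),
    class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat("Partition-scheme comparison (one-way ANOVA)\n")
  cat(sprintf("  F(%d, %d) = %.2f, p = %.4g\n", x$anova$df["between"],
              x$anova$df["within"], x$anova$F, x$anova$p))
  cat(sprintf("  variance components: treatment %.6f%s, residual %.6f\n",
              x$variance_components$treatment,
              if (x$variance_components$treatment_truncated)
                " (truncated at 0)" else "",
              x$variance_components$residual))
  cat("  group summaries:\n")
  print(x$groups, row.names = FALSE)
  cat("  Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  cat("  Cohen's d:\n")
  print(x$effect_sizes, row.names = FALSE)
  invisible(x)
}

#' Reconstruct a sample with an exact mean and SD
#'
#' Utility for recomputing summary-level statistics (ANOVA, effect sizes)
#' when only group means and SDs are published: returns \code{n} values with
#' exactly the requested sample mean and SD (n-1 denominator).
#'
#' @param mean,sd,n target sample moments.
#' @return numeric vector of length n.
#' @export
sampleWithMoments <- function(mean, sd, n) {
  if (n < 2L) stop("need n >= 2")
  z <- seq_len(n) - (n + 1) / 2
  z <- z / sqrt(sum(z^2) / (n - 1))
  mean + sd * z
}
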