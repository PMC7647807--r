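# Routed paired-statistics protocol: min-max phase normalization,
# Shapiro-Wilk gated paired t / Wilcoxon comparisons, Cohen's d with effect
# bands, noncentral-t post hoc power, Order x Condition ANOVA, correlation
# routing, Bonferroni thresholds, and the sensitivity subsets.

#' Min-max normalize a subject's four phase values
#'
#' Rescales one subject's metric across the four experimental phases
#' (Relaxation, Stressor, tRelaxed, tStressed) to `[0, 1]`:
#' `(v - min) / (max - min)`. Order is preserved.
#'
#' @param values Named numeric vector of the four phase values.
#' @return Normalized vector (same names).
#' @export
#' @examples
#' minmax_normalize(c(Relaxation = 2.27, tRelaxed = 3.78,
#'                    Stressor = 6.22, tStressed = 4.50))
minmax_normalize <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0)
    stop("degenerate normalization: all phase values equal", call. = FALSE)
  (values - rng[1]) / diff(rng)
}

#' During-phase self-report value
#'
#' The self-report level *during* a phase is the mean of the marker values
#' immediately before and after it (e.g. the mean of SR4 and SR5 gives the
#' during-tStressed value for the Relax-Stress arm).
#'
#' @param before,after Marker values (scalars or vectors).
#' @return Their arithmetic mean.
#' @export
during_phase_value <- function(before, after) {
  if (any(is.na(before)) || any(is.na(after)))
    stop("missing self-report marker", call. = FALSE)
  (before + after) / 2
}

#' Cohen's d effect-size band
#' @param d Cohen's d.
#' @return `"negligible"` (<0.20), `"small"` (0.20-0.49), `"medium"`
#'   (0.50-0.79) or `"large"` (>= 0.80), judged on `|d|`.
#' @export
effect_band <- function(d) {
  ad <- abs(d)
  if (ad < 0.20) "negligible"
  else if (ad < 0.50) "small"
  else if (ad < 0.80) "medium"
  else "large"
}

#' Cohen's d between two condition vectors
#'
#' `d = (mean(y) - mean(x)) / s_pooled` with the SD pooled across the two
#' condition vectors (the `d_av` convention — the one that reproduces the
#' study's printed effect sizes from its condition means/SDs, unlike
#' `dz = t/sqrt(n)`).
#'
#' @param x,y Condition vectors (relaxed, stressed).
#' @return List with `d` and `band`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) stop("zero pooled SD", call. = FALSE)
  d <- (mean(y) - mean(x)) / sp
  list(d = d, band = effect_band(d))
}

#' Post hoc power of a paired t-test
#'
#' Computed from the noncentral t distribution with `n - 1` degrees of
#' freedom and noncentrality `dz * sqrt(n)`. One-tailed by default, matching
#' the protocol's directional tests.
#'
#' @param dz Standardized effect size used for the noncentrality.
#' @param n Number of pairs.
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' round(100 * power_paired_t(0.73, 18))  # 91
power_paired_t <- function(dz, n, alpha = 0.05, tails = 1) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (tails == 1) {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(crit, df, ncp = ncp)) + stats::pt(-crit, df, ncp = ncp)
  }
}

#' Routed paired comparison
#'
#' Applies the protocol's test routing: a Shapiro-Wilk test on the paired
#' differences at alpha = .05 decides between a 1-tailed paired t-test
#' (differences normal) and a 1-tailed Wilcoxon signed-rank test (not
#' normal; normal approximation with continuity correction for n >= 10,
#' exact distribution below). Cohen's d (pooled across conditions) and its
#' post hoc power are attached.
#'
#' @param x,y Paired condition vectors (`y` is the condition expected to be
#'   higher under `alternative = "greater"`).
#' @param alternative Direction of the one-tailed test on `y - x`.
#' @param alpha Significance level used for routing and power.
#' @return An object of class `"stat_test_result"`: `test_name`
#'   (`"paired_t"` or `"wilcoxon_signed_rank"`), `statistic`, `p_value`
#'   (one-tailed), `n`, `shapiro_p`, `cohens_d`, `effect_band`,
#'   `power_beta`.
#' @export
paired_compare <- function(x, y, alternative = c("greater", "less"),
                           alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stop("need at least 5 pairs", call. = FALSE)
  d <- y - x
  if (all(d == 0))
    stop("all paired differences are zero: signed-rank test undefined", call. = FALSE)
  sw <- stats::shapiro.test(d)
  if (sw$p.value > alpha) {
    tt <- stats::t.test(y, x, paired = TRUE, alternative = alternative)
    test_name <- "paired_t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      y, x, paired = TRUE, alternative = alternative,
      exact = n < 10, correct = TRUE))
    test_name <- "wilcoxon_signed_rank"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  es <- cohens_d(x, y)
  structure(list(test_name = test_name, statistic = statistic, p_value = p,
                 n = n, shapiro_p = sw$p.value, cohens_d = es$d,
                 effect_band = es$band,
                 power_beta = power_paired_t(abs(es$d), n, alpha, tails = 1)),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, one-tailed p = %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n))
  cat(sprintf("  Cohen's d = %.3f (%s), post hoc power = %.1f%% (Shapiro-Wilk p = %.3f)\n",
              x$cohens_d, x$effect_band, 100 * x$power_beta, x$shapiro_p))
  invisible(x)
}

#' Order-by-Condition interaction ANOVA
#'
#' Tests whether the condition effect depends on the counterbalancing arm
#' (Relax-Stress vs Stress-Relax) with a two-way ANOVA on the stacked
#' per-subject condition values, returning the interaction F. With n
#' subjects the interaction is tested on (1, 2n - 4) error degrees of
#' freedom (so (1, 32) at n = 18).
#'
#' @param values Numeric vector, one entry per subject x condition.
#' @param order_arm Arm label per entry (`"Relax-Stress"`/`"Stress-Relax"`).
#' @param condition Condition label per entry.
#' @return An object of class `"anova_result"`: `F`, `df1`, `df2`, `p`.
#' @export
order_condition_anova <- function(values, order_arm, condition) {
  stopifnot(length(values) == length(order_arm),
            length(values) == length(condition))
  arm_counts <- table(order_arm) / length(unique(condition))
  if (any(arm_counts < 2))
    stop("each arm needs at least 2 subjects", call. = FALSE)
  dat <- data.frame(v = values, arm = factor(order_arm),
                    cond = factor(condition))
  fm <- stats::aov(v ~ arm * cond, data = dat)
  tab <- summary(fm)[[1]]
  row <- grep("arm:cond", rownames(tab))
  structure(list(F = tab[row, "F value"], df1 = tab[row, "Df"],
                 df2 = tab["Residuals", "Df"],
                 p = tab[row, "Pr(>F)"]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Order x Condition interaction: F(%d,%d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Routed bivariate correlation
#'
#' Pearson if both vectors pass Shapiro-Wilk normality at alpha = .05,
#' Spearman's rho otherwise.
#'
#' @param x,y Numeric vectors of equal length (>= 5).
#' @param alpha Routing significance level.
#' @return List with `method` (`"pearson"`/`"spearman"`), `estimate`, `p_value`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  normal <- stats::shapiro.test(x)$p.value > alpha &&
    stats::shapiro.test(y)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(method = method, estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Initial-fraction sensitivity subset
#'
#' The trials closest to the stress induction: the first
#' `round(fraction * n)` trials in production order (4 of 40 at the default
#' 10%).
#'
#' @param trials Data frame or vector in production order.
#' @param fraction Fraction in (0, 1].
#' @return The leading subset (same type as `trials`).
#' @export
subset_initial <- function(trials, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0,1]", call. = FALSE)
  n <- if (is.data.frame(trials)) nrow(trials) else length(trials)
  k <- max(1L, round(fraction * n))
  if (is.data.frame(trials)) trials[seq_len(k), , drop = FALSE]
  else trials[seq_len(k)]
}

#' Decimated sensitivity subset
#'
#' Emulates a low trial-production rate: keeps the first trial, the last
#' trial, and two seeded uniform draws without replacement from the
#' interior — exactly four trials.
#'
#' @param trials Data frame or vector with at least 4 trials.
#' @param seed Integer seed for the interior draws.
#' @return Subset of exactly 4 trials, in production order.
#' @export
subset_decimated <- function(trials, seed = 1L) {
  n <- if (is.data.frame(trials)) nrow(trials) else length(trials)
  if (n < 4) stop("need at least 4 trials", call. = FALSE)
  set.seed(as.integer(seed))
  interior <- if (n > 4) sample(2:(n - 1), 2) else 2:3
  idx <- sort(unique(c(1L, interior, n)))
  if (is.data.frame(trials)) trials[idx, , drop = FALSE] else trials[idx]
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise alpha.
#' @param m Number of comparisons (>= 1).
#' @return List with `threshold` (exact `family_alpha / m`) and `display`
#'   (rounded to 3 decimals, as conventionally reported: 0.05/3 -> 0.017).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 3L) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  thr <- family_alpha / m
  list(threshold = thr, display = round(thr, 3))
}
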