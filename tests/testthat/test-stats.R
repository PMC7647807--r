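test_that("min-max normalization matches hand arithmetic", {
  v <- c(Relaxation = 2.27, tRelaxed = 3.78, Stressor = 6.22,
         tStressed = 4.50)
  out <- minmax_normalize(v)
  expect_equal(unname(round(out, 4)), c(0, 0.3823, 1, 0.5646))
  expect_equal(minmax_normalize(c(0, 1)), c(0, 1))
  expect_equal(order(minmax_normalize(c(3, 1, 2, 5))), order(c(3, 1, 2, 5)))
  expect_error(minmax_normalize(rep(4, 4)), "degenerate")
})

test_that("during-phase values average the flanking markers", {
  expect_equal(during_phase_value(2, 4), 3)
  expect_equal(during_phase_value(7, 7), 7)
  expect_equal(during_phase_value(c(1, 2), c(3, 4)), c(2, 3))
  expect_error(during_phase_value(NA, 3), "missing")
})

test_that("paired comparison routes via Shapiro-Wilk on differences", {
  # clear separation: one-tailed p is tiny
  set.seed(91)
  x <- rnorm(18, 10, 0.1)
  y <- x + 2 + rnorm(18, 0, 0.01)
  res <- paired_compare(x, y, "greater")
  expect_lt(res$p_value, 0.001)
  expect_s3_class(res, "stat_test_result")

  # normal differences route to the t test ~95% of the time
  routes <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    x <- rnorm(30); y <- x + rnorm(30, 1, 1)
    paired_compare(x, y)$test_name
  }, "")
  expect_gt(mean(routes == "paired_t"), 0.88)
  expect_lt(mean(routes == "paired_t"), 0.99)

  # heavy-tailed differences route predominantly to Wilcoxon
  routes_c <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    x <- rnorm(30); y <- x + rcauchy(30)
    paired_compare(x, y)$test_name
  }, "")
  expect_gt(mean(routes_c == "wilcoxon_signed_rank"), 0.7)

  expect_error(paired_compare(1:10, 1:10), "zero")
  expect_error(paired_compare(1:4, 2:5), "at least 5")
})

test_that("routing is invariant to affine rescaling of the raw inputs", {
  for (i in 1:20) {
    set.seed(4000 + i)
    x <- rnorm(20, 5, 2); y <- x + rexp(20) - 0.5
    a <- paired_compare(x, y)$test_name
    b <- paired_compare(10 + 3.2 * x, 10 + 3.2 * y)$test_name
    expect_identical(a, b)
  }
})

test_that("Cohen's d uses the pooled across-condition SD with stated bands", {
  # vectors with exactly the printed condition moments (mean 0.40 SD 0.18
  # vs mean 0.55 SD 0.16) reproduce the printed effect size
  mk <- function(n, m, s) { v <- rnorm(n); m + s * (v - mean(v)) / sd(v) }
  set.seed(92)
  x <- mk(18, 0.40, 0.18)
  y <- mk(18, 0.55, 0.16)
  es <- cohens_d(x, y)
  expect_equal(es$d, 0.8808, tolerance = 1e-3)
  expect_equal(es$band, "large")

  expect_equal(effect_band(0.76), "medium")
  expect_equal(effect_band(0.19), "negligible")
  expect_equal(effect_band(0.20), "small")
  expect_equal(effect_band(-0.9), "large")
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero pooled SD")
})

test_that("post hoc power reproduces the study's printed values", {
  expect_equal(round(100 * power_paired_t(0.73, 18)), 91)
  expect_equal(round(100 * power_paired_t(0.44, 18)), 56)
  expect_gte(power_paired_t(0.87, 18), 0.97)
  expect_gt(power_paired_t(5, 18), 0.9999)
  # two-tailed power is lower at the same dz
  expect_lt(power_paired_t(0.5, 18, tails = 2), power_paired_t(0.5, 18))
})

test_that("power agrees with a Monte-Carlo oracle across the dz grid", {
  set.seed(93)
  for (dz in c(0.44, 0.87)) {
    mc <- mc_power_paired_t(dz, 18, reps = 4000)
    expect_equal(mc, power_paired_t(dz, 18), tolerance = 0.02)
  }
})

test_that("the interaction ANOVA reports the study's degrees of freedom", {
  set.seed(94)
  n <- 18
  arm <- rep(c("Relax-Stress", "Stress-Relax"), c(8, 10))
  subj_effect <- rnorm(n)
  vals <- c(subj_effect + rnorm(n, 0, 0.1),        # tRelaxed
            subj_effect + 1 + rnorm(n, 0, 0.1))    # tStressed, same shift
  res <- order_condition_anova(vals, rep(arm, 2),
                               rep(c("tRelaxed", "tStressed"), each = n))
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 32)
  # condition effect identical in both arms: interaction F near zero
  expect_lt(res$F, 4)

  # arm-specific effect: interaction detected at large n
  n2 <- 200
  arm2 <- rep(c("Relax-Stress", "Stress-Relax"), each = n2 / 2)
  base <- rnorm(n2)
  shift <- ifelse(arm2 == "Relax-Stress", 2, 0)
  vals2 <- c(base + rnorm(n2, 0, 0.3), base + shift + rnorm(n2, 0, 0.3))
  res2 <- order_condition_anova(vals2, rep(arm2, 2),
                                rep(c("tRelaxed", "tStressed"), each = n2))
  expect_lt(res2$p, 0.001)

  expect_error(order_condition_anova(
    c(1, 2, 3, 4), c("Relax-Stress", "Relax-Stress", "Relax-Stress",
                     "Stress-Relax") ,
    c("tRelaxed", "tStressed", "tRelaxed", "tStressed")), "2 subjects")
})

test_that("correlation routes between Pearson and Spearman", {
  x <- c(1.2, 2.1, 2.9, 4.2, 5.1, 6.3, 7.2, 8.1)
  expect_equal(correlate(x, x * 2 + 1)$estimate, 1)
  expect_equal(correlate(x, -x)$estimate, -1)
  # monotone nonlinear pair: Spearman route, rho = 1 > Pearson r
  y <- exp(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  xm <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  res <- correlate(xm, y)
  expect_equal(res$method, "spearman")
  expect_equal(res$estimate, 1)
  expect_gt(res$estimate, cor(xm, y))
  expect_error(correlate(x, rep(1, 8)), "constant")
})

test_that("sensitivity subsets pick the protocol's trials", {
  trials <- data.frame(id = 1:40)
  expect_equal(subset_initial(trials, 0.10)$id, 1:4)
  expect_equal(subset_initial(trials, 1)$id, 1:40)
  expect_equal(subset_initial(data.frame(id = 1:10), 0.10)$id, 1L)
  expect_error(subset_initial(trials, 0), "fraction")
  expect_error(subset_initial(trials, 1.2), "fraction")

  dec <- subset_decimated(trials, seed = 5)
  expect_equal(nrow(dec), 4)
  expect_true(all(c(1, 40) %in% dec$id))
  expect_true(all(dec$id[!dec$id %in% c(1, 40)] %in% 2:39))
  expect_equal(subset_decimated(trials, seed = 5)$id, dec$id)
  expect_false(identical(subset_decimated(trials, seed = 6)$id, dec$id))
  expect_equal(subset_decimated(data.frame(id = 1:4), 1)$id, 1:4)
  expect_error(subset_decimated(data.frame(id = 1:3)), "at least 4")
})

test_that("Bonferroni thresholds divide the family alpha", {
  b <- bonferroni_alpha(0.05, 3)
  expect_equal(b$threshold, 0.05 / 3)
  expect_equal(b$display, 0.017)
  expect_equal(bonferroni_alpha(0.05, 1)$threshold, 0.05)
  ms <- vapply(1:6, function(m) bonferroni_alpha(0.05, m)$threshold, 0)
  expect_true(all(diff(ms) < 0))
  expect_error(bonferroni_alpha(0.05, 0), "m")
})
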