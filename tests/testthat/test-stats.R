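test_that("one-sample test against unity matches the t formula", {
  r <- one_sample_vs_unity(c(0.9, 1.0, 1.1))
  expect_equal(r$estimate, 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # zero variance is flagged degenerate rather than producing a t statistic
  rd <- one_sample_vs_unity(rep(0.95, 10))
  expect_true(rd$degenerate)
  expect_equal(rd$estimate, 0.95)
  # frozen normal sample: statistic equals (mean - 1) / (sd / sqrt(n))
  set.seed(314)
  x <- rnorm(20, 0.975, 0.035)
  r2 <- one_sample_vs_unity(x)
  expect_equal(r2$method, "t")
  expect_equal(r2$statistic, (mean(x) - 1) / (sd(x) / sqrt(20)))
  expect_equal(r2$p, 2 * pt(-abs(r2$statistic), df = 19))
  # grossly non-normal data fall through to the signed-rank branch
  set.seed(99)
  y <- 1 + rexp(40)^3
  r3 <- one_sample_vs_unity(y)
  expect_lt(r3$normality_p, 0.05)
  expect_equal(r3$method, "wilcoxon")
  expect_error(one_sample_vs_unity(c(1, 2)), "at least 3")
})

test_that("group comparison recovers planted differences", {
  # zero-variance groups: the pairwise mean difference is exact
  x <- c(rep(1.00, 5), rep(0.96, 5), rep(1.00, 5))
  g <- rep(c("AD", "MCI", "CN"), each = 5)
  gc <- group_compare(x, g)
  pw <- gc$pairwise
  expect_equal(pw$mean_diff[pw$contrast == "AD - MCI"], 0.04)
  expect_equal(pw$mean_diff[pw$contrast == "MCI - CN"], -0.04)
  # planted MCI - CN difference, averaged over replicates
  set.seed(11)
  diffs <- replicate(60, {
    xm <- rnorm(27, 0.902, 0.035); xc <- rnorm(21, 0.940, 0.035)
    mean(xm) - mean(xc)
  })
  expect_lt(abs(mean(diffs) - (-0.038)), 0.005)
  # tiny groups are dropped with a warning
  expect_warning(group_compare(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "n < 2")
  # null case: omnibus p is not extreme under permuted labels
  set.seed(5)
  xn <- rnorm(90, 1, 0.03)
  gn <- sample(rep(c("AD", "MCI", "CN"), each = 30))
  expect_gt(group_compare(xn, gn)$omnibus$p, 1e-4)
})

test_that("adjusted regression reproduces closed-form OLS", {
  # noiseless cohort: the planted coefficient is recovered exactly
  cfg <- phantom_config(seed = 21)
  cfg$cognition_model$residual_sd <- 0
  s <- make_cohort(cfg)$subjects
  fit <- adjusted_regression(s, score = "score", ratio = "ratio_abeta",
                             wmh_volume = "wmh_volume_ml")
  expect_equal(fit$estimate, -37.8, tolerance = 1e-8)
  # closed-form normal equations on a small frozen design
  set.seed(8)
  df <- data.frame(ratio = runif(12, 0.9, 1.1), age = runif(12, 60, 80),
                   education = runif(12, 6, 16), wmh_volume_ml = runif(12, 1, 30))
  df$score <- 30 - 20 * df$ratio + 0.1 * df$age + rnorm(12)
  X <- cbind(1, df$ratio, df$age, df$education, df$wmh_volume_ml)
  beta <- solve(t(X) %*% X, t(X) %*% df$score)
  r <- adjusted_regression(df)
  expect_equal(r$estimate, beta[2, 1])
  # collinear design is flagged, no coefficient reported
  df2 <- df
  df2$education <- 2 * df2$age
  r2 <- adjusted_regression(df2)
  expect_true(r2$degenerate)
  expect_true(is.na(r2$estimate))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(77)
  for (rep in 1:100) {
    m <- sample(1:20, 1)
    p <- runif(m)
    adj <- bh_adjust(p)
    expect_lt(max(abs(adj - brute_force_bh(p))), 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order preserved
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("longitudinal standardization anchors follow-up to baseline", {
  set.seed(3)
  b <- rnorm(23, 0.976, 0.034)
  f <- b - 0.033
  z <- standardize_longitudinal(b, f)
  expect_equal(mean(z$z_baseline), 0)
  expect_equal(sd(z$z_baseline), 1)
  expect_equal(standardize_longitudinal(b, b)$z_month12, z$z_baseline)
  # worked example on the cohort scale: a follow-up MMSE of 19.6 anchored to
  # a baseline with mean 21.4 and SD 5.1 standardizes to (19.6-21.4)/5.1
  mm <- c(16.3, 26.5)                     # two-point sample: mean 21.4, SD 5.1*sqrt(2)
  zm <- standardize_longitudinal(mm, c(19.6, 19.6))
  expect_equal(zm$z_month12[1], (19.6 - 21.4) / (5.1 * sqrt(2)))
  expect_equal(round((19.6 - 21.4) / 5.1, 3), -0.353)
  expect_error(standardize_longitudinal(rep(1, 5), rep(1, 5)), "SD is zero")
})

test_that("the paired change test is the two-timepoint repeated-measures ANOVA", {
  b <- c(0.97, 0.95, 0.99, 0.96, 0.94, 0.98)
  expect_equal(paired_change_test(b, b)$estimate, 0)
  expect_equal(paired_change_test(b, b)$p, 1)
  # constant shift with zero change variance: degenerate but estimable
  r <- paired_change_test(b, b - 0.03)
  expect_true(r$degenerate)
  expect_equal(r$estimate, -0.03)
  # F = t^2 against a generic two-timepoint repeated-measures decomposition
  set.seed(21)
  b2 <- rnorm(12, 0.97, 0.03)
  f2 <- b2 + rnorm(12, -0.03, 0.02)
  pct <- paired_change_test(b2, f2)
  long <- data.frame(y = c(b2, f2),
                     time = factor(rep(c("t0", "t1"), each = 12)),
                     id = factor(rep(1:12, 2)))
  rm_aov <- summary(aov(y ~ time + Error(id), data = long))
  F_time <- rm_aov[["Error: Within"]][[1]]["time", "F value"]
  expect_equal(unname(pct$F), unname(F_time))
  expect_equal(pct$statistic^2, unname(F_time))
})

test_that("slope comparison contrasts standardized ratio and MMSE declines", {
  # identical standardized changes: difference 0, p = 1 (degenerate path)
  rec <- longitudinal_records(c(1, 2, 3, 4), c(0.5, 1.5, 2.5, 3.5),
                              c(10, 20, 30, 40), c(5, 15, 25, 35))
  sc <- slope_comparison(rec)
  expect_equal(sc$estimate, 0)
  expect_equal(sc$p, 1)
  # ratio declining while MMSE is constant gives a negative contrast
  set.seed(4)
  b <- rnorm(23, 0.976, 0.034)
  m <- rnorm(23, 21.4, 5.1)
  rec2 <- longitudinal_records(b, b - 0.033 + rnorm(23, 0, 0.01), m, m)
  sc2 <- slope_comparison(rec2)
  expect_lt(sc2$estimate, 0)
  expect_lt(sc2$p, 0.05)
})

test_that("cohort_stats assembles one-sample and group analyses with BH", {
  set.seed(10)
  n <- 40
  tab <- rbind(
    data.frame(subject = sprintf("s%02d", 1:n), parcel = "dWMH", level = "low",
               metric = "thickness", average = rnorm(n, 0.96, 0.03)),
    data.frame(subject = sprintf("s%02d", 1:n), parcel = "dWMH", level = "low",
               metric = "sv2a_suvr", average = rnorm(n, 0.92, 0.03)),
    data.frame(subject = sprintf("s%02d", 1:n), parcel = "dWMH",
               level = "medium", metric = "thickness",
               average = rnorm(n, 0.95, 0.04)))
  subj <- data.frame(subject = sprintf("s%02d", 1:n),
                     group = sample(rep(c("AD", "MCI", "CN"), length.out = n)))
  out <- cohort_stats(tab, subj)
  expect_equal(nrow(out$one_sample), 3)
  expect_true(all(out$one_sample$p_adjusted >= out$one_sample$p - 1e-15))
  expect_true(all(out$one_sample$p < 0.05))   # strong planted deviation from 1
  expect_equal(nrow(out$group_omnibus), 3)
  expect_equal(nrow(out$group_pairwise), 9)
})
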