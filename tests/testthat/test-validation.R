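test_that("relative expression is affine in delta-Ct with slope -log10(2)", {
  expect_equal(relative_expression(20, 20), 0)
  expect_equal(relative_expression(21, 20), -0.30103, tolerance = 1e-5)
  expect_equal(relative_expression(21, 20), -log10(2), tolerance = 1e-12)
  expect_equal(relative_expression(14, 24), 10 * log10(2), tolerance = 1e-12)
  dct <- seq(-12, 12, by = 0.5)
  expect_equal(relative_expression(20 + dct, 20), -dct * log10(2))
  expect_error(relative_expression(NA, 20), "non-finite")
})

test_that("summary-statistic t-test matches the raw-data t-test", {
  set.seed(21)
  x <- rnorm(23, 1, 0.6); y <- rnorm(31, 0.7, 0.5)
  s <- ttest_from_summary(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
  raw <- t.test(x, y, var.equal = TRUE)
  expect_equal(s$p, raw$p.value, tolerance = 1e-12)
  expect_equal(s$t, unname(raw$statistic), tolerance = 1e-12)
  sw <- ttest_from_summary(length(x), mean(x), sd(x), length(y), mean(y), sd(y),
                           welch = TRUE)
  expect_equal(sw$p, t.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("compare_groups reports crude and covariate-adjusted p-values", {
  set.seed(22)
  n <- 60
  grp <- rep(c("early", "non_early"), each = n / 2)
  age <- rnorm(n, 66, 10)
  stage <- sample(c("II", "III"), n, replace = TRUE)
  vals <- 1 + 0.4 * (grp == "non_early") + 0.01 * age + rnorm(n, 0, 0.4)
  out <- compare_groups(vals, grp,
                        covariates = data.frame(age = age, stage = stage))
  expect_lt(out$crude_p, 0.05)
  expect_equal(unname(out$group_ns), c(30, 30))
  # adjusted p equals the group term of the ANCOVA fit
  fit <- lm(vals ~ factor(grp) + age + factor(stage))
  expect_equal(out$adjusted_p, anova(fit)[1, "Pr(>F)"], tolerance = 1e-12)
  # constant covariates are dropped; adjusted then equals the crude ANOVA p
  expect_warning(
    out2 <- compare_groups(vals, grp, covariates = data.frame(c1 = rep(1, n))),
    "constant")
  expect_equal(out2$adjusted_p, anova(lm(vals ~ factor(grp)))[1, "Pr(>F)"],
               tolerance = 1e-12)
  # collinear covariate is dropped with a warning
  expect_warning(
    out3 <- compare_groups(vals, grp,
                           covariates = data.frame(age = age, age2 = 2 * age)),
    "collinear")
  expect_equal(out3$adjusted_p, anova(lm(vals ~ factor(grp) + age))[1, "Pr(>F)"],
               tolerance = 1e-12)
  expect_equal(out3$dropped_covariates, "age2")
  expect_error(compare_groups(rep(1, n), grp), "constant response")
})

test_that("identical groups give crude p = 1 and zero difference", {
  v <- c(1, 2, 3, 1, 2, 3)
  out <- compare_groups(v, rep(c("a", "b"), each = 3))
  expect_equal(out$crude_p, 1)
  expect_equal(unname(diff(out$group_means)), 0)
})

test_that("median dichotomization labels high strictly above the median", {
  d <- dichotomize_at_median(c(1, 2, 3, 4))
  expect_equal(d$median, 2.5)
  expect_equal(as.character(d$labels), c("low", "low", "high", "high"))
  # odd n: the median element itself is low
  d2 <- dichotomize_at_median(c(10, 30, 20))
  expect_equal(as.character(d2$labels), c("low", "high", "low"))
  expect_warning(d3 <- dichotomize_at_median(rep(5, 4)), "degenerate")
  expect_true(all(d3$labels == "low"))
  expect_error(dichotomize_at_median(3), "at least 2")
})

test_that("KM / log-rank reproduces the hand-tabulated 6-subject example", {
  # events at 1, 2, 3 in 'low'; censored 4, 5, 6 in 'high'
  # risk-set tabulation: O_low = 3, E_low = 0.5 + 0.4 + 0.25 = 1.15,
  # V = 0.25 + 0.24 + 0.1875 = 0.6775 -> chi2 = 1.85^2 / 0.6775
  out <- km_logrank(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0),
                    rep(c("low", "high"), each = 3), horizon_months = 12)
  expect_equal(out$logrank_chi2, 1.85^2 / 0.6775, tolerance = 1e-6)
  expect_equal(out$logrank_p, 0.02460235, tolerance = 1e-6)
  low <- out$curves[out$curves$group == "low", ]
  expect_equal(low$survival[low$time %in% c(1, 2, 3)], c(2 / 3, 1 / 3, 0))
  high <- out$curves[out$curves$group == "high", ]
  expect_true(all(high$survival == 1))
})

test_that("KM handles identical groups, the no-event case and the horizon", {
  t6 <- c(2, 5, 9, 2, 5, 9); e6 <- c(1, 0, 1, 1, 0, 1)
  g <- rep(c("high", "low"), each = 3)
  out <- km_logrank(t6, e6, g)
  expect_equal(out$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(out$logrank_p, 1)
  expect_warning(out2 <- km_logrank(t6, rep(0, 6), g), "no event")
  expect_equal(out2$logrank_p, 1)
  expect_true(all(out2$curves$survival == 1))
  # events beyond the horizon are censored at the horizon
  out3 <- km_logrank(c(2, 14, 20, 3, 15, 30), c(1, 1, 1, 1, 1, 1), g,
                     horizon_months = 12)
  expect_true(all(out3$curves$time <= 12))
  expect_equal(sum(out3$curves$n_event), 2)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    tm <- round(rexp(n, 0.1) + 0.1, 2)
    out <- km_logrank(tm, rep(1, n), rep(c("a", "b"), length.out = n),
                      horizon_months = Inf)
    for (g in c("a", "b")) {
      cv <- out$curves[out$curves$group == g, ]
      expect_equal(cv$survival, empirical_survival(tm[rep(c("a", "b"),
                    length.out = n) == g], cv$time), tolerance = 1e-12)
    }
  }
})

test_that("cohort CSV reader computes rel_expr and applies stage-I exclusion", {
  co <- generate_qpcr_cohort(n_early = 15, n_non_early = 12, seed = 4)
  f <- tempfile(fileext = ".csv")
  write.csv(co[, setdiff(names(co), "rel_expr")], f, row.names = FALSE)
  rd <- read_qpcr_cohort(f)
  expect_equal(rd$rel_expr, co$rel_expr, tolerance = 1e-9)
  rd2 <- read_qpcr_cohort(f, exclude_stage1 = TRUE)
  expect_true(all(rd2$stage != "I"))
  expect_lt(nrow(rd2), nrow(rd))
})

test_that("t-test power on the validation-cohort effect matches the noncentral-t formula", {
  # planted group difference 1.57 vs 1.25, common sd 0.5, n = 27/41
  n1 <- 27; n2 <- 41; delta <- 0.32; sdv <- 0.5
  ncp <- delta / (sdv * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tc <- qt(0.975, df)
  power_formula <- 1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  set.seed(24)
  rej <- replicate(600, {
    co <- generate_qpcr_cohort(n_early = n2, n_non_early = n1,
                               mean_early = 1.25, mean_non_early = 1.57,
                               sd = sdv, seed = sample.int(1e7, 1))
    compare_groups(co$rel_expr, co$group)$crude_p < 0.05
  })
  expect_lt(abs(mean(rej) - power_formula), 0.06)
})
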