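test_that("mixed ANOVA matches aov on balanced designs", {
  for (s in 1:5) {
    d <- fix_measures(n_f = 4, n_m = 4, means = c(0, 1, 0.5, 0.2), seed = s)
    a <- tidy(mixed_anova_2x2(d, "value"))
    ao <- summary(stats::aov(
      value ~ gender * condition + Error(subject_id / condition),
      data = transform(d, subject_id = factor(subject_id),
                       gender = factor(gender),
                       condition = factor(condition))))
    between <- ao[["Error: subject_id"]][[1]]
    within <- ao[["Error: subject_id:condition"]][[1]]
    expect_equal(a$statistic[a$term == "gender"], between["gender", "F value"],
                 tolerance = 1e-10)
    expect_equal(a$statistic[a$term == "condition"],
                 within["condition", "F value"], tolerance = 1e-10)
    expect_equal(a$statistic[a$term == "gender:condition"],
                 within["gender:condition", "F value"], tolerance = 1e-10)
    expect_equal(a$sumsq[a$term == "error: subjects"],
                 between["Residuals", "Sum Sq"], tolerance = 1e-10)
    expect_equal(a$sumsq[a$term == "error: within"],
                 within["Residuals", "Sum Sq"], tolerance = 1e-10)
  }
})

test_that("ANOVA sums of squares decompose additively (balanced)", {
  d <- fix_measures(n_f = 6, n_m = 6, means = c(2, 0, 1, 3), seed = 9)
  a <- tidy(mixed_anova_2x2(d, "value"))
  ss_total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(a$sumsq), ss_total, tolerance = 1e-8)
})

test_that("unequal groups give denominator df N - 2 and valid pes", {
  d <- fix_measures(n_f = 14, n_m = 15, seed = 2)
  a <- mixed_anova_2x2(d, "value")
  expect_equal(unique(tidy(a)$df_error[1:3]), 27)
  pes <- tidy(a)$pes[1:3]
  expect_true(all(pes >= 0 & pes <= 1))
  # pes is F/(F + df_error) in this design
  expect_equal(pes, tidy(a)$statistic[1:3] / (tidy(a)$statistic[1:3] + 27),
               tolerance = 1e-12)
})

test_that("ANOVA between effect equals squared pooled t on subject means", {
  d <- fix_measures(n_f = 5, n_m = 7, means = c(1, 1, 0, 0), seed = 3)
  a <- tidy(mixed_anova_2x2(d, "value"))
  subj <- tapply(d$value, d$subject_id, mean)
  g <- tapply(d$gender, d$subject_id, unique)[names(subj)]
  tt <- independent_t(subj[g == "female"], subj[g == "male"])
  expect_equal(a$statistic[a$term == "gender"], tt$t^2, tolerance = 1e-10)
})

test_that("degenerate and malformed designs are handled", {
  d <- fix_measures(seed = 4)
  d$value <- 5
  a <- mixed_anova_2x2(d, "value")
  expect_true(a$degenerate)
  expect_equal(tidy(a)$statistic[1:3], rep(0, 3))

  d2 <- fix_measures(seed = 5)[-1, ]
  expect_error(mixed_anova_2x2(d2, "value"), "Incomplete design")
  d3 <- fix_measures(n_f = 1, n_m = 4, seed = 6)
  expect_error(mixed_anova_2x2(d3, "value"), "at least 2")
})

test_that("paired t handles exact ties and recovers configured effects", {
  x <- c(1, 2, 3, 4)
  expect_equal(paired_t(x, x)$t, 0)
  expect_equal(paired_t(x, x)$p, 1)
  expect_error(paired_t(x, x + 2), "zero variance")

  # Monte-Carlo recovery of a configured standardized effect
  set.seed(8)
  d_hat <- replicate(1000, {
    delta <- rnorm(14, mean = 0.65, sd = 1)
    mean(delta) / sd(delta)
  })
  expect_equal(mean(d_hat), 0.65, tolerance = 3 * sd(d_hat) / sqrt(1000) + 0.05)
})

test_that("independent t agrees with the summary-statistics route exactly", {
  set.seed(9)
  x <- rnorm(14, 10, 2); y <- rnorm(15, 9, 2)
  ti <- independent_t(x, y)
  ts <- t_from_summary(mean(x), sd(x) / sqrt(14), 14,
                       mean(y), sd(y) / sqrt(15), 15)
  expect_equal(ti$t, ts$t, tolerance = 1e-10)
  expect_equal(ti$d, abs(ts$d) * sign(ti$d), tolerance = 1e-10)
  expect_equal(ti$df, 27)
  expect_equal(independent_t(x, x)$t, 0)

  # textbook-formula oracle
  sp <- sqrt((13 * var(x) + 14 * var(y)) / 27)
  expect_equal(ti$t, (mean(x) - mean(y)) / (sp * sqrt(1 / 14 + 1 / 15)),
               tolerance = 1e-10)
})

test_that("summary-statistics t reproduces the reference group contrasts", {
  r1 <- t_from_summary(173.55, 9.06, 14, 142.58, 6.76, 15)
  expect_equal(round(r1$t, 2), 2.76)
  expect_equal(r1$df, 27)
  expect_equal(round(r1$p, 2), 0.01)
  expect_lte(abs(r1$d - 1.02), 0.02)

  r2 <- t_from_summary(150.11, 8.32, 14, 158.08, 7.49, 15)
  expect_equal(round(r2$t, 2), -0.71)
  expect_equal(round(r2$p, 2), 0.48)

  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12)$d, 0)
  expect_error(t_from_summary(5, 0, 10, 6, 0, 12), "zero")
})

test_that("eta squared partial is monotone in the effect sum of squares", {
  base <- fix_measures(n_f = 5, n_m = 5, means = c(0, 0, 0, 0), seed = 10)
  pes_at <- function(shift) {
    d <- base
    d$value <- d$value + shift *
      (d$gender == "female") * (d$condition == "simple")
    tidy(mixed_anova_2x2(d, "value"))$pes[3]
  }
  pes <- vapply(c(0.5, 1, 2, 4), pes_at, numeric(1))
  expect_true(all(diff(pes) > 0))
})
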