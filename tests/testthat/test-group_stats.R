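test_that("Welch t from summaries reproduces published demographic comparisons", {
  # age comparison of 208 vs 227 subjects
  expect_equal(welch_t(16.35, 6.72, 208, 15.86, 5.16, 227)$value, 0.847,
               tolerance = 5e-4)
  # symptom-score comparison (206 vs 225 with scores available)
  expect_equal(welch_t(8.48, 5.90, 206, 0.08, 0.44, 225)$value, 20.385,
               tolerance = 0.05 / 20.385)
  # matched-subset age comparison
  expect_equal(welch_t(16.35, 6.72, 208, 16.25, 5.31, 115)$value, 0.147,
               tolerance = 5e-3)
  # identical summaries give t = 0
  expect_equal(welch_t(5, 1, 10, 5, 1, 10)$value, 0)
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "degenerate")
})

test_that("Welch t agrees with stats::t.test on raw data and is antisymmetric", {
  set.seed(8)
  x <- rnorm(14, 1, 2); y <- rnorm(19, 0.2, 1.3)
  ours <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  ref <- t.test(x, y)
  expect_equal(ours$value, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p_raw, ref$p.value, tolerance = 1e-10)

  flipped <- welch_t(mean(y), sd(y), length(y), mean(x), sd(x), length(x))
  expect_equal(flipped$value, -ours$value, tolerance = 1e-12)
  expect_equal(flipped$p_raw, ours$p_raw, tolerance = 1e-12)
})

test_that("chi-square reproduces published sex-ratio statistics without correction", {
  expect_lt(abs(chisq_2x2(matrix(c(179, 171, 29, 56), 2))$value - 7.945),
            5e-4)
  expect_lt(abs(chisq_2x2(matrix(c(179, 98, 29, 17), 2))$value - 0.043),
            5e-4)
  expect_equal(chisq_2x2(matrix(c(10, 10, 10, 10), 2))$value, 0)

  # invariant to transposition
  tab <- matrix(c(17, 5, 9, 21), 2)
  expect_equal(chisq_2x2(t(tab))$value, chisq_2x2(tab)$value)
  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("ANCOVA group F reduces to the pooled t^2 without covariates", {
  cohort <- toy_cohort(n_per_group = 10)
  set.seed(9)
  resp <- rnorm(nrow(cohort)) + 0.8 * (cohort$group == "ASD")
  res <- ancova_group_f(resp, cohort, covariates = character(0))
  ref <- t.test(resp ~ cohort$group, var.equal = TRUE)
  expect_equal(res$value, unname(ref$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-10)
})

test_that("ANCOVA agrees with lm/anova on the full covariate model", {
  cohort <- toy_cohort(n_per_group = 12, sites = c("S1", "S2"))
  set.seed(10)
  resp <- rnorm(nrow(cohort), sd = 0.5) + 0.02 * cohort$age +
    2 * cohort$mean_fd + 0.3 * (cohort$group == "ASD")
  res <- ancova_group_f(resp, cohort)
  df <- data.frame(resp = resp, group = factor(cohort$group),
                   age = cohort$age, sex = as.numeric(cohort$sex == "female"),
                   fd = cohort$mean_fd, site = factor(cohort$site))
  fit <- lm(resp ~ group + age + sex + fd + site, data = df)
  tg <- coef(summary(fit))["groupTD", "t value"]
  expect_equal(res$value, tg^2, tolerance = 1e-10)
  expect_equal(res$p_raw, coef(summary(fit))["groupTD", "Pr(>|t|)"],
               tolerance = 1e-10)
  # estimate is reported as ASD minus TD
  expect_equal(res$estimate, -unname(coef(fit)["groupTD"]), tolerance = 1e-10)
})

test_that("degenerate ANCOVA designs error instead of silently dropping columns", {
  cohort <- toy_cohort(n_per_group = 8)
  resp <- rnorm(nrow(cohort))
  cohort$age <- 10                       # constant covariate
  expect_error(ancova_group_f(resp, cohort), "constant covariate")

  # site perfectly confounded with group
  cohort2 <- toy_cohort(n_per_group = 8, sites = c("S1", "S2"))
  cohort2$site <- ifelse(cohort2$group == "ASD", "S1", "S2")
  expect_error(ancova_group_f(rnorm(nrow(cohort2)), cohort2),
               "collinear|constant")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8), tolerance = 1e-12)
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))^2
    adj <- bh_fdr(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    # monotone when input sorted ascending
    expect_true(all(diff(bh_fdr(sort(p))) >= -1e-15))
  }
})

test_that("partial correlation residualizes covariates correctly", {
  set.seed(14)
  n <- 60
  z <- rnorm(n)
  # empty covariate set: plain Pearson r
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  res <- partial_pearson(x, y)
  expect_equal(res$value, cor(x, y), tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-10)

  # shared residual signal with covariate-explained components
  u <- rnorm(n)
  x2 <- u + 3 * z
  y2 <- u - 2 * z
  res2 <- partial_pearson(x2, y2, cbind(z))
  expect_gt(res2$value, 0.99)

  expect_error(partial_pearson(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "insufficient df")
})

test_that("null partial correlations are centred at zero", {
  set.seed(15)
  n <- 400
  rs <- replicate(200, {
    z <- rnorm(n)
    x <- 0.6 * z + rnorm(n)
    y <- -0.4 * z + rnorm(n)
    partial_pearson(x, y, cbind(z))$value
  })
  se <- 1 / sqrt(n - 3)
  expect_lt(abs(mean(rs)), 3 * se / sqrt(200))
})

test_that("matched-subset rule drops only high-motion TD rows by sex", {
  df <- data.frame(
    subject_id = paste0("s", 1:6),
    group = c("TD", "TD", "TD", "TD", "ASD", "ASD"),
    sex = c("male", "male", "female", "female", "male", "female"),
    age = 15, mean_fd = c(0.051, 0.05, 0.06, 0.061, 0.30, 0.30),
    site = "S1", stringsAsFactors = FALSE)
  cohort <- as_cohort(df)
  res <- subset_match(cohort)
  # strict thresholds: TD male 0.051 out, 0.05 in; TD female 0.06 in, 0.061 out
  expect_setequal(res$exclusions$subject_id, c("s1", "s4"))
  # ASD rows untouched regardless of motion
  expect_true(all(c("s5", "s6") %in% res$cohort$subject_id))
})

test_that("ANCOVA type-I error is nominal under the null", {
  cohort <- toy_cohort(n_per_group = 40, sites = c("S1", "S2"), seed = 77)
  set.seed(78)
  p <- replicate(400, {
    resp <- 0.03 * cohort$age + 3 * cohort$mean_fd + rnorm(nrow(cohort))
    ancova_group_f(resp, cohort)$p_raw
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
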