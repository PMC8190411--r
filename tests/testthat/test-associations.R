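test_that("partial correlation reduces to Pearson without a real control", {
  set.seed(6)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  control <- rnorm(50)
  # make a and b exactly uncorrelated with the control in-sample
  a0 <- residuals(lm(a ~ control))
  b0 <- residuals(lm(b ~ control))
  pc <- partial_correlation(a0, b0, control)
  expect_equal(pc$estimate, cor(a0, b0), tolerance = 1e-10)
  # constant control degenerates gracefully to plain Pearson
  pc2 <- partial_correlation(a, b, rep(3, 50))
  expect_equal(pc2$estimate, cor(a, b), tolerance = 1e-12)
  expect_error(partial_correlation(a, control, control), "zero-variance")
})

test_that("partial correlation matches a hand residualization", {
  a <- c(2, 4, 5, 8, 9)
  b <- c(1, 3, 2, 6, 9)
  ctrl <- c(10, 12, 15, 16, 20)
  ra <- residuals(lm(a ~ ctrl))
  rb <- residuals(lm(b ~ ctrl))
  r_hand <- cor(ra, rb)
  pc <- partial_correlation(a, b, ctrl)
  expect_equal(pc$estimate, r_hand, tolerance = 1e-6)
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(pc$p_value, 2 * pt(-abs(t_hand), 2), tolerance = 1e-10)
})

test_that("the quintile trend test recovers flat and linear patterns", {
  q <- rep(1:5, each = 4)
  # same outcome distribution in every quintile: zero slope, p = 1
  flat <- rep(c(1, 2, 3, 4), times = 5)
  tr <- quintile_trend_test(flat, q)
  expect_equal(tr$estimate, 0, tolerance = 1e-12)
  expect_equal(tr$p_value, 1, tolerance = 1e-8)
  # exact linear outcome
  lin <- quintile_trend_test(2 * q, q)
  expect_equal(lin$estimate, 2, tolerance = 1e-10)
  expect_lt(lin$p_value, 1e-12)
  expect_error(quintile_trend_test(rnorm(5), rep(2, 5)), "two populated")
})

test_that("the trend slope matches hand OLS on a 10-point instance", {
  q <- rep(1:5, each = 2)
  y <- c(3.1, 2.9, 3.6, 3.4, 4.2, 3.8, 4.9, 4.7, 5.6, 5.2)
  slope_hand <- sum((q - mean(q)) * (y - mean(y))) / sum((q - mean(q))^2)
  tr <- quintile_trend_test(y, q)
  expect_equal(tr$estimate, slope_hand, tolerance = 1e-6)
  # energy adjustment changes the fitted model, recorded in covariates
  tre <- quintile_trend_test(y, q, adjust_energy = TRUE,
                             energy = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9) * 100)
  expect_equal(tre$covariates, "energy")
})

test_that("trend slope rescales under affine relabelling of quintiles", {
  set.seed(14)
  q <- rep(1:5, each = 10)
  y <- 0.7 * q + rnorm(50)
  base <- quintile_trend_test(y, q)$estimate
  shifted <- quintile_trend_test(y, 2 * q + 3)$estimate
  # labels 2q+3 halve the slope per label unit
  expect_equal(2 * shifted, base, tolerance = 1e-10)
})

test_that("chi-square test matches hand computation and degenerates loudly", {
  cat2 <- rep(c("a", "b"), each = 10)
  q2 <- rep(c(1, 2), each = 10)
  res <- categorical_quintile_test(cat2, q2)
  expect_equal(res$estimate, 20, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_error(categorical_quintile_test(rep("a", 20), rep(1:5, 4)),
               "two category")
  expect_error(categorical_quintile_test(cat2, rep(1, 20)), "two populated")
})

test_that("chi-square p-values are uniform under independence", {
  set.seed(99)
  n_sims <- 200
  p <- replicate(n_sims, {
    cat <- sample(c("x", "y"), 150, replace = TRUE)
    q <- rep(1:5, each = 30)
    categorical_quintile_test(cat, q)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("low expected counts are flagged, not dropped", {
  cat <- c(rep("a", 48), rep("b", 2))
  q <- rep(1:5, 10)
  res <- categorical_quintile_test(cat, q)
  expect_true(res$low_expected)
  expect_equal(res$n_used, 50)
})

test_that("outcome regressions recover a planted negative slope", {
  hits <- 0
  for (seed in 1:10) {
    co <- generate_cohort(cohort_spec(n_participants = 400, seed = seed,
                                      misreport_fraction = 0))
    tab <- co$participants
    r <- outcome_regression(tab$la_dgla_ratio, co$truth$true_pattern2_score,
                            model = "model1")
    if (r$estimate < 0 && r$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("model 2 adjusts for the nine confounders and validates input", {
  co <- generate_cohort(cohort_spec(n_participants = 400, seed = 3))
  tab <- co$participants
  tab$bmi <- compute_bmi(tab$weight_kg, tab$height_cm / 100)
  covs <- tab[, c("age", "energy_kcal", "pir", "race", "vigorous_work",
                  "vigorous_rec", "bmi", "education", "lipid_lowering",
                  "supplement_use")]
  r2 <- outcome_regression(tab$la_dgla_ratio, co$truth$true_pattern2_score,
                           covs, model = "model2")
  expect_true(all(c("age", "race", "bmi", "education") %in% r2$covariates))
  expect_true(all(r2$reference_levels %in% c(levels(factor(tab$race)),
                                             levels(factor(tab$education)))))
  expect_lte(r2$adj_r2, summary(r2$fit)$r.squared)
  expect_error(outcome_regression(tab$la_dgla_ratio,
                                  co$truth$true_pattern2_score,
                                  covs[, 1:3], model = "model2"),
               "requires covariates")
  # collinear design is reported, not silently dropped
  covs_bad <- covs
  covs_bad$bmi <- covs_bad$age
  expect_error(outcome_regression(tab$la_dgla_ratio, covs_bad$age, covs_bad,
                                  model = "model2"), "collinear")
})

test_that("a null effect gives null-calibrated regression coefficients", {
  covered <- 0
  n_rep <- 40
  for (seed in seq_len(n_rep)) {
    co <- generate_cohort(cohort_spec(n_participants = 250, seed = 500 + seed,
                                      beta_ratio = 0, misreport_fraction = 0))
    r <- outcome_regression(co$participants$la_dgla_ratio,
                            co$truth$true_pattern2_score, model = "model1")
    ci <- r$estimate + c(-1, 1) * qt(0.975, r$n_used - 2) * r$se
    if (ci[1] <= 0 && 0 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.85)
})
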