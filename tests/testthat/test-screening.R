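test_that("BMI follows weight over squared height", {
  expect_equal(compute_bmi(80, 1.80), 24.69, tolerance = 5e-3)
  expect_equal(compute_bmi(60, 1.65), 22.04, tolerance = 5e-3)
  h <- c(17, 23.5, 31)
  expect_equal(compute_bmi(h, 1.0), h)
  expect_error(compute_bmi(-70, 1.7), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("predicted TEE matches the prediction equation", {
  expect_equal(predict_tee(40, 80, 180, 0), 13.335, tolerance = 1e-6)
  expect_equal(predict_tee(30, 60, 165, 1), 10.888, tolerance = 5e-4)
  expect_equal(predict_tee(52, 71, 168, 0) - predict_tee(52, 71, 168, 1),
               1.363, tolerance = 1e-12)
  expect_error(predict_tee(40, 80, 180, 2), "sex")
})

test_that("the misreporting cutoff propagates the CV constants", {
  expect_equal(round(misreport_cutoff_sd(screening_config()), 4), 0.3157)
  expect_equal(misreport_cutoff_sd(screening_config(0, 0, 0)), 0)
  # many recall days: the energy-intake CV term washes out
  expect_equal(round(misreport_cutoff_sd(screening_config(d_days = 1e9)), 4),
               0.2180)
})

test_that("reporter classification brackets the plausible band", {
  cfg <- screening_config()
  cut <- misreport_cutoff_sd(cfg)
  pTEE <- 10
  ei_for <- function(ratio) ratio * pTEE / cfg$kcal_to_MJ
  expect_equal(classify_reporter(ei_for(1.0), pTEE, cut, cfg), "plausible")
  expect_equal(classify_reporter(ei_for(0.50), pTEE, cut, cfg), "under")
  expect_equal(classify_reporter(ei_for(1.40), pTEE, cut, cfg), "over")
  # boundary values are inside the closed interval
  expect_equal(classify_reporter(ei_for(1 - cut), pTEE, cut, cfg), "plausible")
  expect_equal(classify_reporter(ei_for(1 + cut), pTEE, cut, cfg), "plausible")
  expect_error(classify_reporter(2000, -1, cut, cfg), "pTEE")
})

test_that("classification is monotone in energy intake", {
  cfg <- screening_config()
  cut <- misreport_cutoff_sd(cfg)
  cls <- classify_reporter(seq(200, 8000, by = 100), 10, cut, cfg)
  ord <- match(cls, c("under", "plausible", "over"))
  expect_true(all(diff(ord) >= 0))
})

test_that("inclusion filters remove rows in the stated order", {
  tab <- toy_participants(5)
  tab$age[1] <- 18
  tab$pregnant[2] <- 1
  tab$serum_la[3] <- NA
  res <- apply_inclusion_filters(tab)
  log <- res$filter_log
  expect_equal(log$n[log$step == "age"], 1)
  expect_equal(log$n[log$step == "pregnant"], 1)
  expect_equal(log$n[log$step == "missing"], 1)
  expect_equal(log$n[log$step == "under_report"] +
                 log$n[log$step == "over_report"], 0)
  expect_equal(log$n[log$step == "final"], 2)
  expect_setequal(res$participants$id, c(4, 5))
})

test_that("a saturating filter removes everyone at its own step", {
  tab <- toy_participants(6)
  tab$age <- 19
  expect_warning(res <- apply_inclusion_filters(tab), "no participants")
  expect_equal(res$filter_log$n[res$filter_log$step == "age"], 6)
  expect_equal(res$filter_log$n[res$filter_log$step == "final"], 0)
})

test_that("filter-log step counts sum to input minus output", {
  co <- generate_cohort(cohort_spec(n_participants = 600, seed = 31))
  res <- apply_inclusion_filters(co$participants)
  log <- res$filter_log
  removed <- sum(log$n[log$step %in% c("age", "pregnant", "missing",
                                       "under_report", "over_report")])
  expect_equal(log$n[log$step == "input"] - removed,
               log$n[log$step == "final"])
  expect_equal(log$n[log$step == "final"], nrow(res$participants))
})

test_that("planted misreporters are screened out at the planted rate", {
  n <- 2000
  co <- generate_cohort(cohort_spec(
    n_participants = n, seed = 41, misreport_fraction = 0.15,
    within_person_cv = 0, between_person_cv = 0, nutrient_noise_cv = 0))
  res <- apply_inclusion_filters(co$participants)
  log <- res$filter_log
  removed_d <- sum(log$n[log$step %in% c("under_report", "over_report")])
  # planted misreporters still in play at step (d): earlier steps (e.g.
  # pregnancy) can remove a few first
  planted <- sum(co$truth$misreporter_flags != "none" &
                   co$participants$pregnant != 1)
  # at zero intake noise every remaining planted misreporter and no honest
  # reporter leaves at step (d)
  expect_equal(removed_d, planted)
})

test_that("low serum Zn is flagged, never excluded", {
  tab <- toy_participants(4)
  tab$serum_zn <- c(60, 80, 74, 90)
  res <- apply_inclusion_filters(tab)
  expect_equal(res$filter_log$n[res$filter_log$step == "final"], 4)
  expect_equal(res$filter_log$n[res$filter_log$step == "serum_zn_low_flagged"], 2)
})
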