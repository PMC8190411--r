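test_that("z-standardization centres, scales, and drops constants", {
  z <- standardize_columns(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(z$z), c(-1, 0, 1))
  # idempotence
  z2 <- standardize_columns(z$z)
  expect_equal(z2$z, z$z, tolerance = 1e-10)
  expect_warning(
    zc <- standardize_columns(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
    "constant")
  expect_equal(colnames(zc$z), "a")
  expect_equal(zc$params$dropped, "b")
  expect_error(standardize_columns(cbind(a = c(2, 2))), "constant")
})

test_that("a response inside the predictor span is fully explained", {
  set.seed(2)
  X <- standardize_columns(matrix(rnorm(400), 100, 4))$z
  colnames(X) <- paste0("X", 1:4)
  Y <- cbind(zn = X[, 1])
  fit <- fit_rrr(X, Y, K = 1)
  expect_equal(unname(fit$explained[1, "zn"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$loadings["X1", 1]), 1, tolerance = 1e-8)
})

test_that("orthonormal rotations of the predictors are fully recovered", {
  n <- 64
  # two exactly orthonormal standardized columns from a design construction
  x1 <- rep(c(1, -1), each = n / 2)
  x2 <- rep(c(1, -1), times = n / 2)
  X <- cbind(a = x1, b = x2)
  Y <- cbind(zn = (x1 + x2) / sqrt(2), pufa = (x1 - x2) / sqrt(2))
  fit <- fit_rrr(standardize_columns(X)$z, standardize_columns(Y)$z, K = 2)
  expect_equal(unname(fit$explained[2, "cumulative_overall"]), 1,
               tolerance = 1e-10)
})

test_that("the eigen solution attains the grid-search maximum", {
  inst <- random_rrr_instance(101)
  fit <- fit_rrr(inst$X, inst$Y, K = 2)
  grid_max <- rrr_grid_max(inst$X, inst$Y)
  expect_equal(unname(fit$explained[1, "overall"]), grid_max,
               tolerance = 1e-3)
})

test_that("factor scores are orthogonal, eigenvalues sorted, signs anchored", {
  for (seed in c(11, 12, 13)) {
    inst <- random_rrr_instance(seed)
    fit <- fit_rrr(inst$X, inst$Y, K = 2)
    Fm <- fit$factor_scores
    expect_lt(abs(crossprod(Fm[, 1], Fm[, 2])), 1e-8 * nrow(Fm))
    expect_true(all(diff(fit$eigenvalues) <= 1e-8))
    expect_true(all(fit$eigenvalues >= 0))
    for (k in 1:2) {
      expect_gte(cor(Fm[, k], inst$Y[, "zn"]), 0)
      expect_equal(sum(fit$response_weights[, k]^2), 1, tolerance = 1e-10)
    }
    expect_true(all(abs(fit$loadings) <= 1 + 1e-10))
    ev <- fit$explained[, "cumulative_overall"]
    expect_true(all(diff(ev) >= -1e-12) && all(ev >= 0) && all(ev <= 1 + 1e-10))
  }
})

test_that("the factor score is the projection of the response score", {
  inst <- random_rrr_instance(77)
  fit <- fit_rrr(inst$X, inst$Y, K = 2)
  for (k in 1:2) {
    proj <- fitted(lm(fit$response_scores[, k] ~ inst$X))
    expect_equal(unname(fit$factor_scores[, k]), unname(proj),
                 tolerance = 1e-8)
    # corr(t, f)^2 = share of response-score variance explained by predictors
    r2 <- summary(lm(fit$response_scores[, k] ~ inst$X))$r.squared
    expect_equal(cor(fit$response_scores[, k], fit$factor_scores[, k])^2, r2,
                 tolerance = 1e-8)
  }
})

test_that("loadings agree with direct correlations and flip with the factor", {
  inst <- random_rrr_instance(55)
  fit <- fit_rrr(inst$X, inst$Y, K = 2)
  direct <- cor(inst$X, fit$factor_scores)
  expect_equal(unname(fit$loadings), unname(direct), tolerance = 1e-12)
  flipped <- fit
  flipped$factor_scores[, 1] <- -flipped$factor_scores[, 1]
  expect_equal(factor_loadings(flipped, inst$X)[, 1], -fit$loadings[, 1],
               tolerance = 1e-12)
  # regression-type loadings exist and differ in scale, not direction
  lr <- factor_loadings(fit, inst$X, type = "regression")
  expect_true(all(sign(lr[abs(lr) > 1e-8]) ==
                    sign(fit$loadings[abs(lr) > 1e-8])))
})

test_that("responses independent of the predictors explain almost nothing", {
  set.seed(33)
  n <- 2000
  X <- standardize_columns(matrix(rnorm(n * 4), n, 4))$z
  Y <- standardize_columns(cbind(zn = rnorm(n), pufa = rnorm(n)))$z
  fit <- fit_rrr(X, Y, K = 2)
  expect_lt(max(fit$explained[, c("zn", "pufa")]), 0.05)
})

test_that("explained variation matches a hand correlation computation", {
  inst <- random_rrr_instance(91, m = 1)
  fit <- fit_rrr(inst$X, inst$Y, K = 1)
  expect_equal(unname(fit$explained[1, 1]),
               cor(inst$Y[, 1], fit$factor_scores[, 1])^2, tolerance = 1e-12)
})

test_that("pattern simplification applies the signed threshold rule", {
  # fit object with known loadings: only the threshold logic is under test
  X <- standardize_columns(matrix(rnorm(200), 50, 4,
                                  dimnames = list(NULL, paste0("G", 1:4))))$z
  model <- structure(list(
    loadings = matrix(c(0.25, -0.30, 0.19, 0.05), 4, 1,
                      dimnames = list(paste0("G", 1:4), "factor1")),
    K = 1L, X = X), class = "rrr_fit")
  pat <- simplify_pattern(model, 1)
  expect_equal(pat$contributing_groups$group_id, c("G1", "G2"))
  expect_equal(pat$contributing_groups$sign, c(1, -1))
  expect_equal(pat$score, unname(X[, "G1"] - X[, "G2"]), tolerance = 1e-12)
  # a loading exactly at the threshold is included
  model$loadings[3, 1] <- 0.20
  expect_true("G3" %in% simplify_pattern(model, 1)$contributing_groups$group_id)
  model$loadings[, 1] <- c(0.1, -0.15, 0.19, 0.05)
  expect_error(simplify_pattern(model, 1), "empty simplified pattern")
})

test_that("quintile assignment balances group sizes and is stable", {
  expect_equal(assign_quintiles(1:10), rep(1:5, each = 2))
  q11 <- assign_quintiles(rnorm(11))
  expect_true(max(table(q11)) - min(table(q11)) <= 1)
  # ties broken by stable input order
  qt <- assign_quintiles(rep(1, 10))
  expect_equal(qt, rep(1:5, each = 2))
  expect_true(all(diff(qt) >= 0))
  expect_error(assign_quintiles(1:4), "at least 5")
})

test_that("model serialization writes labelled delimited text", {
  inst <- random_rrr_instance(3)
  fit <- fit_rrr(inst$X, inst$Y, K = 2)
  dir <- withr::local_tempdir()
  write_rrr_model(fit, dir)
  lo <- read.csv(file.path(dir, "loadings.csv"), row.names = 1)
  expect_equal(as.matrix(lo), fit$loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "explained_variation.csv")))
})
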