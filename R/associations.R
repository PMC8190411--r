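association_result <- function(estimate, se = NA_real_, p_value = NA_real_,
                               adj_r2 = NA_real_, model_label, n_used,
                               covariates = character(0), ...) {
  structure(list(estimate = estimate, se = se, p_value = p_value,
                 adj_r2 = adj_r2, model_label = model_label, n_used = n_used,
                 covariates = covariates, ...),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g (SE %.3g), p = %.3g, n = %d\n",
              x$model_label, x$estimate, x$se, x$p_value, x$n_used))
  if (!is.na(x$adj_r2)) cat(sprintf("  adjusted R-squared %.4f\n", x$adj_r2))
  if (length(x$covariates) > 0)
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Partial correlation adjusted for one control variable
#'
#' Residualizes both variables on the control (OLS with intercept) and
#' correlates the residuals; the p-value uses the t-distribution with n - 3
#' degrees of freedom. A constant control degenerates gracefully to the
#' plain Pearson correlation (with the same df).
#'
#' @param a,b Numeric n-vectors, n >= 4.
#' @param control Numeric n-vector (typically energy intake).
#' @return An `association_result` with `model_label = "partial_corr"`.
#' @export
partial_correlation <- function(a, b, control) {
  n <- length(a)
  if (n < 4 || length(b) != n || length(control) != n)
    stop("need equal-length vectors with n >= 4")
  resid_on <- function(y) {
    if (stats::var(control) <= 0) return(y - mean(y))
    stats::lm.fit(cbind(1, control), y)$residuals
  }
  ra <- resid_on(a); rb <- resid_on(b)
  if (stats::sd(ra) <= 1e-10 * max(stats::sd(a), 1) ||
      stats::sd(rb) <= 1e-10 * max(stats::sd(b), 1))
    stop("zero-variance residual: a or b is collinear with the control")
  r <- stats::cor(ra, rb)
  df <- n - 3
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  association_result(estimate = r, se = sqrt((1 - r^2) / df), p_value = p,
                     model_label = "partial_corr", n_used = n,
                     covariates = "control", df = df)
}

#' Linear trend test across quintiles
#'
#' Regresses the outcome on the ordinal quintile index 1..5 (optionally also
#' on energy intake, as done for food-group and nutrient rows but not for
#' serum rows) and reports the index coefficient. An alternative trend
#' variable — the median score within each quintile — is available via
#' `trend_variable`.
#'
#' @param outcome Numeric n-vector.
#' @param quintile Integer labels 1..5.
#' @param adjust_energy Add energy as a covariate?
#' @param energy Energy intakes (kcal/day), required when `adjust_energy`.
#' @param trend_variable `"index"` (default) or `"median_score"`; the latter
#'   needs `score`.
#' @param score Person-level scores (for `trend_variable = "median_score"`).
#' @return An `association_result` with `model_label = "trend"`.
#' @export
quintile_trend_test <- function(outcome, quintile, adjust_energy = FALSE,
                                energy = NULL,
                                trend_variable = c("index", "median_score"),
                                score = NULL) {
  trend_variable <- match.arg(trend_variable)
  q <- as.integer(quintile)
  if (length(unique(q[!is.na(q)])) < 2)
    stop("need at least two populated quintiles")
  x <- if (trend_variable == "index") as.numeric(q) else {
    if (is.null(score)) stop("'score' required for median_score trend")
    stats::ave(score, q, FUN = stats::median)
  }
  dat <- data.frame(y = outcome, x = x)
  fm <- y ~ x
  if (adjust_energy) {
    if (is.null(energy)) stop("'energy' required when adjust_energy = TRUE")
    dat$energy <- energy
    fm <- y ~ x + energy
  }
  fit <- stats::lm(fm, data = dat)
  cf <- summary(fit)$coefficients
  association_result(estimate = cf["x", 1], se = cf["x", 2],
                     p_value = cf["x", 4],
                     adj_r2 = summary(fit)$adj.r.squared,
                     model_label = "trend", n_used = stats::nobs(fit),
                     covariates = if (adjust_energy) "energy" else character(0))
}

#' Chi-square test of a categorical variable across quintiles
#'
#' Pearson chi-square (no continuity correction) on the category-by-quintile
#' contingency table. Cells with expected counts below 5 are flagged in the
#' result, not dropped.
#'
#' @param category Categorical n-vector.
#' @param quintile Integer labels 1..5.
#' @return An `association_result` with `model_label = "chi_square"`, plus
#'   `df`, `expected` and `low_expected` (logical) fields.
#' @export
categorical_quintile_test <- function(category, quintile) {
  if (length(unique(stats::na.omit(category))) < 2)
    stop("need at least two category levels")
  if (length(unique(stats::na.omit(quintile))) < 2)
    stop("need at least two populated quintiles")
  tab <- table(category, quintile)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  association_result(estimate = unname(ct$statistic),
                     p_value = ct$p.value,
                     model_label = "chi_square", n_used = sum(tab),
                     df = unname(ct$parameter), expected = ct$expected,
                     low_expected = any(ct$expected < 5))
}

# reference level = largest category, recorded for reproducibility
relevel_largest <- function(x) {
  f <- factor(x)
  stats::relevel(f, ref = names(which.max(table(f))))
}

#' Model-1 / model-2 outcome regression
#'
#' Ordinary least squares of a serum outcome on the simplified pattern
#' score: model 1 is unadjusted; model 2 adds age, energy intake, PIR,
#' race, physical activity (two binary indicators), BMI, education level,
#' lipid-lowering medication use and dietary supplement use. Categorical
#' covariates are expanded to indicator contrasts against the largest
#' category in the analysed stratum. Complete cases only.
#'
#' @param outcome Numeric n-vector (serum DGLA or LA/DGLA ratio).
#' @param score Simplified pattern score.
#' @param covariates Data frame with columns `age`, `energy_kcal`, `pir`,
#'   `race`, `vigorous_work`, `vigorous_rec`, `bmi`, `education`,
#'   `lipid_lowering`, `supplement_use` (required for model 2).
#' @param model `"model1"` or `"model2"`.
#' @return An `association_result` carrying the score coefficient, its SE
#'   and p-value, and the adjusted R-squared of the whole model; reference
#'   levels used for the factors are recorded in `reference_levels`.
#' @export
outcome_regression <- function(outcome, score, covariates = NULL,
                               model = c("model1", "model2")) {
  model <- match.arg(model)
  dat <- data.frame(y = outcome, score = score)
  refs <- character(0)
  if (model == "model2") {
    need <- c("age", "energy_kcal", "pir", "race", "vigorous_work",
              "vigorous_rec", "bmi", "education", "lipid_lowering",
              "supplement_use")
    if (is.null(covariates) || !all(need %in% names(covariates)))
      stop("model 2 requires covariates: ", paste(need, collapse = ", "))
    dat <- cbind(dat, covariates[need])
    dat$race <- relevel_largest(dat$race)
    dat$education <- relevel_largest(dat$education)
    refs <- c(race = levels(dat$race)[1], education = levels(dat$education)[1])
    fm <- y ~ score + age + energy_kcal + pir + race + vigorous_work +
      vigorous_rec + bmi + education + lipid_lowering + supplement_use
  } else {
    fm <- y ~ score
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- stats::lm(fm, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("collinear design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  if (nrow(dat) < length(stats::coef(fit)) + 2)
    stop("too few complete cases for the requested model")
  cf <- summary(fit)$coefficients
  association_result(estimate = cf["score", 1], se = cf["score", 2],
                     p_value = cf["score", 4],
                     adj_r2 = summary(fit)$adj.r.squared,
                     model_label = model, n_used = nrow(dat),
                     covariates = setdiff(all.vars(fm), c("y", "score")),
                     reference_levels = refs, fit = fit)
}
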