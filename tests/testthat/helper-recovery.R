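# reduced end-to-end recovery run: generate -> screen -> usual intake ->
# energy-adjust -> RRR -> simplified pattern for the factor best matching the
# planted signs -> outcome regressions
recover_planted_pattern <- function(seed, n = 800, sex = "female",
                                    spec_args = list(), with_model2 = TRUE) {
  spec <- do.call(cohort_spec, c(list(n_participants = n, sex = sex,
                                      seed = seed), spec_args))
  co <- generate_cohort(spec)
  filt <- apply_inclusion_filters(co$participants)
  tab <- filt$participants
  usual <- estimate_usual_intake(cohort_day_matrix(tab, 1),
                                 cohort_day_matrix(tab, 2))
  Xs <- standardize_columns(usual)
  Ys <- standardize_columns(cbind(
    zn = energy_adjust(tab$zn_mg, tab$energy_kcal),
    pufa = energy_adjust(tab$pufa_g, tab$energy_kcal)))
  fit <- fit_rrr(Xs$z, Ys$z, K = 2, sign_ref = "zn")
  planted <- co$truth$planted_signs
  match_frac <- apply(fit$loadings[names(planted), , drop = FALSE], 2,
                      function(l) mean(sign(l) == planted))
  k <- which.max(match_frac)
  pat <- simplify_pattern(fit, k)
  m1 <- outcome_regression(tab$la_dgla_ratio, pat$score, model = "model1")
  m2 <- NULL
  if (with_model2) {
    covs <- tab[, c("age", "energy_kcal", "pir", "race", "vigorous_work",
                    "vigorous_rec", "bmi", "education", "lipid_lowering",
                    "supplement_use")]
    m2 <- outcome_regression(tab$la_dgla_ratio, pat$score, covs,
                             model = "model2")
  }
  list(sign_frac = max(match_frac), factor = k,
       simpl_corr = cor(pat$score, fit$factor_scores[, k]),
       m1 = m1, m2 = m2, n_used = nrow(tab))
}
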