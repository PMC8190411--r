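#' Screening configuration
#'
#' Constants for the energy-intake plausibility screen and the cohort
#' inclusion filters. The defaults are the published constants of the
#' McCrory-type screen: within-subject CV of reported energy intake 32.3%,
#' within-subject CV of predicted total energy expenditure 20.2%, within-
#' subject CV of measured total energy expenditure 8.2%, and two recall days.
#'
#' @param cv_wEI Within-subject CV of energy intake, percent.
#' @param cv_wpTEE Within-subject CV of predicted TEE, percent.
#' @param cv_tmTEE Within-subject CV of measured TEE, percent.
#' @param d_days Number of recall days contributing to the energy-intake mean.
#' @param kcal_to_MJ Conversion factor from kcal to MJ.
#' @param min_age Minimum age (years) for inclusion.
#' @param serum_zn_cutoff Lower limit of normal serum Zn (ug/dL); values
#'   below are flagged for prevalence reporting, never excluded.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(cv_wEI = 32.3, cv_wpTEE = 20.2, cv_tmTEE = 8.2,
                             d_days = 2, kcal_to_MJ = 0.004184,
                             min_age = 20, serum_zn_cutoff = 75) {
  if (any(c(cv_wEI, cv_wpTEE, cv_tmTEE) < 0)) stop("CVs must be non-negative")
  if (d_days < 1) stop("'d_days' must be at least 1")
  if (kcal_to_MJ <= 0) stop("'kcal_to_MJ' must be positive")
  structure(list(cv_wEI = cv_wEI, cv_wpTEE = cv_wpTEE, cv_tmTEE = cv_tmTEE,
                 d_days = d_days, kcal_to_MJ = kcal_to_MJ, min_age = min_age,
                 serum_zn_cutoff = serum_zn_cutoff),
            class = "screening_config")
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Standing height in metres.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(80, 1.80)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_m <= 0, na.rm = TRUE))
    stop("weight and height must be positive")
  weight_kg / height_m^2
}

#' Predicted total energy expenditure (MJ/day)
#'
#' Vinken-type prediction equation:
#' pTEE = 7.377 - 0.073 age + 0.0806 weight + 0.0135 height - 1.363 sex,
#' with age in years, weight in kg, standing height in cm, and sex coded
#' 0 for men, 1 for women.
#'
#' @param age Years.
#' @param weight_kg Kilograms.
#' @param height_cm Centimetres.
#' @param sex 0 (male) or 1 (female); vectors recycled as usual.
#' @return pTEE in MJ/day.
#' @examples
#' predict_tee(40, 80, 180, 0)
#' @export
predict_tee <- function(age, weight_kg, height_cm, sex) {
  if (!all(sex %in% c(0, 1))) stop("'sex' must be coded 0 (male) or 1 (female)")
  if (any(age < 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE) ||
      any(height_cm <= 0, na.rm = TRUE))
    stop("age must be non-negative; weight and height positive")
  7.377 - 0.073 * age + 0.0806 * weight_kg + 0.0135 * height_cm - 1.363 * sex
}

#' +/- 1 SD cut-off for the energy-intake / pTEE ratio
#'
#' Propagates the within-subject CVs of reported energy intake (divided by
#' the number of recall days) and of predicted and measured total energy
#' expenditure into the 1-SD half-width of the plausible EI/pTEE band:
#' sqrt(cv_wEI^2 / d + cv_wpTEE^2 + cv_tmTEE^2) / 100.
#'
#' @param config A [screening_config()].
#' @return The half-width as a fraction of the ratio.
#' @examples
#' misreport_cutoff_sd(screening_config())  # 0.3157 with the defaults
#' @export
misreport_cutoff_sd <- function(config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  sqrt(config$cv_wEI^2 / config$d_days + config$cv_wpTEE^2 +
         config$cv_tmTEE^2) / 100
}

#' Classify energy reporters
#'
#' A participant is an under-reporter when mean reported energy intake
#' (converted to MJ/day) falls below pTEE (1 - sd_cutoff), an over-reporter
#' above pTEE (1 + sd_cutoff); values exactly on a bound count as plausible.
#'
#' @param EI_kcal Mean energy intake over the recall days, kcal/day.
#' @param pTEE Predicted total energy expenditure, MJ/day.
#' @param sd_cutoff Band half-width, from [misreport_cutoff_sd()].
#' @param config A [screening_config()] (for the kcal-to-MJ constant).
#' @return Character vector in `c("plausible", "under", "over")`.
#' @export
classify_reporter <- function(EI_kcal, pTEE, sd_cutoff = misreport_cutoff_sd(config),
                              config = screening_config()) {
  if (any(pTEE <= 0, na.rm = TRUE)) stop("pTEE must be positive")
  if (any(EI_kcal < 0, na.rm = TRUE)) stop("EI_kcal must be non-negative")
  ratio <- (EI_kcal * config$kcal_to_MJ) / pTEE
  out <- rep("plausible", length(ratio))
  out[ratio < 1 - sd_cutoff] <- "under"
  out[ratio > 1 + sd_cutoff] <- "over"
  out[is.na(ratio)] <- NA_character_
  out
}

#' Per-participant screening table
#'
#' Convenience wrapper computing BMI, pTEE, the EI/pTEE ratio and the
#' reporter class for every row of a participant table.
#'
#' @param participants Participant data frame (see [generate_cohort()]).
#' @param config A [screening_config()].
#' @return Data frame with columns `id`, `bmi`, `pTEE`, `EI_MJ`, `ratio`,
#'   `sd_cutoff`, `reporter_class`, `serum_zn_low`.
#' @export
screen_participants <- function(participants, config = screening_config()) {
  sex01 <- ifelse(participants$sex == "female", 1, 0)
  pTEE <- predict_tee(participants$age, participants$weight_kg,
                      participants$height_cm, sex01)
  cutoff <- misreport_cutoff_sd(config)
  EI_MJ <- participants$energy_kcal * config$kcal_to_MJ
  serum_zn <- if ("serum_zn" %in% names(participants)) participants$serum_zn
              else rep(NA_real_, nrow(participants))
  data.frame(
    id = participants$id,
    bmi = compute_bmi(participants$weight_kg, participants$height_cm / 100),
    pTEE = pTEE,
    EI_MJ = EI_MJ,
    ratio = EI_MJ / pTEE,
    sd_cutoff = rep(cutoff, length.out = nrow(participants)),
    reporter_class = classify_reporter(participants$energy_kcal, pTEE,
                                       cutoff, config),
    serum_zn_low = !is.na(serum_zn) & serum_zn < config$serum_zn_cutoff,
    stringsAsFactors = FALSE
  )
}

#' Apply the cohort inclusion filters
#'
#' Removes participants in the stated order: (a) age below the minimum,
#' (b) pregnant, (c) missing any of weight, height, PUFA intake, Zn intake,
#' serum LA, serum DGLA, (d) energy under/over-reporters. Low serum Zn is
#' flagged (for prevalence reporting) but never used for exclusion.
#'
#' @param participants Participant data frame.
#' @param config A [screening_config()].
#' @return List with `participants` (filtered table, plus `bmi`, `pTEE` and
#'   `reporter_class` columns), and `filter_log` (data frame of per-step
#'   removal counts plus the low-serum-Zn flag count among the retained).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_participants = 200, seed = 5))
#' res <- apply_inclusion_filters(cohort$participants)
#' res$filter_log
#' @export
apply_inclusion_filters <- function(participants, config = screening_config()) {
  required <- c("id", "sex", "age", "pregnant", "weight_kg", "height_cm",
                "energy_kcal", "zn_mg", "pufa_g", "serum_la", "serum_dgla")
  missing_cols <- setdiff(required, names(participants))
  if (length(missing_cols) > 0)
    stop("participant table lacks columns: ", paste(missing_cols, collapse = ", "))

  n0 <- nrow(participants)
  tab <- participants

  keep <- !is.na(tab$age) & tab$age >= config$min_age
  n_age <- sum(!keep); tab <- tab[keep, , drop = FALSE]

  keep <- is.na(tab$pregnant) | tab$pregnant != 1
  keep[is.na(tab$pregnant)] <- TRUE
  n_preg <- sum(!keep); tab <- tab[keep, , drop = FALSE]

  vars <- c("weight_kg", "height_cm", "pufa_g", "zn_mg", "serum_la", "serum_dgla")
  keep <- stats::complete.cases(tab[, vars, drop = FALSE])
  n_missing <- sum(!keep); tab <- tab[keep, , drop = FALSE]

  scr <- screen_participants(tab, config)
  tab$bmi <- scr$bmi
  tab$pTEE <- scr$pTEE
  tab$reporter_class <- scr$reporter_class
  keep <- scr$reporter_class == "plausible"
  n_under <- sum(scr$reporter_class == "under")
  n_over <- sum(scr$reporter_class == "over")
  tab <- tab[keep, , drop = FALSE]

  if (nrow(tab) == 0) warning("no participants remain after filtering")

  n_zn_low <- sum(!is.na(tab$serum_zn) & tab$serum_zn < config$serum_zn_cutoff)
  filter_log <- data.frame(
    step = c("input", "age", "pregnant", "missing", "under_report",
             "over_report", "final", "serum_zn_low_flagged"),
    n = c(n0, n_age, n_preg, n_missing, n_under, n_over, nrow(tab), n_zn_low),
    stringsAsFactors = FALSE
  )
  list(participants = tab, filter_log = filter_log)
}
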