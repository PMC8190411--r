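#' Specify a synthetic recall cohort
#'
#' Builds the parameter object for [generate_cohort()]. The generator emulates
#' the data shape of a two-day 24-hour-recall survey: person-level usual
#' food-group intakes are log-normal (positive, right-skewed), each recall day
#' multiplies the usual intake by independent log-normal day noise, and
#' nutrient intakes (Zn, PUFA, energy) are density-weighted sums of the
#' food-group intakes plus measurement noise. A "rich in Zn, poor in PUFAs"
#' pattern is planted through the `pattern2_groups_pos` / `pattern2_groups_neg`
#' sets together with the Zn/PUFA density vectors, and the serum LA/DGLA ratio
#' and serum DGLA respond linearly to the true planted pattern score. A
#' fraction of participants has every reported intake multiplied by an under-
#' or over-reporting factor, so the energy-intake plausibility screen can be
#' validated against known flags.
#'
#' @param n_participants Number of participants.
#' @param sex `"female"` or `"male"`; cohorts are generated one sex at a time.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param group_medians Named 34-vector of median usual intakes (g/day),
#'   names `G1`..`G34`.
#' @param within_person_cv Day-to-day coefficient of variation of intake
#'   (fraction, > 0 in the default model; 0 is allowed and makes the two
#'   recall days identical).
#' @param between_person_cv Between-person coefficient of variation of usual
#'   intake (fraction).
#' @param zn_density,pufa_density,energy_density Named 34-vectors of nutrient
#'   content per gram of food group: mg Zn/g, g PUFA/g, kcal/g.
#' @param pattern2_groups_pos,pattern2_groups_neg Disjoint sets of group ids
#'   planted as the positive (Zn-dense) and negative (PUFA-dense) poles of
#'   dietary pattern 2.
#' @param beta_ratio Planted slope of serum LA/DGLA ratio on the true
#'   pattern-2 score (negative by default: higher adherence, lower ratio).
#' @param beta_dgla Planted slope of serum DGLA (umol/L) on the true score.
#' @param outcome_noise_sd Residual SD of the LA/DGLA ratio outcome.
#' @param dgla_noise_sd Residual SD of the DGLA outcome (umol/L).
#' @param misreport_fraction Fraction of participants whose reported intakes
#'   are uniformly scaled (half under-, half over-reporters on average).
#' @param misreport_factors Length-2 vector `c(under, over)` with the
#'   multiplicative factors (< 1 and > 1).
#' @param nutrient_noise_cv Fractional SD of the nutrient measurement noise
#'   added on top of the density-weighted sums.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [truth_summary()]
#' @export
cohort_spec <- function(n_participants = 800,
                        sex = c("female", "male"),
                        seed = 1L,
                        group_medians = default_group_medians(),
                        within_person_cv = 0.5,
                        between_person_cv = 0.45,
                        zn_density = default_zn_density(),
                        pufa_density = default_pufa_density(),
                        energy_density = default_energy_density(),
                        pattern2_groups_pos = c("G1", "G2", "G3", "G17"),
                        pattern2_groups_neg = c("G13", "G29", "G30"),
                        beta_ratio = -0.8,
                        beta_dgla = 6,
                        outcome_noise_sd = 5.5,
                        dgla_noise_sd = 45,
                        misreport_fraction = 0.15,
                        misreport_factors = c(0.5, 1.6),
                        nutrient_noise_cv = 0.05) {
  sex <- match.arg(sex)
  gids <- food_group_ids()
  if (length(n_participants) != 1L || is.na(n_participants) || n_participants < 1)
    stop("'n_participants' must be a positive count")
  for (nm in c("group_medians", "zn_density", "pufa_density", "energy_density")) {
    v <- get(nm)
    if (length(v) != 34L)
      stop(sprintf("'%s' must have length 34, got %d", nm, length(v)))
    if (any(v < 0)) stop(sprintf("'%s' must be non-negative", nm))
  }
  if (within_person_cv < 0 || between_person_cv < 0)
    stop("coefficients of variation must be non-negative")
  if (length(pattern2_groups_pos) == 0L || length(pattern2_groups_neg) == 0L)
    stop("planted pattern group sets must be non-empty")
  if (!all(c(pattern2_groups_pos, pattern2_groups_neg) %in% gids))
    stop("pattern group ids must be in G1..G34")
  if (length(intersect(pattern2_groups_pos, pattern2_groups_neg)) > 0L)
    stop("pattern group sets must be disjoint")
  if (misreport_fraction < 0 || misreport_fraction >= 1)
    stop("'misreport_fraction' must be in [0, 1)")
  if (!(misreport_factors[1] < 1 && misreport_factors[2] > 1))
    stop("'misreport_factors' must be c(under < 1, over > 1)")

  spec <- list(
    n_participants = as.integer(n_participants), sex = sex,
    seed = as.integer(seed),
    group_medians = stats::setNames(as.numeric(group_medians), gids),
    within_person_cv = within_person_cv, between_person_cv = between_person_cv,
    zn_density = stats::setNames(as.numeric(zn_density), gids),
    pufa_density = stats::setNames(as.numeric(pufa_density), gids),
    energy_density = stats::setNames(as.numeric(energy_density), gids),
    pattern2_groups_pos = pattern2_groups_pos,
    pattern2_groups_neg = pattern2_groups_neg,
    beta_ratio = beta_ratio, beta_dgla = beta_dgla,
    outcome_noise_sd = outcome_noise_sd, dgla_noise_sd = dgla_noise_sd,
    misreport_fraction = misreport_fraction,
    misreport_factors = misreport_factors,
    nutrient_noise_cv = nutrient_noise_cv
  )
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  n = %d %ss, seed %d\n", x$n_participants, x$sex, x$seed))
  cat(sprintf("  intake CV: within-person %.2f, between-person %.2f\n",
              x$within_person_cv, x$between_person_cv))
  cat(sprintf("  planted pattern 2: +{%s} -{%s}\n",
              paste(x$pattern2_groups_pos, collapse = ","),
              paste(x$pattern2_groups_neg, collapse = ",")))
  cat(sprintf("  planted slopes: LA/DGLA %.3g, DGLA %.3g; misreport fraction %.2f\n",
              x$beta_ratio, x$beta_dgla, x$misreport_fraction))
  invisible(x)
}

# Default intake medians (g/day) and nutrient densities. The density vectors
# are base profiles (relative nutrient content per gram) times a calibration
# scale chosen so the density-weighted totals land in the range seen for US
# adults: Zn ~9-13 mg/day, PUFA ~15-20 g/day, and energy intake centred just
# below predicted expenditure (EI/pTEE ~0.92 before intake noise), which also
# brackets the quintile medians the downstream tables report.

#' @rdname cohort_spec
#' @export
default_group_medians <- function() {
  stats::setNames(c(
    45, 70, 25, 20, 3, 12, 85, 40, 12, 25, 2, 55, 25, 6, 12, 60, 4,
    130, 1, 140, 80, 120, 90, 32, 8, 18, 55, 5, 4, 4, 18, 900, 90, 8
  ), food_group_ids())
}

#' @rdname cohort_spec
#' @export
default_zn_density <- function() {
  stats::setNames(0.75 * c(
    0.015, 0.012, 0.060, 0.020, 0.040, 0.010, 0.012, 0.008, 0.013, 0.010,
    0.030, 0.009, 0.004, 0.020, 0.006, 0.008, 0.150, 0.010, 0.015, 0.012,
    0.007, 0.001, 0.0005, 0.004, 0.005, 0.003, 0.003, 0.001, 0, 0.001,
    0.002, 0.0002, 0.0005, 0.015
  ), food_group_ids())
}

#' @rdname cohort_spec
#' @export
default_pufa_density <- function() {
  stats::setNames(0.95 * c(
    0.001, 0.004, 0.010, 0.015, 0.010, 0.020, 0.012, 0.008, 0.020, 0.005,
    0.250, 0.020, 0.040, 0.030, 0.015, 0.004, 0.010, 0.010, 0.010, 0.015,
    0.010, 0.001, 0.0005, 0.004, 0.002, 0.002, 0.003, 0.150, 0.350, 0.300,
    0.005, 0.0002, 0.0005, 0.010
  ), food_group_ids())
}

#' @rdname cohort_spec
#' @export
default_energy_density <- function() {
  stats::setNames(1.18 * c(
    0.5, 0.9, 2.5, 2.0, 1.5, 1.5, 1.8, 1.0, 1.5, 1.2, 6.0, 2.8, 4.0, 4.5,
    2.5, 1.3, 3.8, 1.2, 2.0, 1.5, 1.3, 0.55, 0.45, 0.9, 0.3, 0.35, 0.3,
    7.0, 8.8, 3.0, 3.8, 0.15, 0.8, 1.0
  ), food_group_ids())
}

# sdlog of a log-normal with coefficient of variation cv
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Generate a synthetic two-day recall cohort
#'
#' Draws a participant table and the matching ground-truth record from a
#' [cohort_spec()]. Demographics: age truncated-normal on 20-80 y,
#' sex-specific weight/height normals, PIR uniform on 0-5, multinomial
#' race/education, Bernoulli activity/medication/supplement indicators, and a
#' small pregnancy fraction in female cohorts. The true pattern-2 score of a
#' participant is the sum of z-scored usual (person-level) intakes over the
#' planted positive groups minus the sum over the planted negative groups;
#' serum outcomes respond linearly to it with small age and BMI covariate
#' terms. The same seed gives a bit-identical result.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synth_cohort` with elements
#'   \describe{
#'     \item{participants}{data frame, one row per participant (see Details).}
#'     \item{truth}{a `truth_record`: `true_pattern2_score`, `planted_signs`,
#'       `misreporter_flags`, `beta_ratio`, `beta_dgla`.}
#'   }
#' @details The participant table columns are: `id`, `sex`, `age`, `race`,
#' `education`, `pir`, `vigorous_work`, `vigorous_rec`, `lipid_lowering`,
#' `supplement_use`, `pregnant`, `weight_kg`, `height_cm`, the 68 per-day
#' intakes `g1_day1`..`g34_day2` (g/day), `energy_day1_kcal`,
#' `energy_day2_kcal`, `energy_kcal` (two-day mean), `zn_mg`, `pufa_g`,
#' `serum_la`, `serum_dgla` (umol/L), `la_dgla_ratio`, `serum_zn` (ug/dL).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_participants = 50, seed = 3))
#' dim(cohort$participants)
#' truth_summary(cohort$truth)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  n <- spec$n_participants
  gids <- food_group_ids()
  female <- spec$sex == "female"

  age <- rtrunc_norm(n, 48, 17.5, 20, 80)
  weight <- pmax(stats::rnorm(n, if (female) 75 else 85, if (female) 19 else 18), 35)
  height <- pmax(stats::rnorm(n, if (female) 162 else 176, if (female) 7 else 7.5), 130)
  bmi <- weight / (height / 100)^2
  pir <- stats::runif(n, 0, 5)
  race <- sample(c("Mexican American", "Other Hispanic", "Non-Hispanic White",
                   "Non-Hispanic Black", "Non-Hispanic Asian", "Other/Multi"),
                 n, replace = TRUE,
                 prob = c(0.11, 0.105, 0.39, 0.22, 0.15, 0.025))
  education <- sample(c("<9th grade", "9-11th grade", "High school graduate",
                        "Some college/AA", "College graduate+"),
                      n, replace = TRUE, prob = c(0.08, 0.14, 0.22, 0.28, 0.28))
  vigorous_work <- stats::rbinom(n, 1, 0.17)
  vigorous_rec <- stats::rbinom(n, 1, 0.22)
  lipid_lowering <- stats::rbinom(n, 1, 0.18)
  supplement_use <- stats::rbinom(n, 1, 0.24)
  pregnant <- if (female) stats::rbinom(n, 1, 0.02) else integer(n)

  # person-level usual intakes: log-normal around the group medians, scaled
  # by the person's predicted energy requirement relative to a typical
  # female requirement (intake tracks expenditure, so reported energy stays
  # plausibly centred on pTEE for honest reporters of either sex)
  pTEE <- predict_tee(age, weight, height, as.numeric(female))
  req_scale <- pmax(pTEE / predict_tee(48, 75, 162, 1), 0.3)
  sd_b <- lnorm_sdlog(spec$between_person_cv)
  sd_w <- lnorm_sdlog(spec$within_person_cv)
  mu <- log(pmax(spec$group_medians, 1e-8))
  base <- req_scale * exp(matrix(stats::rnorm(n * 34), n, 34) * sd_b +
                            matrix(mu, n, 34, byrow = TRUE))
  day1 <- base * exp(matrix(stats::rnorm(n * 34), n, 34) * sd_w)
  day2 <- base * exp(matrix(stats::rnorm(n * 34), n, 34) * sd_w)
  colnames(base) <- gids

  # true planted pattern score from the usual (person-level) intakes
  zb <- scale(base)
  score <- rowSums(zb[, spec$pattern2_groups_pos, drop = FALSE]) -
    rowSums(zb[, spec$pattern2_groups_neg, drop = FALSE])

  # nutrient intakes: density-weighted sums of the mean daily intakes
  day_mean <- (day1 + day2) / 2
  noise <- function(x) x * (1 + stats::rnorm(n, 0, spec$nutrient_noise_cv))
  zn_mg <- pmax(noise(drop(day_mean %*% spec$zn_density)), 0)
  pufa_g <- pmax(noise(drop(day_mean %*% spec$pufa_density)), 0)
  energy_day1 <- pmax(noise(drop(day1 %*% spec$energy_density)), 1)
  energy_day2 <- pmax(noise(drop(day2 %*% spec$energy_density)), 1)

  # serum outcomes respond to the true score plus small covariate terms
  ratio <- 25 + spec$beta_ratio * score + 0.02 * (age - 48) -
    0.05 * (bmi - 28) + stats::rnorm(n, 0, spec$outcome_noise_sd)
  ratio <- pmax(ratio, 2)
  dgla <- 150 + spec$beta_dgla * score + 0.3 * (bmi - 28) +
    stats::rnorm(n, 0, spec$dgla_noise_sd)
  dgla <- pmax(dgla, 20)
  serum_la <- ratio * dgla
  serum_zn <- pmax(stats::rnorm(n, 90, 8.5), 30)

  # misreporting: a uniform multiplicative factor on everything reported
  flags <- rep("none", n)
  n_mis <- stats::rbinom(1, n, spec$misreport_fraction)
  if (n_mis > 0) {
    idx <- sample.int(n, n_mis)
    under <- stats::rbinom(n_mis, 1, 0.5) == 1
    flags[idx[under]] <- "under"
    flags[idx[!under]] <- "over"
  }
  fac <- ifelse(flags == "under", spec$misreport_factors[1],
                ifelse(flags == "over", spec$misreport_factors[2], 1))
  day1 <- day1 * fac
  day2 <- day2 * fac
  zn_mg <- zn_mg * fac
  pufa_g <- pufa_g * fac
  energy_day1 <- energy_day1 * fac
  energy_day2 <- energy_day2 * fac

  participants <- data.frame(
    id = seq_len(n), sex = spec$sex, age = age, race = race,
    education = education, pir = pir, vigorous_work = vigorous_work,
    vigorous_rec = vigorous_rec, lipid_lowering = lipid_lowering,
    supplement_use = supplement_use, pregnant = pregnant,
    weight_kg = weight, height_cm = height,
    stringsAsFactors = FALSE
  )
  d1 <- as.data.frame(day1); names(d1) <- day_intake_cols(1)
  d2 <- as.data.frame(day2); names(d2) <- day_intake_cols(2)
  participants <- cbind(participants, d1, d2)
  participants$energy_day1_kcal <- energy_day1
  participants$energy_day2_kcal <- energy_day2
  participants$energy_kcal <- (energy_day1 + energy_day2) / 2
  participants$zn_mg <- zn_mg
  participants$pufa_g <- pufa_g
  participants$serum_la <- serum_la
  participants$serum_dgla <- dgla
  participants$la_dgla_ratio <- ratio
  participants$serum_zn <- serum_zn

  planted <- c(stats::setNames(rep(1, length(spec$pattern2_groups_pos)),
                               spec$pattern2_groups_pos),
               stats::setNames(rep(-1, length(spec$pattern2_groups_neg)),
                               spec$pattern2_groups_neg))
  truth <- structure(list(
    true_pattern2_score = score,
    planted_signs = planted,
    misreporter_flags = flags,
    beta_ratio = spec$beta_ratio,
    beta_dgla = spec$beta_dgla
  ), class = "truth_record")

  structure(list(participants = participants, truth = truth),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d %ss, %d columns\n",
              nrow(x$participants), x$participants$sex[1],
              ncol(x$participants)))
  tab <- table(factor(x$truth$misreporter_flags,
                      levels = c("none", "under", "over")))
  cat(sprintf("  misreporters: %d under, %d over (of %d)\n",
              tab[["under"]], tab[["over"]], nrow(x$participants)))
  invisible(x)
}

#' Summarise the planted ground truth of a synthetic cohort
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @return A list with `signs` (data frame of planted group signs),
#'   `slopes` (named vector: `beta_ratio`, `beta_dgla`) and
#'   `misreporter_counts` (named vector: none/under/over tallies).
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "truth_record"))
  counts <- table(factor(truth$misreporter_flags,
                         levels = c("none", "under", "over")))
  list(
    signs = data.frame(group_id = names(truth$planted_signs),
                       sign = unname(truth$planted_signs),
                       stringsAsFactors = FALSE),
    slopes = c(beta_ratio = truth$beta_ratio, beta_dgla = truth$beta_dgla),
    misreporter_counts = stats::setNames(as.integer(counts), names(counts))
  )
}

#' Write / read a participant table as CSV
#'
#' The CSV schema is identical to the in-memory schema documented in
#' [generate_cohort()], so a written cohort round-trips exactly through the
#' downstream screening and modelling stages.
#'
#' @param participants Participant data frame.
#' @param path File path.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
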