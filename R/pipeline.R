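#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end sex-stratified analysis. Input is
#' either synthetic (a [cohort_spec()] template applied per sex) or CSV paths
#' per sex in the [generate_cohort()] schema.
#'
#' @param input `"synthetic"` or a named character vector of CSV paths,
#'   e.g. `c(female = "f.csv", male = "m.csv")`.
#' @param sexes Strata to run, subset of `c("female", "male")`.
#' @param n_participants Per-sex cohort size for synthetic input.
#' @param screening A [screening_config()].
#' @param K Number of RRR factors retained (1 or 2).
#' @param loading_threshold Absolute-loading cut-off for simplified patterns.
#' @param loading_type `"correlation"` or `"regression"` (see [fit_rrr()]).
#' @param trend_variable `"index"` or `"median_score"` (see
#'   [quintile_trend_test()]).
#' @param outdir Output directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @param seed Master seed; per-sex generator seeds are derived from it.
#' @param cohort_args Extra arguments passed to [cohort_spec()] for
#'   synthetic input (e.g. `beta_ratio`, `misreport_fraction`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic",
                            sexes = c("female", "male"),
                            n_participants = 800,
                            screening = screening_config(),
                            K = 2,
                            loading_threshold = 0.20,
                            loading_type = c("correlation", "regression"),
                            trend_variable = c("index", "median_score"),
                            outdir = NULL,
                            seed = 1L,
                            cohort_args = list()) {
  loading_type <- match.arg(loading_type)
  trend_variable <- match.arg(trend_variable)
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  if (!K %in% c(1, 2)) stop("K must be 1 or 2")
  if (loading_threshold <= 0 || loading_threshold >= 1)
    stop("loading_threshold must be in (0, 1)")
  structure(list(input = input, sexes = sexes,
                 n_participants = n_participants, screening = screening,
                 K = as.integer(K), loading_threshold = loading_threshold,
                 loading_type = loading_type, trend_variable = trend_variable,
                 outdir = outdir, seed = as.integer(seed),
                 cohort_args = cohort_args),
            class = "pipeline_config")
}

# deterministic cheap fingerprint of the configuration (plumbing, not crypto)
config_fingerprint <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "outdir")]), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

fmt_cell <- function(x) {
  sprintf("%.4g (%.3g-%.3g)", stats::median(x), min(x), max(x))
}

# median (min-max) per quintile for one variable, plus the trend p-value
quintile_row <- function(values, quintile, adjust_energy, energy,
                         trend_variable, score) {
  tr <- quintile_trend_test(values, quintile, adjust_energy, energy,
                            trend_variable = trend_variable, score = score)
  cells <- vapply(1:5, function(q) fmt_cell(values[quintile == q]), "")
  c(stats::setNames(cells, paste0("Q", 1:5)),
    p_trend = sprintf("%.4g", tr$p_value))
}

#' Quintile descriptive table
#'
#' The Table-3/4/5 style summary: one row per variable with median (min-max)
#' in each quintile of a simplified pattern score and the linear-trend
#' p-value. Food-group and nutrient rows are energy-adjusted in the trend
#' test; serum rows are not.
#'
#' @param vars Named list of numeric vectors (the variables to summarise).
#' @param quintile Quintile labels 1..5.
#' @param energy Energy intakes for trend adjustment.
#' @param adjust Named logical vector (or single logical) saying which
#'   variables get the energy-adjusted trend test.
#' @param trend_variable,score Passed to [quintile_trend_test()].
#' @return Data frame with columns `variable`, `Q1`..`Q5`, `p_trend`.
#' @export
quintile_table <- function(vars, quintile, energy, adjust = TRUE,
                           trend_variable = "index", score = NULL) {
  if (length(adjust) == 1) adjust <- stats::setNames(rep(adjust, length(vars)),
                                                     names(vars))
  rows <- lapply(names(vars), function(v) {
    quintile_row(vars[[v]], quintile, isTRUE(adjust[[v]]), energy,
                 trend_variable, score)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  cbind(variable = names(vars), out, stringsAsFactors = FALSE)
}

run_stratum <- function(participants, config, sex) {
  filt <- apply_inclusion_filters(participants, config$screening)
  tab <- filt$participants
  if (nrow(tab) < 30)
    stop("stage screening [", sex, "]: too few participants after filtering (",
         nrow(tab), ")")

  day1 <- cohort_day_matrix(tab, 1)
  day2 <- cohort_day_matrix(tab, 2)
  usual <- estimate_usual_intake(day1, day2)

  zn_adj <- energy_adjust(tab$zn_mg, tab$energy_kcal)
  pufa_adj <- energy_adjust(tab$pufa_g, tab$energy_kcal)

  Xs <- standardize_columns(usual)
  Ys <- standardize_columns(cbind(zn = zn_adj, pufa = pufa_adj))
  fit <- fit_rrr(Xs$z, Ys$z, K = config$K, sign_ref = "zn",
                 loading_type = config$loading_type)

  patterns <- lapply(seq_len(config$K), function(k)
    simplify_pattern(fit, k, threshold = config$loading_threshold))
  names(patterns) <- paste0("pattern", seq_len(config$K))

  # descriptive + association layers per pattern
  per_pattern <- lapply(patterns, function(pat) {
    q <- pat$quintile
    food_vars <- stats::setNames(
      lapply(pat$contributing_groups$group_id, function(g) usual[, g]),
      pat$contributing_groups$group_id)
    nutrient_vars <- list(zn_mg = tab$zn_mg, pufa_g = tab$pufa_g)
    serum_vars <- list(serum_zn = tab$serum_zn, serum_dgla = tab$serum_dgla,
                       la_dgla_ratio = tab$la_dgla_ratio)
    adj <- c(rep(TRUE, length(food_vars) + length(nutrient_vars)),
             rep(FALSE, length(serum_vars)))
    all_vars <- c(food_vars, nutrient_vars, serum_vars)
    names(adj) <- names(all_vars)
    desc <- quintile_table(all_vars, q, tab$energy_kcal, adj,
                           config$trend_variable, pat$score)

    chi <- lapply(list(race = tab$race, education = tab$education),
                  function(v) categorical_quintile_test(v, q))

    pcor <- list(
      pufa = partial_correlation(pat$score, tab$pufa_g, tab$energy_kcal),
      zn = partial_correlation(pat$score, tab$zn_mg, tab$energy_kcal))

    covs <- data.frame(age = tab$age, energy_kcal = tab$energy_kcal,
                       pir = tab$pir, race = tab$race,
                       vigorous_work = tab$vigorous_work,
                       vigorous_rec = tab$vigorous_rec, bmi = tab$bmi,
                       education = tab$education,
                       lipid_lowering = tab$lipid_lowering,
                       supplement_use = tab$supplement_use,
                       stringsAsFactors = FALSE)
    regs <- list()
    for (oc in c("serum_dgla", "la_dgla_ratio")) {
      regs[[paste0(oc, "_model1")]] <-
        outcome_regression(tab[[oc]], pat$score, model = "model1")
      regs[[paste0(oc, "_model2")]] <-
        outcome_regression(tab[[oc]], pat$score, covs, model = "model2")
    }
    list(pattern = pat, quintile_table = desc, chi_square = chi,
         partial_correlations = pcor, regressions = regs)
  })

  list(sex = sex, filter_log = filt$filter_log, n = nrow(tab),
       usual_intake = usual, fit = fit, explained = fit$explained,
       loadings = fit$loadings, patterns = per_pattern,
       participants = tab)
}

#' Run the full sex-stratified analysis
#'
#' Executes, per sex stratum: generate or ingest the cohort, apply the
#' inclusion and misreporting filters, estimate usual food-group intakes,
#' energy-adjust the nutrient responses, z-standardize, fit the reduced rank
#' regression, derive loadings and simplified patterns with quintiles, and
#' compute the descriptive and association layers. Deterministic given the
#' seed; when `outdir` is set all stage artifacts are written as CSV.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: per-sex results plus provenance.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(n_participants = 300, seed = 11))
#' rep$female$explained
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  strata <- list()
  for (sex in config$sexes) {
    participants <- if (identical(config$input, "synthetic")) {
      seed_sex <- config$seed + 1000L * match(sex, c("female", "male"))
      spec <- do.call(cohort_spec, c(
        list(n_participants = config$n_participants, sex = sex,
             seed = seed_sex), config$cohort_args))
      generate_cohort(spec)$participants
    } else {
      if (is.null(names(config$input)) || !sex %in% names(config$input))
        stop("stage ingest [", sex, "]: no input path for this stratum")
      read_participants(config$input[[sex]])
    }
    strata[[sex]] <- run_stratum(participants, config, sex)
  }
  report <- structure(c(strata, list(
    provenance = list(seed = config$seed,
                      config_fingerprint = config_fingerprint(config),
                      package_version = as.character(utils::packageVersion("rrrdiet")),
                      K = config$K, loading_threshold = config$loading_threshold)
  )), class = "run_report")
  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  report
}

#' @rdname run_pipeline
#' @param report A `run_report`.
#' @param outdir Directory to write into.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sex in intersect(c("female", "male"), names(report))) {
    d <- file.path(outdir, sex)
    dir.create(d, showWarnings = FALSE)
    st <- report[[sex]]
    utils::write.csv(st$filter_log, file.path(d, "filter_log.csv"),
                     row.names = FALSE)
    write_rrr_model(st$fit, file.path(d, "rrr_model"))
    for (pn in names(st$patterns)) {
      pp <- st$patterns[[pn]]
      utils::write.csv(pp$pattern$contributing_groups,
                       file.path(d, paste0(pn, "_groups.csv")),
                       row.names = FALSE)
      utils::write.csv(pp$quintile_table,
                       file.path(d, paste0(pn, "_quintile_table.csv")),
                       row.names = FALSE)
      assoc <- do.call(rbind, lapply(names(pp$regressions), function(nm) {
        r <- pp$regressions[[nm]]
        data.frame(test = nm, estimate = r$estimate, se = r$se,
                   p_value = r$p_value, adj_r2 = r$adj_r2, n = r$n_used)
      }))
      utils::write.csv(assoc, file.path(d, paste0(pn, "_associations.csv")),
                       row.names = FALSE)
    }
  }
  prov <- report$provenance
  utils::write.csv(data.frame(key = names(prov),
                              value = vapply(prov, as.character, "")),
                   file.path(outdir, "provenance.csv"), row.names = FALSE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Dietary-pattern pipeline report\n")
  for (sex in intersect(c("female", "male"), names(x))) {
    st <- x[[sex]]
    cat(sprintf("  %s: n = %d after filtering; cumulative explained variation %.3f\n",
                sex, st$n, st$explained[nrow(st$explained), "cumulative_overall"]))
  }
  invisible(x)
}

#' Render a run report as human-readable tables
#'
#' Formats the demographic comparison between sexes (mean +/- SD, category
#' percentages, Welch t and chi-square tests), the partial-correlation
#' table, the quintile median (min-max) tables, and the regression
#' summaries, as plain text.
#'
#' @param report A `run_report` with both sex strata for the demographic
#'   comparison (a single stratum renders without it).
#' @return Character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  sexes <- intersect(c("female", "male"), names(report))
  lines <- c("=== Dietary pattern analysis report ===", "")

  for (sex in sexes) {
    st <- report[[sex]]
    for (pn in names(st$patterns)) {
      q <- st$patterns[[pn]]$pattern$quintile
      if (is.null(q) || length(unique(q)) != 5)
        stop("expected 5 quintiles in ", sex, " ", pn)
    }
  }

  if (length(sexes) == 2) {
    f <- report$female$participants; m <- report$male$participants
    lines <- c(lines, "-- Demographics (female vs male) --")
    for (v in c("age", "bmi", "pir")) {
      tt <- stats::t.test(f[[v]], m[[v]])
      lines <- c(lines, sprintf(
        "%-6s %.1f +/- %.1f vs %.1f +/- %.1f (Welch p = %.3g)", v,
        mean(f[[v]]), stats::sd(f[[v]]), mean(m[[v]]), stats::sd(m[[v]]),
        tt$p.value))
    }
    for (v in c("race", "education")) {
      both <- rbind(data.frame(sex = "female", x = f[[v]]),
                    data.frame(sex = "male", x = m[[v]]))
      ct <- suppressWarnings(stats::chisq.test(table(both$sex, both$x),
                                               correct = FALSE))
      lines <- c(lines, sprintf("%s: chi-square p = %.3g", v, ct$p.value))
    }
    lines <- c(lines, "")
  }

  for (sex in sexes) {
    st <- report[[sex]]
    lines <- c(lines, sprintf("-- %s (n = %d) --", sex, st$n),
               "Explained variation:",
               utils::capture.output(print(round(st$explained, 4))))
    lines <- c(lines, "", "Partial correlations (adjusted for energy):")
    for (pn in names(st$patterns)) {
      pc <- st$patterns[[pn]]$partial_correlations
      lines <- c(lines, sprintf("  %s: r(PUFA) = %.2f, r(Zn) = %.2f", pn,
                                pc$pufa$estimate, pc$zn$estimate))
    }
    for (pn in names(st$patterns)) {
      pp <- st$patterns[[pn]]
      lines <- c(lines, "", sprintf("Quintile table, %s [median (min-max)]:", pn),
                 utils::capture.output(print(pp$quintile_table, row.names = FALSE)))
      if (length(pp$regressions) == 0) {
        warning("empty association section for ", sex, " ", pn, "; omitted")
        next
      }
      lines <- c(lines, "Regressions (score coefficient):")
      for (nm in names(pp$regressions)) {
        r <- pp$regressions[[nm]]
        lines <- c(lines, sprintf(
          "  %-24s beta = %8.4f (SE %.4f), p = %.3g, adj R2 = %.3f", nm,
          r$estimate, r$se, r$p_value, r$adj_r2))
      }
    }
    lines <- c(lines, "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
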