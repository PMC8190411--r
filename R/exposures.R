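#' Map recall food items onto the 34 food groups
#'
#' Sums item-level grams per participant and recall day into the 34-group
#' scheme of [food_groups()]. The mapping file routes each food code either
#' directly to a group (`split = "none"`) or through one of the two published
#' splits: `"dairy_fat"` sends low-fat items to G1 and whole-fat items to G2;
#' `"grain_fiber"` sends items with strictly more than 2.5 g fiber per
#' serving to G20 (good source) and the rest (at or below 2.5 g) to G21.
#'
#' @param items Data frame with columns `id`, `day`, `food_code`, `grams`,
#'   and, where the mapping requires a split, `low_fat` (logical) and/or
#'   `fiber_per_serving` (g).
#' @param mapping Data frame with columns `food_code`, `group_id`, `split`
#'   (`"none"`, `"dairy_fat"`, `"grain_fiber"`); `group_id` is ignored for
#'   split rows. See `system.file("extdata", "toy_food_mapping.csv",
#'   package = "rrrdiet")`.
#' @return Named list of `food_group_matrix` objects, one per recall day:
#'   n x 34 matrices (rownames = participant ids) of g/day.
#' @export
map_food_groups <- function(items, mapping) {
  need <- c("id", "day", "food_code", "grams")
  if (!all(need %in% names(items)))
    stop("item table needs columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(items$food_code), mapping$food_code)
  if (length(unknown) > 0)
    stop("unknown food code(s): ", paste(unknown, collapse = ", "))

  m <- mapping[match(items$food_code, mapping$food_code), ]
  gid <- m$group_id
  is_dairy <- m$split == "dairy_fat"
  if (any(is_dairy)) {
    if (!"low_fat" %in% names(items) || anyNA(items$low_fat[is_dairy]))
      stop("dairy split requires a non-missing 'low_fat' attribute")
    gid[is_dairy] <- ifelse(items$low_fat[is_dairy], "G1", "G2")
  }
  is_grain <- m$split == "grain_fiber"
  if (any(is_grain)) {
    if (!"fiber_per_serving" %in% names(items) ||
        anyNA(items$fiber_per_serving[is_grain]))
      stop("grain split requires a non-missing 'fiber_per_serving' attribute")
    gid[is_grain] <- ifelse(items$fiber_per_serving[is_grain] > 2.5, "G20", "G21")
  }

  ids <- sort(unique(items$id))
  days <- sort(unique(items$day))
  out <- lapply(days, function(d) {
    sel <- items$day == d
    mat <- matrix(0, length(ids), 34,
                  dimnames = list(ids, food_group_ids()))
    agg <- stats::aggregate(items$grams[sel],
                            by = list(id = items$id[sel], gid = gid[sel]), sum)
    mat[cbind(match(agg$id, ids), match(agg$gid, food_group_ids()))] <- agg$x
    class(mat) <- c("food_group_matrix", class(mat))
    mat
  })
  names(out) <- paste0("day", days)
  out
}

#' Usual food-group intake by variance-component shrinkage
#'
#' Removes within-person day-to-day variation from two recall days. For each
#' food group a one-way ANOVA on persons decomposes the variance into
#' between-person (`sigma2_b`) and within-person (`sigma2_w`) components
#' (negative moment estimates truncated at zero), and the usual intake of
#' person i is the population mean plus the person's deviation shrunk by
#' `sigma2_b / (sigma2_b + sigma2_w / 2)`. This is a deliberately simplified
#' stand-in for fuller usual-intake models: two recall days identify only the
#' within/between decomposition, which is all the downstream pattern
#' extraction needs.
#'
#' @param day1,day2 n x 34 matrices of g/day for the same participants in the
#'   same row order (e.g. from [map_food_groups()] or the generator columns).
#' @return n x 34 matrix of usual intakes, with attribute `"shrinkage"`
#'   giving the per-group shrinkage factor.
#' @export
estimate_usual_intake <- function(day1, day2) {
  day1 <- as.matrix(day1); day2 <- as.matrix(day2)
  if (!all(dim(day1) == dim(day2)))
    stop("day matrices must have identical dimensions")
  n <- nrow(day1)
  if (n < 3) stop("need at least 3 participants")

  ind_mean <- (day1 + day2) / 2
  pop_mean <- colMeans(ind_mean)
  # one-way ANOVA with 2 observations per person:
  # MS_between = 2 * var(person means), MS_within = mean squared half-difference
  ms_between <- 2 * apply(ind_mean, 2, stats::var)
  ms_within <- colSums((day1 - day2)^2 / 2) / n
  sigma2_w <- ms_within
  sigma2_b <- pmax((ms_between - ms_within) / 2, 0)
  denom <- sigma2_b + sigma2_w / 2
  shrink <- ifelse(denom > 0, sigma2_b / denom, 0)
  # if both components are zero the group is constant; usual = mean
  usual <- sweep(sweep(ind_mean, 2, pop_mean, "-"), 2, shrink, "*")
  usual <- sweep(usual, 2, pop_mean, "+")
  dimnames(usual) <- dimnames(day1)
  attr(usual, "shrinkage") <- shrink
  usual
}

#' Energy adjustment by the residual method
#'
#' Replaces a nutrient intake by its residual from an ordinary least squares
#' regression on total energy intake (with intercept), plus the nutrient
#' sample mean. The adjusted vector keeps the original mean, is exactly
#' uncorrelated with energy in-sample, and may contain negative values.
#'
#' @param nutrient n-vector of nutrient intakes.
#' @param energy n-vector of energy intakes (kcal/day), positive variance.
#' @return Adjusted n-vector.
#' @examples
#' energy_adjust(c(5, 10, 12), c(1000, 2000, 3000))  # 8.5 10.0 8.5
#' @export
energy_adjust <- function(nutrient, energy) {
  if (length(nutrient) != length(energy)) stop("length mismatch")
  if (length(nutrient) < 3) stop("need n >= 3")
  if (stats::var(energy) <= 0) stop("energy has zero variance")
  fit <- stats::lm.fit(cbind(1, energy), nutrient)
  fit$residuals + mean(nutrient)
}

#' Extract the per-day intake matrices from a participant table
#'
#' @param participants Participant data frame in the [generate_cohort()]
#'   schema.
#' @param day Recall day, 1 or 2.
#' @return n x 34 matrix (columns `G1`..`G34`, rownames = `id`).
#' @export
cohort_day_matrix <- function(participants, day) {
  cols <- day_intake_cols(day)
  if (!all(cols %in% names(participants)))
    stop("participant table lacks day-", day, " intake columns")
  m <- as.matrix(participants[, cols])
  dimnames(m) <- list(participants$id, food_group_ids())
  m
}
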