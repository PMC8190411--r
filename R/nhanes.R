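#' Read survey microdata from SAS XPORT files into the participant schema
#'
#' Best-effort real-data mode for the public NHANES 2011-2012 release: reads
#' one or more SAS XPORT (.xpt) files (demographics DEMO_G, body measures
#' BMX_G, the day-1/day-2 dietary totals DR1TOT_G/DR2TOT_G, and the serum
#' fatty-acid panel FAS_G), merges them on the participant id, and renames
#' variables to the internal schema through a user-editable mapping file.
#'
#' The mapping file is delimited text with columns `source` (NHANES variable
#' name, e.g. `RIDAGEYR`) and `target` (internal column, e.g. `age`); a
#' template covering the variables this pipeline needs ships at
#' `system.file("extdata", "nhanes_variable_map.csv", package = "rrrdiet")`.
#' Food-group day intakes are not part of NHANES totals files; item-level
#' recalls must be aggregated with [map_food_groups()] separately.
#'
#' @param paths Character vector of .xpt file paths.
#' @param mapping Data frame with columns `source`, `target`, or a path to
#'   such a CSV. Defaults to the shipped template.
#' @param id_var Merge key, default `"SEQN"`.
#' @return Data frame with the internal column names; unmapped source
#'   variables are dropped.
#' @export
read_nhanes_xpt <- function(paths,
                            mapping = system.file("extdata",
                                                  "nhanes_variable_map.csv",
                                                  package = "rrrdiet"),
                            id_var = "SEQN") {
  if (!requireNamespace("foreign", quietly = TRUE))
    stop("package 'foreign' is required to read XPORT files")
  if (is.character(mapping)) mapping <- utils::read.csv(mapping,
                                                        stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(mapping)))
    stop("mapping needs columns 'source' and 'target'")
  tabs <- lapply(paths, foreign::read.xport)
  merged <- Reduce(function(a, b) merge(a, b, by = id_var, all = TRUE), tabs)
  apply_variable_mapping(merged, mapping, id_var)
}

#' @rdname read_nhanes_xpt
#' @param data Data frame with source-named columns.
#' @export
apply_variable_mapping <- function(data, mapping, id_var = "SEQN") {
  keep <- mapping$source %in% names(data)
  out <- data[, mapping$source[keep], drop = FALSE]
  names(out) <- mapping$target[keep]
  if (id_var %in% names(data) && !"id" %in% names(out))
    out$id <- data[[id_var]]
  # NHANES codes sex 1 = male, 2 = female
  if ("sex" %in% names(out) && is.numeric(out$sex))
    out$sex <- ifelse(out$sex == 2, "female", "male")
  # NHANES codes pregnancy status 1 = yes; other codes and NA mean not pregnant
  if ("pregnant" %in% names(out) && is.numeric(out$pregnant))
    out$pregnant <- as.integer(!is.na(out$pregnant) & out$pregnant == 1)
  if (all(c("energy_day1_kcal", "energy_day2_kcal") %in% names(out)) &&
      !"energy_kcal" %in% names(out))
    out$energy_kcal <- (out$energy_day1_kcal + out$energy_day2_kcal) / 2
  if (all(c("serum_la", "serum_dgla") %in% names(out)) &&
      !"la_dgla_ratio" %in% names(out))
    out$la_dgla_ratio <- out$serum_la / out$serum_dgla
  out
}
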