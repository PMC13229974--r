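phenotype_columns <- c(
  "genotype", "year", "role", "n_planted", "n_evaluated", "n_fertile",
  "seed_available"
)

#' Read a phenotype table
#'
#' Reads the delimited phenotype-record schema shared by field data and
#' simulated panels: a UTF-8 CSV with a header and the columns `genotype`,
#' `year`, `role` (`entry` / `positive_control` / `negative_control`),
#' `n_planted`, `n_evaluated`, `n_fertile` and `seed_available`. Unknown
#' columns are preserved as pass-through metadata. Count inconsistencies
#' (more fertile than evaluated, more evaluated than planted) are hard errors
#' naming the offending file lines.
#'
#' The packaged example `stage1_qualifiers.csv` is a three-season stage-1
#' qualifier list from a maize SHGD screening program (genotypes at or above
#' 25% observed HMF, with the positive check A427 and seed-availability
#' advancement flags). Per-plant counts were not part of the published
#' summary, so the fixture uses a nominal evaluated count of 100 plants per
#' record, which represents every reported integer percentage exactly; the
#' count columns are a transcription convention, not field data. The positive
#' check A427 is recorded as an `entry` in 2022 — its qualifying cohort year,
#' when it advanced to confirmation with the other qualifiers — and as
#' `positive_control` in the later seasons where it returns as the in-trial
#' check.
#'
#' @param path Path to a CSV file.
#' @return A tibble of typed phenotype records.
#' @examples
#' path <- system.file("extdata", "stage1_qualifiers.csv", package = "hmfscreen")
#' records <- read_phenotype_table(path)
#' dplyr::count(records, year)
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      genotype = readr::col_character(),
      year = readr::col_integer(),
      role = readr::col_character(),
      n_planted = readr::col_integer(),
      n_evaluated = readr::col_integer(),
      n_fertile = readr::col_integer(),
      seed_available = readr::col_logical(),
      .default = readr::col_guess()
    ),
    show_col_types = FALSE
  )
  missing <- setdiff(phenotype_columns, names(records))
  if (length(missing) > 0) {
    abort(paste0(
      "Phenotype table ", path, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(records) == 0) {
    warn(paste0("Phenotype table ", path, " has a header but no records."))
    return(records)
  }
  bad_role <- !records$role %in% c("entry", "positive_control", "negative_control")
  if (any(bad_role)) {
    abort(paste0(
      "Unknown role on line(s) ", paste(which(bad_role) + 1L, collapse = ", "),
      " of ", path
    ))
  }
  check_rows <- function(bad, what) {
    if (any(bad)) {
      abort(paste0(
        what, " on line(s) ", paste(which(bad) + 1L, collapse = ", "),
        " of ", path, " (genotype ",
        paste(records$genotype[bad], collapse = ", "), ")"
      ))
    }
  }
  incomplete <- !stats::complete.cases(
    records[c("genotype", "year", "n_planted", "n_evaluated", "n_fertile", "seed_available")]
  )
  check_rows(incomplete, "Missing or unparseable value")
  check_rows(records$n_fertile > records$n_evaluated, "n_fertile exceeds n_evaluated")
  check_rows(records$n_evaluated > records$n_planted, "n_evaluated exceeds n_planted")
  check_rows(records$n_fertile < 0 | records$n_evaluated < 0 | records$n_planted < 0, "Negative count")
  records
}

#' Write a phenotype table
#'
#' Writes records in the schema read by [read_phenotype_table()]; writing
#' then reading is an identity on the typed columns.
#'
#' @param records A phenotype-record data frame.
#' @param path Output CSV path.
#' @return `records`, invisibly.
#' @export
write_phenotype_table <- function(records, path) {
  missing <- setdiff(phenotype_columns, names(records))
  if (length(missing) > 0) {
    abort(paste0("Records are missing required column(s): ", paste(missing, collapse = ", ")))
  }
  records <- dplyr::relocate(as_tibble(records), dplyr::all_of(phenotype_columns))
  readr::write_csv(records, path)
  invisible(records)
}

#' Write a per-year qualifier report
#'
#' Stage-1 decisions sorted by observed HMF descending — the layout of the
#' traditional yearly qualifier table — with percentages printed to one
#' decimal.
#'
#' @param decisions A `stage1_decisions` tibble from [stage1_select()].
#' @param path Output CSV path.
#' @return The report tibble, invisibly.
#' @export
write_qualifier_report <- function(decisions, path) {
  if (!inherits(decisions, "stage1_decisions")) {
    abort("`decisions` must come from `stage1_select()`.")
  }
  report <- dplyr::arrange(
    dplyr::transmute(
      as_tibble(decisions),
      genotype = .data$genotype,
      year = .data$year,
      role = .data$role,
      hmf_pct = round(.data$hmf_pct, 1),
      passed_threshold = .data$passed_threshold,
      advanced = .data$advanced,
      reason = as.character(.data$reason)
    ),
    dplyr::desc(.data$hmf_pct)
  )
  readr::write_csv(report, path)
  invisible(report)
}

#' Export a GWAS-ready phenotype file
#'
#' Collapses multi-year records to one row per genotype — per-year HMF
#' columns plus the across-year mean — the shape expected as phenotypic input
#' by downstream association tools.
#'
#' @param records Multi-year phenotype records.
#' @param path Optional output CSV path.
#' @return A tibble with `genotype`, one `hmf_<year>` column per year, and
#'   `hmf_mean` over the evaluated years.
#' @export
export_gwas_phenotypes <- function(records, path = NULL) {
  records <- compute_hmf(records)
  if (!"year" %in% names(records)) abort("`records` must have a `year` column.")
  evaluated <- dplyr::filter(records, !.data$unevaluable)
  wide <- tidyr::pivot_wider(
    dplyr::select(evaluated, "genotype", "year", "hmf_pct"),
    names_from = "year", values_from = "hmf_pct", names_prefix = "hmf_"
  )
  means <- dplyr::summarise(
    dplyr::group_by(evaluated, .data$genotype),
    hmf_mean = mean(.data$hmf_pct), .groups = "drop"
  )
  out <- dplyr::left_join(wide, means, by = "genotype")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

run_config_keys <- c(
  "n_kernels", "thresholds", "threshold", "threshold_pct",
  "germination_rate", "roguing_rate", "adjust_n", "rounding_rule",
  "pi_high", "low", "high", "integration",
  "n_genotypes", "years", "year_effect_sd", "diploid_contamination_rate",
  "min_detect", "max_fpr", "seed", "input", "stage1", "output", "log_level"
)

#' Read a flat run-configuration file
#'
#' Run configurations are flat YAML key/value files covering the design grid,
#' field rates, prior specification, pipeline thresholds, seed and IO paths.
#' Keys outside the documented schema are an error, so a typo fails loudly
#' before any computation runs.
#'
#' Recognized keys: `n_kernels`, `thresholds`, `threshold`, `threshold_pct`,
#' `germination_rate`, `roguing_rate`, `adjust_n`, `rounding_rule`,
#' `pi_high`, `low`, `high`, `integration`, `n_genotypes`, `years`,
#' `year_effect_sd`, `diploid_contamination_rate`, `min_detect`, `max_fpr`,
#' `seed`, `input`, `stage1`, `output`, `log_level`.
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  config <- yaml::read_yaml(path)
  if (is.null(config)) {
    return(list())
  }
  if (!is.list(config) || is.null(names(config)) || any(names(config) == "")) {
    abort("Config must be a flat mapping of named keys.")
  }
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config
}
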