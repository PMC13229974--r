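#' Compute observed haploid male fertility from plant counts
#'
#' HMF(%) is the number of pollen-shedding haploid plants over the total
#' number of haploids evaluated, times 100. Adds an `hmf_pct` column and an
#' `unevaluable` flag (no plants survived to scoring, so no numeric HMF
#' exists) after validating the count bookkeeping.
#'
#' @param records A phenotype-record data frame with columns `n_evaluated`
#'   and `n_fertile` (and optionally `n_planted`).
#' @return The input as a tibble with `hmf_pct` (NA when unevaluable) and
#'   `unevaluable` columns.
#' @examples
#' compute_hmf(tibble::tibble(
#'   genotype = "N525", n_evaluated = 50, n_fertile = 45
#' ))
#' @export
compute_hmf <- function(records) {
  records <- as_tibble(records)
  required <- c("n_evaluated", "n_fertile")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("`records` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  validate_counts(records)
  dplyr::mutate(
    records,
    unevaluable = .data$n_evaluated == 0,
    hmf_pct = dplyr::if_else(
      .data$n_evaluated > 0,
      100 * .data$n_fertile / .data$n_evaluated,
      NA_real_
    )
  )
}

validate_counts <- function(records) {
  label <- if ("genotype" %in% names(records)) records$genotype else seq_len(nrow(records))
  if (!is_count(records$n_evaluated) || !is_count(records$n_fertile)) {
    abort("`n_evaluated` and `n_fertile` must be nonnegative integers.")
  }
  bad <- which(records$n_fertile > records$n_evaluated)
  if (length(bad) > 0) {
    abort(paste0(
      "n_fertile exceeds n_evaluated for record(s): ",
      paste(label[bad], collapse = ", ")
    ))
  }
  if ("n_planted" %in% names(records)) {
    bad <- which(records$n_evaluated > records$n_planted)
    if (length(bad) > 0) {
      abort(paste0(
        "n_evaluated exceeds n_planted for record(s): ",
        paste(label[bad], collapse = ", ")
      ))
    }
  }
  invisible(records)
}

decision_levels <- c(
  "advanced", "below_threshold", "insufficient_seed",
  "control_excluded", "unevaluable"
)

#' Stage-1 threshold selection for one field season
#'
#' Applies the inclusive observed-HMF rule to one year of phenotype records:
#' a record passes when its HMF is at least `threshold_pct`. Controls are
#' scored and counted in the passing tally (the yearly "exceeded the
#' threshold" bookkeeping traditionally includes the positive control) but
#' are never advanced; passing entries advance only when haploid seed is
#' available (`seed_available` column, assumed available when absent — see
#' [apply_seed_availability()] to resolve availability from a separate map).
#'
#' Every record receives exactly one decision `reason`: `advanced`,
#' `below_threshold`, `insufficient_seed`, `control_excluded` or
#' `unevaluable`.
#'
#' @param records Phenotype records for a single year (columns `genotype`,
#'   `n_evaluated`, `n_fertile`; optional `year`, `role`, `seed_available`).
#' @param threshold_pct Advancement threshold as a percentage; default 25.
#' @return A `stage1_decisions` tibble: the input columns plus `hmf_pct`,
#'   `passed_threshold`, `advanced` and `reason`. Summary counts are
#'   available through [glance()].
#' @examples
#' recs <- tibble::tibble(
#'   genotype = c("A", "B"), n_evaluated = 50, n_fertile = c(20, 5)
#' )
#' glance(stage1_select(recs))
#' @export
stage1_select <- function(records, threshold_pct = 25) {
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1L ||
    threshold_pct <= 0 || threshold_pct >= 100) {
    abort("`threshold_pct` must be a single percentage in (0, 100).")
  }
  records <- compute_hmf(records)
  if (!"role" %in% names(records)) records$role <- "entry"
  if (!"year" %in% names(records)) records$year <- NA_integer_
  if (!"seed_available" %in% names(records)) records$seed_available <- TRUE
  bad_role <- setdiff(unique(records$role), c("entry", "positive_control", "negative_control"))
  if (length(bad_role) > 0) {
    abort(paste0("Unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (dplyr::n_distinct(records$year) > 1) {
    abort("`stage1_select()` expects records from a single year; see `simulate_multiyear()`/`stability_metrics()` for multi-year data.")
  }
  dup <- unique(records$genotype[duplicated(records$genotype)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate genotype(s) within the year: ", paste(dup, collapse = ", ")))
  }

  out <- dplyr::mutate(
    records,
    passed_threshold = !.data$unevaluable & .data$hmf_pct >= threshold_pct,
    advanced = .data$passed_threshold & .data$role == "entry" & .data$seed_available,
    reason = dplyr::case_when(
      .data$unevaluable ~ "unevaluable",
      !.data$passed_threshold ~ "below_threshold",
      .data$role != "entry" ~ "control_excluded",
      !.data$seed_available ~ "insufficient_seed",
      TRUE ~ "advanced"
    )
  )
  out$reason <- factor(out$reason, levels = decision_levels)
  new_stage1_decisions(out, threshold_pct)
}

new_stage1_decisions <- function(x, threshold_pct) {
  class(x) <- c("stage1_decisions", setdiff(class(x), "stage1_decisions"))
  attr(x, "threshold_pct") <- threshold_pct
  x
}

#' Summarize stage-1 decisions
#'
#' One-row bookkeeping for a [stage1_select()] result: records scored,
#' records passing the threshold (controls included, matching the
#' conventional yearly tally), entries advanced, entries held back for seed,
#' and unevaluable records.
#'
#' @param x A `stage1_decisions` tibble.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @method glance stage1_decisions
#' @export
glance.stage1_decisions <- function(x, ...) {
  tibble(
    year = x$year[1],
    threshold_pct = attr(x, "threshold_pct"),
    n_records = nrow(x),
    n_evaluable = sum(!x$unevaluable),
    n_passing = sum(x$passed_threshold),
    n_controls_passing = sum(x$passed_threshold & x$role != "entry"),
    n_advanced = sum(x$advanced),
    n_insufficient_seed = sum(x$reason == "insufficient_seed"),
    top_hmf_pct = if (any(!x$unevaluable)) max(x$hmf_pct, na.rm = TRUE) else NA_real_
  )
}

#' @export
print.stage1_decisions <- function(x, ...) {
  s <- glance(x)
  cat(sprintf(
    "<stage1_decisions> year %s: %d records, %d at >=%.0f%% HMF (%d control), %d advanced, %d seed-limited\n",
    as.character(s$year), s$n_records, s$n_passing, s$threshold_pct,
    s$n_controls_passing, s$n_advanced, s$n_insufficient_seed
  ))
  NextMethod()
}

#' Resolve advancement against a haploid seed-availability map
#'
#' Stage-1 qualifiers can only be advanced when enough haploid seed exists
#' for a confirmatory planting. This re-resolves the `advanced` flag and
#' `reason` of a [stage1_select()] result against an explicit availability
#' map; passing entries missing from the map are treated as unavailable, with
#' a warning.
#'
#' @param decisions A `stage1_decisions` tibble.
#' @param availability Either `NULL` (keep the `seed_available` column already
#'   in `decisions`), a named logical vector keyed by genotype, or a data
#'   frame with columns `genotype` and `seed_available`.
#' @return The decisions with `seed_available`, `advanced` and `reason`
#'   updated.
#' @export
apply_seed_availability <- function(decisions, availability = NULL) {
  if (!inherits(decisions, "stage1_decisions")) {
    abort("`decisions` must come from `stage1_select()`.")
  }
  if (!is.null(availability)) {
    if (is.data.frame(availability)) {
      if (!all(c("genotype", "seed_available") %in% names(availability))) {
        abort("`availability` data frame needs columns `genotype` and `seed_available`.")
      }
      avail <- rlang::set_names(availability$seed_available, availability$genotype)
    } else if (is.logical(availability) && !is.null(names(availability))) {
      avail <- availability
    } else {
      abort("`availability` must be NULL, a named logical vector, or a data frame.")
    }
    known <- decisions$genotype %in% names(avail)
    unresolved <- decisions$passed_threshold & decisions$role == "entry" & !known
    if (any(unresolved)) {
      warn(paste0(
        "No seed-availability entry for passing genotype(s), treated as unavailable: ",
        paste(decisions$genotype[unresolved], collapse = ", ")
      ))
    }
    decisions$seed_available <- ifelse(known, unname(avail[decisions$genotype]), FALSE)
  }
  decisions <- dplyr::mutate(
    decisions,
    advanced = .data$passed_threshold & .data$role == "entry" & .data$seed_available,
    reason = dplyr::case_when(
      .data$unevaluable ~ "unevaluable",
      !.data$passed_threshold ~ "below_threshold",
      .data$role != "entry" ~ "control_excluded",
      !.data$seed_available ~ "insufficient_seed",
      TRUE ~ "advanced"
    )
  )
  decisions$reason <- factor(decisions$reason, levels = decision_levels)
  new_stage1_decisions(decisions, attr(decisions, "threshold_pct"))
}

#' Stage-2 confirmatory evaluation
#'
#' Scores the confirmatory (larger, targeted) planting of advanced genotypes
#' against the same inclusive threshold — or a stricter one, since stage 2
#' traditionally focuses on genotypes holding above 30% — and reports the
#' change from the stage-1 estimate when a baseline is supplied.
#'
#' @param records Stage-2 phenotype records (one year).
#' @param threshold_pct Confirmation threshold as a percentage; default 25.
#' @param stage1 Optional `stage1_decisions` from the qualifying year; used
#'   to flag genotypes that were never advanced (processed anyway, with a
#'   warning) and to compute the stage-1 to stage-2 HMF delta.
#' @return A tibble with `genotype`, `year`, `hmf_pct`, `confirmed`, and —
#'   when `stage1` is given — `hmf_stage1` and `delta_hmf`.
#' @export
stage2_confirm <- function(records, threshold_pct = 25, stage1 = NULL) {
  records <- compute_hmf(records)
  if (!"year" %in% names(records)) records$year <- NA_integer_
  if (nrow(records) == 0) {
    return(tibble(
      genotype = character(), year = integer(), hmf_pct = numeric(),
      confirmed = logical()
    ))
  }
  out <- dplyr::transmute(
    records,
    genotype = .data$genotype,
    year = .data$year,
    hmf_pct = .data$hmf_pct,
    confirmed = !.data$unevaluable & .data$hmf_pct >= threshold_pct
  )
  if (!is.null(stage1)) {
    if (!inherits(stage1, "stage1_decisions")) {
      abort("`stage1` must come from `stage1_select()`.")
    }
    not_advanced <- setdiff(out$genotype, stage1$genotype[stage1$advanced | stage1$role != "entry"])
    if (length(not_advanced) > 0) {
      warn(paste0(
        "Stage-2 record(s) for genotype(s) not advanced at stage 1 (processed anyway): ",
        paste(not_advanced, collapse = ", ")
      ))
    }
    baseline <- dplyr::select(as_tibble(stage1), "genotype", hmf_stage1 = "hmf_pct")
    out <- dplyr::left_join(out, baseline, by = "genotype")
    no_baseline <- is.na(out$hmf_stage1)
    if (any(no_baseline)) {
      warn(paste0(
        "No stage-1 baseline for genotype(s), delta omitted: ",
        paste(out$genotype[no_baseline], collapse = ", ")
      ))
    }
    out$delta_hmf <- out$hmf_pct - out$hmf_stage1
  }
  out
}
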