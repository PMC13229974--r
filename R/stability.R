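#' Multi-year stability of haploid male fertility
#'
#' A genotype is a credible donor only if its fertility holds up across
#' seasons: sporadic high HMF usually reflects genotype-by-environment
#' interaction rather than heritable doubling ability. This summarises
#' multi-year phenotype records into per-genotype trajectories, a
#' retained-all-years classification (HMF at or above the threshold in every
#' evaluated year), and pairwise between-year Pearson correlations over the
#' genotypes shared by each year pair.
#'
#' Year pairs sharing fewer than 3 evaluated genotypes, or with zero HMF
#' variance in either year, have their correlation omitted with a warning
#' rather than reported as a spurious number.
#'
#' @param records Phenotype records spanning one or more years (columns
#'   `genotype`, `year`, `n_evaluated`, `n_fertile`).
#' @param threshold_pct Retention threshold as a percentage; default 25.
#' @return An object of class `stability_report` with components
#'   `genotypes` (one row per genotype: `n_years`, `min_hmf`, `mean_hmf`,
#'   `retained_all_years`, and one `hmf_<year>` column per year),
#'   `trajectories` (long genotype-year HMF), and `correlations`
#'   (`year_a`, `year_b`, `r`, `p_value`, `n_shared`). [tidy()] returns the
#'   trajectories, [glance()] the correlations, and [autoplot()] draws the
#'   year-to-year progression.
#' @examples
#' recs <- tibble::tibble(
#'   genotype = rep(c("A", "B", "C"), each = 2),
#'   year = rep(2022:2023, 3),
#'   n_evaluated = 50,
#'   n_fertile = c(30, 25, 10, 12, 20, 18)
#' )
#' stability_metrics(recs)
#' @export
stability_metrics <- function(records, threshold_pct = 25) {
  records <- compute_hmf(records)
  if (!all(c("genotype", "year") %in% names(records))) {
    abort("`records` must have `genotype` and `year` columns.")
  }
  traj <- dplyr::arrange(
    dplyr::select(
      dplyr::filter(records, !.data$unevaluable),
      "genotype", "year", "hmf_pct"
    ),
    .data$genotype, .data$year
  )
  if (anyDuplicated(traj[c("genotype", "year")]) > 0) {
    abort("Multiple records for the same genotype-year; aggregate counts first.")
  }

  genotypes <- dplyr::summarise(
    dplyr::group_by(traj, .data$genotype),
    n_years = dplyr::n(),
    min_hmf = min(.data$hmf_pct),
    mean_hmf = mean(.data$hmf_pct),
    retained_all_years = all(.data$hmf_pct >= threshold_pct),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    traj,
    names_from = "year", values_from = "hmf_pct", names_prefix = "hmf_"
  )
  genotypes <- dplyr::left_join(genotypes, wide, by = "genotype")

  years <- sort(unique(traj$year))
  correlations <- year_pair_correlations(traj, years)

  structure(
    list(
      genotypes = genotypes,
      trajectories = traj,
      correlations = correlations,
      threshold_pct = threshold_pct,
      years = years
    ),
    class = "stability_report"
  )
}

year_pair_correlations <- function(traj, years) {
  empty <- tibble(
    year_a = years[0], year_b = years[0],
    r = numeric(), p_value = numeric(), n_shared = integer()
  )
  if (length(years) < 2) {
    return(empty)
  }
  pairs <- utils::combn(years, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pair) {
    a <- dplyr::filter(traj, .data$year == pair[1])
    b <- dplyr::filter(traj, .data$year == pair[2])
    shared <- dplyr::inner_join(a, b, by = "genotype", suffix = c("_a", "_b"))
    if (nrow(shared) < 3) {
      warn(sprintf(
        "Correlation %s-%s omitted: only %d shared genotype(s).",
        as.character(pair[1]), as.character(pair[2]), nrow(shared)
      ))
      return(NULL)
    }
    if (sd(shared$hmf_pct_a) == 0 || sd(shared$hmf_pct_b) == 0) {
      warn(sprintf(
        "Correlation %s-%s omitted: zero HMF variance in one year.",
        as.character(pair[1]), as.character(pair[2])
      ))
      return(NULL)
    }
    ct <- pearson_r(shared$hmf_pct_a, shared$hmf_pct_b)
    tibble(
      year_a = pair[1], year_b = pair[2],
      r = ct$r, p_value = ct$p_value, n_shared = nrow(shared)
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %d genotypes over %d year(s); %d retained at >=%.0f%% HMF every evaluated year\n",
    nrow(x$genotypes), length(x$years),
    sum(x$genotypes$retained_all_years), x$threshold_pct
  ))
  if (nrow(x$correlations) > 0) {
    cat("Between-year Pearson correlations:\n")
    print(as.data.frame(x$correlations), row.names = FALSE)
  }
  invisible(x)
}

#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$trajectories

#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble(
    n_genotypes = nrow(x$genotypes),
    n_years = length(x$years),
    n_retained = sum(x$genotypes$retained_all_years),
    mean_r = if (nrow(x$correlations) > 0) mean(x$correlations$r) else NA_real_
  )
}

#' Plot year-to-year HMF trajectories
#'
#' One line per genotype across evaluated years, with the retention
#' threshold drawn as a dashed reference — the standard way to eyeball which
#' qualifiers hold their fertility and which ones were one-season wonders.
#'
#' @param object A `stability_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(
    object$trajectories,
    ggplot2::aes(
      x = .data$year, y = .data$hmf_pct,
      group = .data$genotype, colour = .data$genotype
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = object$threshold_pct,
      linetype = "dashed", colour = "orange3"
    ) +
    ggplot2::labs(x = "Year", y = "HMF (%)", colour = "Genotype") +
    ggplot2::theme_minimal()
}
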