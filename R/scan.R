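#' Scan operating characteristics over sample sizes and thresholds
#'
#' Computes the four design metrics — detection probability and false-negative
#' rate at the high-class reference fertility, false-positive rate at the
#' low-class reference, and true discovery rate under the prior — for every
#' combination of kernel count and observed-HMF threshold. The result is the
#' table behind the usual design curves: detection and TDR falling as the
#' threshold rises, and sample size buying back sensitivity.
#'
#' @param n_kernels Integer vector of kernels planted per genotype;
#'   default `c(25, 50, 75)`.
#' @param thresholds Numeric vector of observed-fraction thresholds in (0, 1);
#'   default `seq(0.10, 0.70, by = 0.05)`.
#' @param prior An [hmf_prior()]; supplies the class reference points and the
#'   mixture weight for the TDR column.
#' @param integration Passed to [true_discovery_rate()];
#'   default `"reference_points"`.
#' @param germination_rate,roguing_rate,adjust_n,rounding_rule Passed to
#'   [screening_scenario()] for every grid point.
#' @return A tibble of class `design_scan`, one row per (n, threshold)
#'   combination ordered by kernel count then threshold, with columns
#'   `n_kernels`, `n_evaluated`, `threshold`, `k_min`, `p_detect`, `fnr`,
#'   `fpr`, `tdr`.
#' @examples
#' scan <- threshold_scan()
#' dplyr::filter(scan, threshold == 0.25)
#' @export
threshold_scan <- function(n_kernels = c(25L, 50L, 75L),
                           thresholds = seq(0.10, 0.70, by = 0.05),
                           prior = hmf_prior(),
                           integration = "reference_points",
                           germination_rate = 0.80,
                           roguing_rate = 0.05,
                           adjust_n = FALSE,
                           rounding_rule = "ceil_geq") {
  if (length(n_kernels) == 0 || length(thresholds) == 0) {
    abort("`n_kernels` and `thresholds` must be nonempty.")
  }
  stopifnot(inherits(prior, "hmf_prior"))
  grid <- tidyr::expand_grid(
    n_kernels = sort(unique(as.integer(n_kernels))),
    threshold = sort(unique(thresholds))
  )
  rows <- purrr::pmap(grid, function(n_kernels, threshold) {
    sc <- screening_scenario(
      n_kernels,
      germination_rate = germination_rate, roguing_rate = roguing_rate,
      threshold = threshold, adjust_n = adjust_n, rounding_rule = rounding_rule
    )
    n_eval <- effective_n(sc)
    tibble(
      n_kernels = n_kernels,
      n_evaluated = n_eval,
      threshold = threshold,
      k_min = min_count_for_threshold(n_eval, threshold, rounding_rule),
      p_detect = detection_probability(sc, prior$p_high_ref),
      fnr = false_negative_rate(sc, prior$p_high_ref),
      fpr = false_positive_rate(sc, prior$p_low_ref),
      tdr = true_discovery_rate(sc, prior, integration = integration)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("design_scan", class(out))
  attr(out, "prior") <- prior
  out
}

#' Pick the cheapest design meeting sensitivity and specificity constraints
#'
#' Filters a design scan to rows with detection probability at least
#' `min_detect` and false-positive rate at most `max_fpr`, then returns the
#' row with the smallest kernel count, breaking ties toward the largest
#' (most selective) threshold.
#'
#' @param scan A table produced by [threshold_scan()].
#' @param min_detect Minimum acceptable detection probability; default 0.75.
#' @param max_fpr Maximum acceptable false-positive rate; default 0.05.
#' @return A one-row tibble, or a zero-row tibble (with a warning and
#'   attribute `feasible = FALSE`) when no grid point satisfies both
#'   constraints.
#' @examples
#' recommend_design(threshold_scan())
#' @export
recommend_design <- function(scan, min_detect = 0.75, max_fpr = 0.05) {
  if (!is.data.frame(scan) || nrow(scan) == 0) abort("`scan` must be a nonempty design table.")
  check_probability(min_detect, "min_detect")
  check_probability(max_fpr, "max_fpr")
  ok <- dplyr::filter(scan, .data$p_detect >= min_detect, .data$fpr <= max_fpr)
  if (nrow(ok) == 0) {
    warn("No feasible design: no grid point meets both constraints.")
    out <- dplyr::slice(as_tibble(scan), 0)
    attr(out, "feasible") <- FALSE
    return(out)
  }
  out <- dplyr::slice(
    dplyr::arrange(as_tibble(ok), .data$n_kernels, dplyr::desc(.data$threshold)),
    1
  )
  attr(out, "feasible") <- TRUE
  out
}

#' Monte-Carlo estimate of design operating characteristics
#'
#' Simulates the screen instead of evaluating it analytically: genotypes are
#' drawn from each prior class, fertile counts are binomial in the evaluated
#' plant number, and the threshold rule is applied. Useful as an independent
#' check on the exact calculator and as the natural route for priors without
#' closed-form class averages.
#'
#' @param scenario A [screening_scenario()].
#' @param prior An [hmf_prior()]; true fertilities are drawn from its class
#'   distributions.
#' @param n_genotypes_per_class Genotypes simulated per class per replicate;
#'   default 1.
#' @param n_reps Number of replicates; the total draws per class are
#'   `n_genotypes_per_class * n_reps`. Default 10000.
#' @param seed RNG seed; required for a reproducible estimate.
#' @return A one-row tibble with the empirical `p_detect`, `fnr`, `fpr`,
#'   `tdr`, binomial-proportion standard errors `se_p_detect`, `se_fnr`,
#'   `se_fpr`, a replicate-spread `se_tdr` (NA when `n_reps` is 1), and the
#'   per-class draw count `n_per_class`.
#' @examples
#' monte_carlo_metrics(
#'   screening_scenario(50),
#'   hmf_prior(low = 0.10, high = 0.30),
#'   seed = 1
#' )
#' @export
monte_carlo_metrics <- function(scenario, prior,
                                n_genotypes_per_class = 1L,
                                n_reps = 10000L,
                                seed = NULL) {
  stopifnot(inherits(scenario, "screening_scenario"), inherits(prior, "hmf_prior"))
  if (!is_count(n_reps) || n_reps < 1) abort("`n_reps` must be a positive integer.")
  if (!is_count(n_genotypes_per_class) || n_genotypes_per_class < 1) {
    abort("`n_genotypes_per_class` must be a positive integer.")
  }
  n_eval <- effective_n(scenario)
  k_min <- min_count_for_threshold(n_eval, scenario$threshold, scenario$rounding_rule)
  n_total <- as.integer(n_genotypes_per_class) * as.integer(n_reps)

  sim <- with_seed_if(seed, {
    p_high <- sample_class_p(prior$high_dist, n_total)
    p_low <- sample_class_p(prior$low_dist, n_total)
    list(
      pass_high = rbinom(n_total, n_eval, p_high) >= k_min,
      pass_low = rbinom(n_total, n_eval, p_low) >= k_min
    )
  })

  d_hat <- mean(sim$pass_high)
  fpr_hat <- mean(sim$pass_low)
  tdr_hat <- empirical_tdr(prior, d_hat, fpr_hat)
  se_prop <- function(p) sqrt(p * (1 - p) / n_total)

  se_tdr <- NA_real_
  if (n_reps > 1) {
    rep_id <- rep(seq_len(n_reps), each = n_genotypes_per_class)
    tdr_reps <- purrr::map_dbl(split(seq_len(n_total), rep_id), function(i) {
      empirical_tdr(prior, mean(sim$pass_high[i]), mean(sim$pass_low[i]))
    })
    tdr_reps <- tdr_reps[is.finite(tdr_reps)]
    if (length(tdr_reps) > 1) se_tdr <- sd(tdr_reps) / sqrt(length(tdr_reps))
  }

  tibble(
    n_evaluated = n_eval,
    threshold = scenario$threshold,
    k_min = k_min,
    p_detect = d_hat,
    fnr = 1 - d_hat,
    fpr = fpr_hat,
    tdr = tdr_hat,
    se_p_detect = se_prop(d_hat),
    se_fnr = se_prop(d_hat),
    se_fpr = se_prop(fpr_hat),
    se_tdr = se_tdr,
    n_per_class = n_total
  )
}

empirical_tdr <- function(prior, d_hat, fpr_hat) {
  den <- prior$pi_high * d_hat + prior$pi_low * fpr_hat
  if (den == 0) {
    return(NA_real_)
  }
  prior$pi_high * d_hat / den
}

#' Plot design operating-characteristic curves
#'
#' Renders a [threshold_scan()] table as metric-versus-threshold curves, one
#' line per kernel count and one facet per metric, with a reference line at
#' the conventional 25% operating threshold.
#'
#' @param object A `design_scan` table.
#' @param metrics Which metric columns to facet; default all four.
#' @param ref_threshold Vertical reference line; default 0.25, `NULL` to omit.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot design_scan
#' @export
autoplot.design_scan <- function(object,
                                 metrics = c("p_detect", "fnr", "fpr", "tdr"),
                                 ref_threshold = 0.25, ...) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = metrics, labels = toupper(metrics))
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$threshold, y = .data$value,
      colour = factor(.data$n_kernels), group = .data$n_kernels
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "Observed-HMF threshold", y = NULL,
      colour = "Kernels per genotype"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(ref_threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = ref_threshold, linetype = "dashed", colour = "red3")
  }
  p
}
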