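#' Draw a panel of true fertility probabilities
#'
#' Samples each genotype's latent per-plant fertility from a two-class
#' [hmf_prior()]: class membership with weights `(pi_low, pi_high)`, then the
#' fertility probability from the class distribution. This is the "truth"
#' layer of the synthetic panel; field observation noise is added by
#' [simulate_panel_year()].
#'
#' @param prior An [hmf_prior()].
#' @param n_genotypes Number of genotypes to draw.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `genotype`, `class` (`"low"`/`"high"`) and
#'   `p_true`.
#' @examples
#' sample_true_hmf(hmf_prior(), 5, seed = 1)
#' @export
sample_true_hmf <- function(prior, n_genotypes, seed = NULL) {
  stopifnot(inherits(prior, "hmf_prior"))
  if (!is_count(n_genotypes) || length(n_genotypes) != 1L || n_genotypes < 1) {
    abort("`n_genotypes` must be a single positive integer.")
  }
  with_seed_if(seed, {
    is_high <- runif(n_genotypes) < prior$pi_high
    p <- numeric(n_genotypes)
    p[is_high] <- sample_class_p(prior$high_dist, sum(is_high))
    p[!is_high] <- sample_class_p(prior$low_dist, sum(!is_high))
    tibble(
      genotype = sprintf("G%05d", seq_len(n_genotypes)),
      class = ifelse(is_high, "high", "low"),
      p_true = p
    )
  })
}

# Year-specific fertility: normal perturbation on the logit scale, with
# structural zeros and ones preserved (a genotype that cannot shed pollen does
# not start doing so because of a good year).
perturb_fertility <- function(p, year_effect_sd) {
  if (year_effect_sd == 0) {
    return(p)
  }
  interior <- p > 0 & p < 1
  out <- p
  out[interior] <- plogis(qlogis(p[interior]) + rnorm(sum(interior), 0, year_effect_sd))
  out
}

#' Simulate one field season of stage-1 phenotype records
#'
#' Generates the observation layer for one year: kernels germinate
#' binomially, a fraction of emerged seedlings are rogued as misclassified
#' diploids, the genotype's fertility is perturbed on the logit scale by a
#' genotype-by-year effect, and the fertile-plant count among the remaining
#' evaluated haploids is binomial. Records follow the standard phenotype-table
#' schema, so simulated panels feed straight into [stage1_select()] and
#' friends.
#'
#' @param panel A true panel from [sample_true_hmf()] (columns `genotype`,
#'   `p_true`; `class` carried through if present).
#' @param scenario A [screening_scenario()]; supplies kernels planted and the
#'   germination rate.
#' @param year Year label for the records; default `2022L`.
#' @param year_effect_sd Standard deviation of the genotype-by-year
#'   perturbation on the logit scale; default 0.5, use 0 for a
#'   sampling-noise-only panel.
#' @param diploid_contamination_rate Fraction of emerged seedlings rogued as
#'   diploids; defaults to the scenario's `roguing_rate`.
#' @param seed Optional RNG seed.
#' @return A tibble of phenotype records: `genotype`, `year`, `role`,
#'   `n_planted`, `n_evaluated`, `n_fertile`, `seed_available`, plus the
#'   truth columns `class` and `p_true` and the realized `p_year`.
#' @examples
#' panel <- sample_true_hmf(hmf_prior(), 20, seed = 1)
#' simulate_panel_year(panel, screening_scenario(50), seed = 2)
#' @export
simulate_panel_year <- function(panel, scenario, year = 2022L,
                                year_effect_sd = 0.5,
                                diploid_contamination_rate = NULL,
                                seed = NULL) {
  stopifnot(inherits(scenario, "screening_scenario"))
  if (!is.data.frame(panel) || nrow(panel) == 0) abort("`panel` must be a nonempty data frame.")
  if (!all(c("genotype", "p_true") %in% names(panel))) {
    abort("`panel` must have columns `genotype` and `p_true`.")
  }
  if (!is.numeric(year_effect_sd) || year_effect_sd < 0) {
    abort("`year_effect_sd` must be a nonnegative number.")
  }
  contamination <- diploid_contamination_rate %||% scenario$roguing_rate
  check_probability(contamination, "diploid_contamination_rate")

  n_g <- nrow(panel)
  with_seed_if(seed, {
    germinated <- rbinom(n_g, scenario$n_kernels, scenario$germination_rate)
    rogued <- rbinom(n_g, germinated, contamination)
    evaluated <- germinated - rogued
    p_year <- perturb_fertility(panel$p_true, year_effect_sd)
    fertile <- rbinom(n_g, evaluated, p_year)
    out <- tibble(
      genotype = panel$genotype,
      year = year,
      role = "entry",
      n_planted = scenario$n_kernels,
      n_evaluated = evaluated,
      n_fertile = fertile,
      seed_available = TRUE,
      p_true = panel$p_true,
      p_year = p_year
    )
    if ("class" %in% names(panel)) out$class <- panel$class
    out
  })
}

#' Simulate several seasons of a screening panel
#'
#' Repeats [simulate_panel_year()] for each configured year with independent
#' germination, roguing, year-effect and fertility draws — fresh haploids are
#' induced and planted each season, so nothing is shared across years except
#' the genotype's latent fertility.
#'
#' @inheritParams simulate_panel_year
#' @param years Vector of year labels; default `c(2022L, 2023L, 2024L)`.
#' @param seed Optional RNG seed covering the whole multi-year draw.
#' @return Row-bound per-year records tagged by `year`.
#' @examples
#' panel <- sample_true_hmf(hmf_prior(), 10, seed = 1)
#' simulate_multiyear(panel, screening_scenario(50), years = 2022:2023, seed = 2)
#' @export
simulate_multiyear <- function(panel, scenario,
                               years = c(2022L, 2023L, 2024L),
                               year_effect_sd = 0.5,
                               diploid_contamination_rate = NULL,
                               seed = NULL) {
  if (length(years) == 0) abort("`years` must contain at least one year label.")
  with_seed_if(seed, {
    purrr::map_dfr(years, function(y) {
      simulate_panel_year(
        panel, scenario,
        year = y, year_effect_sd = year_effect_sd,
        diploid_contamination_rate = diploid_contamination_rate,
        seed = NULL
      )
    })
  })
}
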