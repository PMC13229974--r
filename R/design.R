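#' Define a candidate screening scenario
#'
#' A screening scenario fixes the field design knobs for one year of stage-1
#' evaluation: how many haploid kernels are planted per genotype, the expected
#' germination rate, the fraction of emerged seedlings rogued as misclassified
#' diploids, and the observed-fraction threshold used to advance genotypes.
#'
#' The threshold acts on the *observed* haploid male fertility (HMF), the
#' fraction of evaluated haploid plants that shed pollen. With `n` plants
#' evaluated, the event "observed HMF meets the threshold" is discrete; the
#' `rounding_rule` controls how it is discretized:
#'
#' * `"ceil_geq"` (default): pass when the fertile count `X >= ceiling(t * n)`,
#'   i.e. the inclusive rule "observed fraction >= t". This is the field
#'   convention: a genotype sitting exactly at the threshold qualifies.
#' * `"strict_gt"`: pass when `X / n > t`, i.e. `X >= floor(t * n) + 1`.
#'   Exposed because screening programs differ in how they treat the boundary.
#'
#' By default germination and roguing do **not** shrink the evaluated count
#' (`adjust_n = FALSE`): the operating characteristics are then those of
#' `Binomial(n_kernels, p)` sampling, which is how the design curves are
#' usually quoted. Set `adjust_n = TRUE` when planning a real planting, so
#' that probabilities refer to the plants actually left standing after
#' germination loss and diploid roguing.
#'
#' @param n_kernels Positive integer, haploid kernels planted per genotype.
#'   Typical stage-1 grids use 25, 50 or 75.
#' @param germination_rate Proportion in \[0, 1\]; default 0.80.
#' @param roguing_rate Proportion in \[0, 1\] of emerged seedlings removed as
#'   misclassified diploids; default 0.05.
#' @param threshold Observed-HMF cutoff in (0, 1); default 0.25.
#' @param adjust_n Logical; shrink the evaluated count by germination and
#'   roguing? Default `FALSE`.
#' @param rounding_rule `"ceil_geq"` (inclusive, default) or `"strict_gt"`.
#'
#' @return An object of class `screening_scenario`.
#' @examples
#' sc <- screening_scenario(50)
#' detection_probability(sc, p_true = 0.30)
#' @export
screening_scenario <- function(n_kernels,
                               germination_rate = 0.80,
                               roguing_rate = 0.05,
                               threshold = 0.25,
                               adjust_n = FALSE,
                               rounding_rule = c("ceil_geq", "strict_gt")) {
  rounding_rule <- match.arg(rounding_rule)
  if (!is_count(n_kernels) || length(n_kernels) != 1L || n_kernels < 1) {
    abort("`n_kernels` must be a single positive integer.")
  }
  check_probability(germination_rate, "germination_rate")
  check_probability(roguing_rate, "roguing_rate")
  check_probability(threshold, "threshold", open = TRUE)
  if (!is.logical(adjust_n) || length(adjust_n) != 1L || is.na(adjust_n)) {
    abort("`adjust_n` must be TRUE or FALSE.")
  }
  sc <- structure(
    list(
      n_kernels = as.integer(n_kernels),
      germination_rate = germination_rate,
      roguing_rate = roguing_rate,
      threshold = threshold,
      adjust_n = adjust_n,
      rounding_rule = rounding_rule
    ),
    class = "screening_scenario"
  )
  if (effective_n(sc) < 1) abort("Effective evaluated count must be >= 1.")
  sc
}

#' @export
print.screening_scenario <- function(x, ...) {
  cat(sprintf(
    "<screening_scenario> %d kernels, threshold %.0f%% (%s), germination %.0f%%, roguing %.0f%%, adjust_n = %s\n",
    x$n_kernels, 100 * x$threshold, x$rounding_rule,
    100 * x$germination_rate, 100 * x$roguing_rate, x$adjust_n
  ))
  cat(sprintf(
    "  evaluated n = %d, minimum fertile count = %d\n",
    effective_n(x), min_count_for_threshold(effective_n(x), x$threshold, x$rounding_rule)
  ))
  invisible(x)
}

#' Number of plants actually evaluated under a scenario
#'
#' With `adjust_n = FALSE` this is simply the number of kernels planted. With
#' `adjust_n = TRUE` it is `n_kernels * germination_rate * (1 - roguing_rate)`,
#' rounded half-up to the nearest integer and floored at 1 — the expected
#' number of true haploids left standing for fertility scoring.
#'
#' @param scenario A [screening_scenario()].
#' @return A positive integer.
#' @examples
#' effective_n(screening_scenario(50, adjust_n = TRUE)) # 38
#' @export
effective_n <- function(scenario) {
  stopifnot(inherits(scenario, "screening_scenario"))
  if (!scenario$adjust_n) {
    return(scenario$n_kernels)
  }
  n <- scenario$n_kernels * scenario$germination_rate * (1 - scenario$roguing_rate)
  max(1L, as.integer(floor(n + 0.5)))
}

#' Upper tail of the binomial distribution
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, the workhorse of every operating
#' characteristic here: a genotype with true per-plant fertility `p` passes an
#' observed-count cutoff `k` out of `n` with exactly this probability.
#' Evaluated through the regularized incomplete beta function
#' (via [stats::pbinom()]), which equals the direct summation
#' `sum(choose(n, x) p^x (1-p)^(n-x))` over `x = k..n`.
#'
#' @param n Positive integer, number of plants evaluated.
#' @param p Per-plant fertility probability in \[0, 1\].
#' @param k Nonnegative integer cutoff, `0 <= k <= n + 1` (`k = 0` gives 1,
#'   `k = n + 1` gives 0).
#' @return `P(X >= k)`, vectorized over `p`.
#' @examples
#' binomial_tail_geq(25, 0.3, 7) # about 0.659
#' @export
binomial_tail_geq <- function(n, p, k) {
  if (!is_count(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a single positive integer.")
  }
  if (!is_count(k) || length(k) != 1L || k > n + 1) {
    abort("`k` must be a single integer in 0..n+1.")
  }
  check_probability(p, "p")
  if (k == 0) {
    return(rep(1, length(p)))
  }
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Minimum fertile count implied by an observed-fraction threshold
#'
#' Converts the continuous rule "observed HMF meets threshold `t`" into the
#' equivalent count rule on `X` fertile plants out of `n` evaluated. Under the
#' inclusive rule (`"ceil_geq"`) the event `{X/n >= t}` is exactly
#' `{X >= ceiling(t * n)}`; under `"strict_gt"` the event `{X/n > t}` is
#' `{X >= floor(t * n) + 1}`.
#'
#' @param n_evaluated Positive integer.
#' @param threshold Proportion in (0, 1).
#' @param rounding_rule `"ceil_geq"` (default) or `"strict_gt"`.
#' @return A nonnegative integer count.
#' @examples
#' min_count_for_threshold(25, 0.25) # 7
#' min_count_for_threshold(50, 0.25) # 13
#' @export
min_count_for_threshold <- function(n_evaluated, threshold,
                                    rounding_rule = c("ceil_geq", "strict_gt")) {
  rounding_rule <- match.arg(rounding_rule)
  if (!is_count(n_evaluated) || any(n_evaluated < 1)) {
    abort("`n_evaluated` must be a positive integer.")
  }
  check_probability(threshold, "threshold", open = TRUE)
  if (rounding_rule == "ceil_geq") {
    fuzzy_ceiling(threshold * n_evaluated)
  } else {
    fuzzy_floor(threshold * n_evaluated) + 1L
  }
}

#' Probability that a genotype passes the stage-1 threshold
#'
#' For a genotype with true per-plant fertility `p_true`, the fertile count
#' among the evaluated plants is binomial, and the genotype passes when the
#' observed fraction meets the scenario threshold. This is the screen's
#' sensitivity when evaluated at a truly-high fertility value and its
#' false-positive rate when evaluated at a truly-low one.
#'
#' @param scenario A [screening_scenario()].
#' @param p_true True per-plant fertility probability (vectorized).
#' @return Probability of passing, in \[0, 1\].
#' @examples
#' detection_probability(screening_scenario(50), 0.30) # about 0.78
#' @export
detection_probability <- function(scenario, p_true) {
  stopifnot(inherits(scenario, "screening_scenario"))
  check_probability(p_true, "p_true")
  n <- effective_n(scenario)
  k <- min_count_for_threshold(n, scenario$threshold, scenario$rounding_rule)
  binomial_tail_geq(n, p_true, k)
}

#' False-negative rate: discarding a truly high-HMF genotype
#'
#' The probability that a genotype whose true fertility is `p_true` (by
#' default the high-class boundary, 0.30) fails the observed-fraction
#' threshold and is discarded at stage 1. Exactly the complement of
#' [detection_probability()].
#'
#' @inheritParams detection_probability
#' @param p_true True fertility of the high class; default 0.30.
#' @return Probability in \[0, 1\].
#' @export
false_negative_rate <- function(scenario, p_true = 0.30) {
  1 - detection_probability(scenario, p_true)
}

#' False-positive rate: retaining a truly low-HMF genotype
#'
#' The probability that a genotype whose true fertility is `p_true` (by
#' default the low-class boundary, 0.10) nevertheless passes the threshold
#' and is carried into stage 2.
#'
#' @inheritParams detection_probability
#' @param p_true True fertility of the low class; default 0.10.
#' @return Probability in \[0, 1\].
#' @export
false_positive_rate <- function(scenario, p_true = 0.10) {
  detection_probability(scenario, p_true)
}

# ---- fertility prior ---------------------------------------------------------

#' Two-class prior over true haploid male fertility
#'
#' Field panels show a heavily skewed HMF distribution: most genotypes sit in
#' a low class (true fertility at most 10%) and a small fraction in a high
#' class (at least 30%). This prior captures that structure as a two-class
#' mixture with an arbitrary distribution inside each class, and carries the
#' class boundary values (0.10 and 0.30) as the conservative reference points
#' for analytic false-positive / false-negative evaluation.
#'
#' Each class distribution is either a point mass (a single number) or a
#' uniform distribution (a length-2 numeric range). The low-class support must
#' stay within \[0, 0.10\] and the high-class support within \[0.30, 1\].
#'
#' The default mixture weight `pi_high = 47/295` is the empirical high-class
#' fraction of a 295-genotype diversity-panel screen (about 16% of genotypes
#' above 30% HMF); the default class distributions are uniform on \[0, 0.10\]
#' and \[0.30, 0.70\].
#'
#' @param pi_high Prior weight of the high class, in \[0, 1\].
#' @param low Low-class distribution over true fertility: a scalar (point
#'   mass) or a length-2 range (uniform). Default `c(0, 0.10)`.
#' @param high High-class distribution, same conventions. Default
#'   `c(0.30, 0.70)`.
#' @param p_low_ref,p_high_ref Class boundary reference points used for
#'   analytic FPR/FNR; defaults 0.10 and 0.30.
#' @return An object of class `hmf_prior`.
#' @examples
#' hmf_prior() # skewed panel default
#' hmf_prior(pi_high = 0.16, low = 0.10, high = 0.30) # point classes
#' @export
hmf_prior <- function(pi_high = 47 / 295,
                      low = c(0, 0.10),
                      high = c(0.30, 0.70),
                      p_low_ref = 0.10,
                      p_high_ref = 0.30) {
  check_probability(pi_high, "pi_high")
  low <- as_class_dist(low, "low", support = c(0, 0.10))
  high <- as_class_dist(high, "high", support = c(0.30, 1))
  check_probability(p_low_ref, "p_low_ref")
  check_probability(p_high_ref, "p_high_ref")
  structure(
    list(
      pi_low = 1 - pi_high,
      pi_high = pi_high,
      low_dist = low,
      high_dist = high,
      p_low_ref = p_low_ref,
      p_high_ref = p_high_ref
    ),
    class = "hmf_prior"
  )
}

as_class_dist <- function(x, class, support) {
  if (!is.numeric(x) || anyNA(x) || !length(x) %in% 1:2) {
    abort(sprintf("The %s-class distribution must be a scalar or a length-2 range.", class))
  }
  if (any(x < support[1] | x > support[2])) {
    abort(sprintf(
      "The %s-class support must stay within [%.2f, %.2f].",
      class, support[1], support[2]
    ))
  }
  if (length(x) == 1L) {
    list(type = "point", value = x)
  } else {
    if (x[2] < x[1]) abort(sprintf("The %s-class range must be increasing.", class))
    list(type = "uniform", min = x[1], max = x[2])
  }
}

#' @export
print.hmf_prior <- function(x, ...) {
  fmt <- function(d) {
    if (d$type == "point") sprintf("point mass at %.3f", d$value)
    else sprintf("uniform on [%.2f, %.2f]", d$min, d$max)
  }
  cat(sprintf(
    "<hmf_prior> pi_high = %.3f (low: %s; high: %s); reference points %.2f / %.2f\n",
    x$pi_high, fmt(x$low_dist), fmt(x$high_dist), x$p_low_ref, x$p_high_ref
  ))
  invisible(x)
}

# Mean of detection_probability over one class distribution.
class_mean_detection <- function(scenario, dist, integration, n_draws = 10000L) {
  if (dist$type == "point") {
    return(detection_probability(scenario, dist$value))
  }
  switch(integration,
    reference_points = abort("internal: reference_points handled by caller"),
    quadrature = {
      if (dist$min == dist$max) {
        detection_probability(scenario, dist$min)
      } else {
        integrate(
          function(p) detection_probability(scenario, p),
          lower = dist$min, upper = dist$max, rel.tol = 1e-8
        )$value / (dist$max - dist$min)
      }
    },
    monte_carlo = {
      mean(detection_probability(scenario, runif(n_draws, dist$min, dist$max)))
    }
  )
}

sample_class_p <- function(dist, n) {
  if (dist$type == "point") rep(dist$value, n) else runif(n, dist$min, dist$max)
}

#' True discovery rate of the stage-1 screen
#'
#' Among genotypes that pass the threshold, the fraction that are truly
#' high-HMF. Writing `D_H` and `D_L` for the class-averaged probabilities of
#' passing, the TDR is `pi_H D_H / (pi_H D_H + pi_L D_L)` — a posterior
#' probability that depends on the class prior as much as on the design, which
#' is why it is reported alongside (not instead of) detection probability.
#'
#' @param scenario A [screening_scenario()].
#' @param prior An [hmf_prior()].
#' @param integration How to average detection over each class:
#'   `"reference_points"` (evaluate at the class boundaries 0.30 / 0.10, the
#'   conservative default), `"quadrature"` (numeric integration over each
#'   class distribution) or `"monte_carlo"` (sampled average; honours `seed`).
#' @param n_draws Draws per class for `"monte_carlo"`; default 10000.
#' @param seed Optional RNG seed for `"monte_carlo"`.
#' @return The TDR in \[0, 1\]; `NA` (with a warning) when no genotype of
#'   either class can pass, e.g. `pi_high = 0` with a zero false-positive
#'   rate.
#' @examples
#' true_discovery_rate(screening_scenario(50), hmf_prior())
#' @export
true_discovery_rate <- function(scenario, prior,
                                integration = c("reference_points", "quadrature", "monte_carlo"),
                                n_draws = 10000L, seed = NULL) {
  stopifnot(inherits(scenario, "screening_scenario"), inherits(prior, "hmf_prior"))
  integration <- match.arg(integration)
  if (integration == "reference_points") {
    d_high <- detection_probability(scenario, prior$p_high_ref)
    d_low <- detection_probability(scenario, prior$p_low_ref)
  } else {
    d_high <- with_seed_if(seed, class_mean_detection(scenario, prior$high_dist, integration, n_draws))
    d_low <- with_seed_if(seed, class_mean_detection(scenario, prior$low_dist, integration, n_draws))
  }
  num <- prior$pi_high * d_high
  den <- num + prior$pi_low * d_low
  if (den == 0) {
    warn("True discovery rate is undefined: no genotype of either class can pass this design.")
    return(NA_real_)
  }
  num / den
}
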