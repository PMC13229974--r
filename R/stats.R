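#' Entry-mean heritability
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e / n_env)`: the proportion of variance
#' among genotype means attributable to genetics when each genotype is
#' evaluated in `n_env` environments. Residual variance is averaged down by
#' replication across environments, so entry-mean heritability rises with the
#' number of environments even when the underlying variances are fixed.
#'
#' @param sigma2_g Genetic variance component (nonnegative).
#' @param sigma2_e Residual variance component (nonnegative).
#' @param n_env Number of environments (positive integer).
#' @return Heritability in \[0, 1\], vectorized over the inputs.
#' @examples
#' entry_mean_heritability(8, 3, 3) # 8 / (8 + 1)
#' @export
entry_mean_heritability <- function(sigma2_g, sigma2_e, n_env) {
  if (!is.numeric(sigma2_g) || !is.numeric(sigma2_e) ||
    any(sigma2_g < 0) || any(sigma2_e < 0)) {
    abort("Variance components must be nonnegative numbers.")
  }
  if (!is_count(n_env) || any(n_env < 1)) {
    abort("`n_env` must be a positive integer.")
  }
  if (any(sigma2_g == 0 & sigma2_e == 0)) {
    abort("Heritability is undefined when both variance components are zero.")
  }
  sigma2_g / (sigma2_g + sigma2_e / n_env)
}

#' Logit and inverse-logit transforms
#'
#' `logit(p) = log(p / (1 - p))` maps a proportion to the real line;
#' `inv_logit()` is its inverse. Proportion-scale fertility data are usually
#' transformed to the logit scale before variance analysis, and the synthetic
#' panel's year effects act on this scale. `logit()` rejects exact 0 and 1
#' unless a clamp `eps` is supplied, in which case `p` is first squeezed into
#' `[eps, 1 - eps]`.
#'
#' @param p Proportions in \[0, 1\] (strictly inside unless `eps` is given).
#' @param eps Optional clamp half-width for boundary values; default `NULL`
#'   (boundary values are an error).
#' @param x Real numbers.
#' @return `logit()` returns real numbers; `inv_logit()` proportions in
#'   (0, 1).
#' @examples
#' logit(0.25) # log(1/3)
#' inv_logit(0) # 0.5
#' @export
logit <- function(p, eps = NULL) {
  check_probability(p, "p")
  if (!is.null(eps)) {
    if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5) {
      abort("`eps` must be a single number in (0, 0.5).")
    }
    p <- pmin(pmax(p, eps), 1 - eps)
  } else if (any(p == 0 | p == 1)) {
    abort("logit of 0 or 1 is undefined; supply `eps` to clamp boundary values.")
  }
  qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  plogis(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' Thin, validated wrapper around [stats::cor.test()] returning a tidy
#' one-row tibble. The p-value comes from the usual t transform on
#' `length(x) - 2` degrees of freedom. Zero variance in either vector is an
#' error — a correlation of constant data is undefined, not zero.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A tibble with `r`, `p_value`, `n` and `df`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)) # r = 0.6
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    abort("`x` and `y` must be numeric with no missing values.")
  }
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("At least 3 paired observations are required.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for zero-variance input.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x),
    df = unname(ct$parameter)
  )
}
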