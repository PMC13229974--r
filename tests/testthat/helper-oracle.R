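# Independent oracles, kept deliberately naive.

# Direct summation of the binomial pmf over the upper tail.
oracle_tail_sum <- function(n, p, k) {
  if (k <= 0) {
    return(1)
  }
  if (k > n) {
    return(0)
  }
  x <- k:n
  sum(choose(n, x) * p^x * (1 - p)^(n - x))
}

# Brute force: enumerate all 2^n fertile/sterile outcome vectors and add up
# the probability of those with at least k fertile plants. Only viable for
# small n; that is the point.
oracle_tail_enum <- function(n, p, k) {
  outcomes <- expand.grid(rep(list(c(0L, 1L)), n))
  fertile <- rowSums(outcomes)
  prob <- p^fertile * (1 - p)^(n - fertile)
  sum(prob[fertile >= k])
}

# Textbook Pearson correlation, written out.
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

fixture_path <- function() {
  system.file("extdata", "stage1_qualifiers.csv", package = "hmfscreen")
}

# Small handmade record table builder.
make_records <- function(genotype, fertile, evaluated = 50L, year = 2022L,
                         role = "entry", seed_available = TRUE) {
  tibble::tibble(
    genotype = genotype,
    year = year,
    role = role,
    n_planted = evaluated,
    n_evaluated = evaluated,
    n_fertile = fertile,
    seed_available = seed_available
  )
}
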