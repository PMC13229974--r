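Package: hmfscreen
Title: Design and Analysis of Two-Stage Screens for Haploid Male Fertility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing and running two-stage field screens for rare
    binary plant phenotypes, built around haploid male fertility (HMF) as the
    observable proxy for spontaneous haploid genome doubling in maize. Provides
    an exact and Monte-Carlo binomial design calculator (detection probability,
    false-negative and false-positive rates, true discovery rate as functions
    of sample size and observed-fraction threshold), a synthetic genotype-panel
    generator with a skewed two-class fertility mixture, germination loss,
    diploid roguing and logit-scale year effects, a stage-1/stage-2 screening
    pipeline with control handling and seed-availability bookkeeping,
    multi-year stability reports, and small closed-form statistics
    (entry-mean heritability, logit transforms, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
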