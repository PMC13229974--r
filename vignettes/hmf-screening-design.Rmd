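---
title: "Designing and running a two-stage screen for haploid male fertility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and running a two-stage screen for haploid male fertility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmfscreen)
library(dplyr)
```

## The screening problem

Spontaneous haploid genome doubling (SHGD) lets maize breeders produce
doubled-haploid lines without colchicine, but it is a needle-in-a-haystack
trait: in diverse panels, most genotypes show haploid male fertility (HMF)
near zero and well under 10%, while the useful donors sit above 30%. Scoring
HMF means growing out haploid plants and watching for pollen shed, so every
extra plant per genotype is real field cost. A two-stage screen spends little
on each of many genotypes in stage 1, then re-evaluates the few qualifiers
with more plants in stage 2 and across years.

The package answers the design question — how many haploids per genotype, and
what observed-HMF cutoff? — with an exact sampling model, and then runs the
resulting pipeline on phenotype tables.

## The sampling model

For a genotype with true per-plant fertility $p$, the fertile count among $n$
evaluated haploids is

$$X \sim \mathrm{Binomial}(n, p), \qquad \widehat{\mathrm{HMF}} = X / n .$$

A genotype passes stage 1 when $\widehat{\mathrm{HMF}} \ge t$. Because $X$ is
discrete, the rule is equivalent to $X \ge k$ with
$k = \lceil t\,n \rceil$ (the inclusive convention: a genotype observed at
exactly the threshold qualifies, which is how qualifier tables are kept in
practice — a 25% entry is a qualifier under a 25% rule). A strict variant
($X/n > t$, so $k = \lfloor t\,n \rfloor + 1$) is available through
`rounding_rule = "strict_gt"` because programs differ on the boundary, and at
some $(n, t)$ pairs the two rules differ by one plant and visibly move the
false-positive rate.

Everything else is tail arithmetic on this model:

* **Detection probability** at $p$: $P(X \ge k \mid n, p)$ — sensitivity when
  $p$ is a truly-high fertility.
* **False-negative rate**: its complement at the high-class reference
  $p = 0.30$.
* **False-positive rate**: $P(X \ge k \mid n, p)$ at the low-class reference
  $p = 0.10$.
* **True discovery rate** under a two-class prior with high-class weight
  $\pi_H$:
  $\mathrm{TDR} = \pi_H D_H / (\pi_H D_H + \pi_L D_L)$, where $D_H$ and
  $D_L$ are class-averaged passing probabilities.

The tails are evaluated through the regularized incomplete beta function
(`stats::pbinom`), which is exact to machine precision; the test suite checks
it against exhaustive enumeration of all $2^n$ outcomes for small $n$.

```{r operating-points}
scan <- threshold_scan()
filter(scan, threshold == 0.25)
```

At the 25% rule a genotype with $p = 0.30$ is detected with probability
0.659, 0.777 and 0.843 for 25, 50 and 75 plants, while the false-positive
rate at $p = 0.10$ is already below 1% at 25 plants. Raising the sample from
50 to 75 plants buys about seven points of detection; from 25 to 50 it buys
twelve. That is the quantitative case for 50 plants at a 25% threshold as the
stage-1 compromise, which `recommend_design()` recovers as the smallest
design with detection at least 0.75 and false-positive rate at most 0.05:

```{r recommend}
recommend_design(scan, min_detect = 0.75, max_fpr = 0.05)
```

### Class reference points, and what the TDR does not claim

The classes are defined by cutoffs (low below 10%, high above 30%), not by
full distributions. Analytic FNR/FPR are therefore evaluated at the boundary
values 0.10 and 0.30 — the conservative worst case: any low-class genotype
below 0.10 has a smaller FPR, any high-class genotype above 0.30 a smaller
FNR. The TDR additionally needs class weights; the default prior uses
$\pi_H = 47/295 \approx 0.16$, the empirical fraction of a 295-genotype
panel above 30% HMF, with uniform within-class distributions on
$[0, 0.10]$ and $[0.30, 0.70]$. TDR magnitudes are prior-dependent by
construction, so the package treats them as a comparative tool across
designs, not as reproducible absolute numbers; only their monotone behaviour
(in $\pi_H$, in $n$, against threshold) is asserted in tests.

### Germination and roguing

Stage-1 plantings lose plants before scoring: the default expectations are
80% germination and 5% of emerged seedlings rogued as misclassified diploids
(the R1-nj kernel marker is imperfect). By default these do **not** shrink
the evaluated count in the design curves — the published operating points
quote $\mathrm{Binomial}(n, p)$ tails in the planted number, and roguing
removes diploids rather than fertile haploids. For planning a real planting,
`adjust_n = TRUE` evaluates the same characteristics at
$n' = \mathrm{round}(n \times 0.80 \times 0.95)$ (half-up rounding, floored
at one plant; both stock parameter sets give exact integers, so the rounding
convention never changes the default grid).

## The synthetic panel

`sample_true_hmf()` draws a panel's latent fertilities from the two-class
prior; `simulate_panel_year()` adds the observation layer:

1. germination: $\mathrm{Binomial}(n_\text{kernels}, 0.80)$;
2. roguing: a $\mathrm{Binomial}(\cdot, 0.05)$ thinning of emerged seedlings
   (removing diploids, leaving fertility untouched);
3. a genotype-by-year effect on the logit scale:
   $p_y = \mathrm{logit}^{-1}(\mathrm{logit}(p) + e_{gy})$ with
   $e_{gy} \sim N(0, \sigma_y^2)$, structural zeros and ones preserved;
4. the fertile count: $\mathrm{Binomial}(n_\text{evaluated}, p_y)$.

The year effect is the minimal structure consistent with modelling
environment as a random effect on logit-transformed HMF; no scale is
published for it, so the default $\sigma_y = 0.5$ was fixed once as a
realistic genotype-by-year swing (about $\pm 12$ percentage points around
$p = 0.30$ per one SD) and is a plain argument, with $\sigma_y = 0$ giving a
sampling-noise-only panel for analytic cross-checks. Years are independent
given $p$: fresh haploids are induced and planted each season.

What the generator does *not* emulate: genotype-by-year correlation beyond
the independent logit perturbation, any genetic architecture (no loci, no
kinship), spatial field structure, or scoring error in pollen-shed calls.
Tests passing on these panels therefore validate the screening arithmetic
and pipeline bookkeeping, not the biology of any particular germplasm.

```{r simulate}
panel <- sample_true_hmf(hmf_prior(), n_genotypes = 200, seed = 42)
records <- simulate_multiyear(panel, screening_scenario(50),
  years = 2022:2024, seed = 43
)
count(records, year)
```

## The screening pipeline

`stage1_select()` applies the inclusive threshold to one season of records.
Three bookkeeping rules reflect how qualifier tables are kept in the field:

* the yearly "passing" tally includes positive controls (the check belongs
  in the qualifier table, where its HMF benchmarks the season);
* controls are never *advanced* — their decision reason is
  `control_excluded`;
* passing entries advance only when haploid seed is available; the rest are
  `insufficient_seed`. `apply_seed_availability()` re-resolves the flags
  against an explicit availability map.

Every record gets exactly one reason, so reason counts partition the input —
a property the tests assert — and decisions are idempotent: re-selecting a
decision table's records changes no flag.

```{r stage1}
qualifiers <- read_phenotype_table(
  system.file("extdata", "stage1_qualifiers.csv", package = "hmfscreen")
)
dec_2022 <- stage1_select(filter(qualifiers, year == 2022))
glance(dec_2022)
```

`stage2_confirm()` scores the confirmatory planting (the same inclusive
threshold by default; pass a stricter `threshold_pct`, e.g. 30, to focus on
the high-confidence donors) and reports stage-1 to stage-2 deltas.
`stability_metrics()` summarises multi-year data into per-genotype
trajectories, a retained-all-years flag (at or above threshold in *every*
evaluated year), and pairwise between-year Pearson correlations over shared
genotypes — with a correlation omitted, not fabricated, when fewer than
three genotypes are shared or a year has zero variance.

```{r stability}
advanced_2022 <- filter(dec_2022, advanced)$genotype
stab <- stability_metrics(filter(qualifiers, genotype %in% advanced_2022))
stab
```

(With only qualifier-table records, later-year rows exist only for the
recurring check, so most trajectories here are single-year; on full
multi-year data the correlations table is the stability headline.)

## Numerical and degenerate-input choices

* Threshold counts use a $10^{-9}$ fuzz before `ceiling()`/`floor()` so grid
  thresholds such as $0.55 \times 20$ are not tipped over an exact integer by
  floating-point representation.
* `n_evaluated = 0` records are `unevaluable`, carried with `NA` HMF and
  excluded from tallies rather than dropped silently.
* A TDR denominator of zero (nothing in either class can pass) is `NA` with
  a warning, not a crash and not a silent zero.
* `logit()` rejects exact 0/1 unless given a clamp `eps`; the simulator
  instead preserves structural zeros and ones through the year effect.
* Monte-Carlo estimators take an explicit seed and report
  binomial-proportion standard errors (TDR: the spread of per-replicate
  estimates); the suite checks agreement with the exact calculator within
  three standard errors at 10,000 replicates.
* `recommend_design()` under infeasible constraints returns an explicit
  zero-row result with `feasible = FALSE`, because "no design qualifies" is
  an answer, not an error.

One monotonicity subtlety is worth recording: the false-negative rate is
*not* uniformly decreasing in sample size. For thresholds at or above the
true fertility of the high class, more plants make passing less likely (the
screen is then correctly concentrating around a $p$ below the cutoff), and
exactly at $t = p$ the ceiling discretization makes the effective cutoff
fraction wiggle across $n$ (8/25 vs 15/50 vs 23/75). The familiar
"more plants, fewer lost donors" ordering holds below the class boundary,
which is where an operating threshold belongs, and that is the regime the
property tests assert.

## Problem sizes used in validation

The test suite validates the calculator against exhaustive enumeration at
$n \le 12$, Monte-Carlo agreement at 10,000 replicates per class, and
end-to-end synthetic screens of 4,000–5,000 genotypes per class — sizes at
which three-standard-error bands are a few tenths of a percentage point,
chosen as the package's own validation scale. The large-sample consistency
check uses $n = 2000$ plants, where detection at $p = 0.40$ versus
$p = 0.10$ under a 25% rule separates to within 0.01 of its 0/1 limits.

## Limitations

* Plants are assumed exchangeable within a plot; overdispersion relative to
  the binomial (micro-environment, induction-batch effects) would make the
  printed operating characteristics optimistic.
* The class prior is a modelling input; TDR values inherit its uncertainty.
* The pipeline scores fertility as a binary pollen-shed call; anther and
  pollen scores on a graded scale are outside the model.
* Variance components for entry-mean heritability are inputs
  (`entry_mean_heritability()` is a closed form, not a mixed-model fit);
  BLUE estimation and association mapping are deliberately downstream of the
  exported per-genotype phenotype table.
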