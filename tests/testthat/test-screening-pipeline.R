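test_that("observed HMF is the fertile fraction of evaluated plants", {
  recs <- make_records(c("a", "b", "c"), fertile = c(0L, 45L, 10L), evaluated = c(40L, 50L, 40L))
  out <- compute_hmf(recs)
  expect_equal(out$hmf_pct, c(0, 90, 25))
  expect_false(any(out$unevaluable))

  none <- compute_hmf(make_records("z", fertile = 0L, evaluated = 0L))
  expect_true(none$unevaluable)
  expect_true(is.na(none$hmf_pct))

  expect_error(
    compute_hmf(make_records("bad", fertile = 51L, evaluated = 50L)),
    "bad"
  )
  expect_error(
    compute_hmf(tibble::tibble(genotype = "x", n_planted = 10L, n_evaluated = 20L, n_fertile = 1L)),
    "n_planted"
  )
})

test_that("stage-1 selection partitions every record into one decision reason", {
  recs <- dplyr::bind_rows(
    make_records(c("hi", "edge", "lo"), fertile = c(30L, 13L, 5L), evaluated = c(50L, 52L, 50L)),
    make_records("posctl", fertile = 35L, role = "positive_control"),
    make_records("negctl", fertile = 0L, role = "negative_control"),
    make_records("seedless", fertile = 20L, seed_available = FALSE),
    make_records("empty", fertile = 0L, evaluated = 0L)
  )
  dec <- stage1_select(recs, threshold_pct = 25)
  expect_identical(as.character(dec$reason), c(
    "advanced", "advanced", "below_threshold", "control_excluded",
    "below_threshold", "insufficient_seed", "unevaluable"
  ))
  expect_identical(sum(table(dec$reason)), nrow(recs))
  # the boundary case: exactly 25% passes the inclusive rule
  expect_true(dec$passed_threshold[dec$genotype == "edge"])
  # controls pass but never advance
  expect_true(dec$passed_threshold[dec$genotype == "posctl"])
  expect_false(dec$advanced[dec$genotype == "posctl"])
  s <- glance(dec)
  expect_identical(s$n_passing, 4L)
  expect_identical(s$n_controls_passing, 1L)
  expect_identical(s$n_advanced, 2L)

  expect_identical(glance(stage1_select(make_records(c("a", "b"), c(0L, 1L))))$n_passing, 0L)
  expect_error(stage1_select(make_records(c("a", "a"), c(1L, 2L))), "Duplicate")
  expect_error(
    stage1_select(make_records(c("a", "b"), c(1L, 2L), year = c(2022L, 2023L))),
    "single year"
  )
})

test_that("stage-1 selection is idempotent on its own decisions", {
  recs <- dplyr::bind_rows(
    make_records(c("hi", "lo"), fertile = c(30L, 5L)),
    make_records("posctl", fertile = 35L, role = "positive_control"),
    make_records("seedless", fertile = 20L, seed_available = FALSE)
  )
  once <- stage1_select(recs)
  again <- stage1_select(dplyr::select(
    tibble::as_tibble(once),
    dplyr::all_of(names(recs))
  ))
  expect_identical(once$passed_threshold, again$passed_threshold)
  expect_identical(once$advanced, again$advanced)
  expect_identical(once$reason, again$reason)
})

test_that("seed availability maps resolve advancement", {
  recs <- make_records(c("a", "b", "c"), fertile = c(30L, 28L, 26L))
  dec <- stage1_select(recs)
  expect_identical(sum(dec$advanced), 3L)

  resolved <- apply_seed_availability(dec, c(a = TRUE, b = FALSE, c = TRUE))
  expect_identical(resolved$reason[resolved$genotype == "b"], factor("insufficient_seed", levels = levels(dec$reason)))
  expect_identical(sum(resolved$advanced), 2L)

  expect_warning(
    partial <- apply_seed_availability(dec, c(a = TRUE)),
    "treated as unavailable"
  )
  expect_identical(sum(partial$advanced), 1L)

  none <- apply_seed_availability(dec, c(a = FALSE, b = FALSE, c = FALSE))
  expect_identical(sum(none$advanced), 0L)
})

test_that("the packaged qualifier table reproduces the published bookkeeping", {
  records <- read_phenotype_table(fixture_path())
  by_year <- split(records, records$year)

  dec22 <- stage1_select(by_year[["2022"]])
  s22 <- glance(dec22)
  expect_identical(s22$n_records, 11L)
  expect_identical(s22$n_passing, 11L)
  expect_identical(s22$n_advanced, 9L)
  expect_identical(s22$top_hmf_pct, 90)
  expect_identical(dec22$genotype[which.max(dec22$hmf_pct)], "N525")

  dec23 <- stage1_select(by_year[["2023"]])
  s23 <- glance(dec23)
  expect_identical(s23$n_passing, 19L)
  expect_identical(s23$n_advanced, 4L)
  # the returning positive check passes the threshold but is excluded
  expect_identical(
    as.character(dec23$reason[dec23$genotype == "A427"]),
    "control_excluded"
  )

  s24 <- glance(stage1_select(by_year[["2024"]]))
  expect_identical(s24$n_passing, 20L)
})

test_that("stage-2 confirmation reports deltas against the stage-1 baseline", {
  stage1 <- stage1_select(make_records(c("A427", "N525"), fertile = c(345L, 450L), evaluated = 500L))
  stage2 <- make_records(c("A427", "weak"), fertile = c(712L, 150L), evaluated = 750L, year = 2023L)
  warns <- capture_warnings(out <- stage2_confirm(stage2, stage1 = stage1))
  expect_match(warns, "not advanced", all = FALSE)
  expect_match(warns, "baseline", all = FALSE)
  a427 <- out[out$genotype == "A427", ]
  expect_true(a427$confirmed)
  expect_equal(a427$hmf_stage1, 69)
  expect_equal(a427$delta_hmf, 95 - 69, tolerance = 0.05)
  expect_false(out$confirmed[out$genotype == "weak"])
  expect_true(is.na(out$delta_hmf[out$genotype == "weak"]))

  expect_identical(nrow(stage2_confirm(make_records(character(), integer()))), 0L)
  not_confirmed <- stage2_confirm(make_records("x", fertile = 10L, evaluated = 50L))
  expect_false(not_confirmed$confirmed)
})

test_that("stability reports classify retention and between-year correlation", {
  recs <- dplyr::bind_rows(
    make_records("NK778", fertile = c(59L, 42L, 31L), evaluated = 100L, year = 2022:2024),
    make_records("fade", fertile = c(40L, 10L, 5L), evaluated = 100L, year = 2022:2024),
    make_records("low", fertile = c(8L, 12L, 9L), evaluated = 100L, year = 2022:2024),
    make_records("late", fertile = c(30L, 35L), evaluated = 100L, year = 2023:2024)
  )
  rep <- stability_metrics(recs, threshold_pct = 25)
  g <- rep$genotypes
  expect_true(g$retained_all_years[g$genotype == "NK778"])
  expect_false(g$retained_all_years[g$genotype == "fade"])
  expect_identical(g$n_years[g$genotype == "late"], 2L)
  expect_identical(g$min_hmf[g$genotype == "NK778"], 31)
  expect_identical(nrow(rep$correlations), 3L)
  expect_true(all(rep$correlations$r >= -1 & rep$correlations$r <= 1))
  # the 2023-2024 pair shares all four genotypes
  pair <- rep$correlations[rep$correlations$year_a == 2023, ]
  expect_identical(pair$n_shared, 4L)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_identical(nrow(tidy(rep)), 11L)
})

test_that("degenerate stability inputs are flagged, not silently scored", {
  # constant HMF across genotypes: correlation undefined, retention still works
  const <- dplyr::bind_rows(
    make_records(c("a", "b", "c"), fertile = 30L, year = 2022L),
    make_records(c("a", "b", "c"), fertile = 30L, year = 2023L)
  )
  expect_warning(rep <- stability_metrics(const), "zero HMF variance")
  expect_identical(nrow(rep$correlations), 0L)
  expect_true(all(rep$genotypes$retained_all_years))

  # too few shared genotypes
  sparse <- dplyr::bind_rows(
    make_records(c("a", "b"), fertile = c(30L, 20L), year = 2022L),
    make_records(c("a", "b"), fertile = c(25L, 22L), year = 2023L)
  )
  expect_warning(stability_metrics(sparse), "shared genotype")
})

test_that("simulated between-year correlation is positive when true fertility varies", {
  panel <- sample_true_hmf(hmf_prior(pi_high = 0.3), 300, seed = 20)
  sc <- screening_scenario(50)
  recs <- simulate_multiyear(panel, sc, years = 2022:2023, year_effect_sd = 0, seed = 21)
  rep <- stability_metrics(recs)
  expect_gt(rep$correlations$r[1], 0.5)
})

test_that("end-to-end: advancement of high-class genotypes matches exact detection", {
  n_high <- 4000L
  panel <- tibble::tibble(genotype = sprintf("H%05d", 1:n_high), p_true = 0.30)
  sc <- screening_scenario(50, germination_rate = 1, roguing_rate = 0)
  recs <- simulate_panel_year(panel, sc,
    year_effect_sd = 0,
    diploid_contamination_rate = 0, seed = 22
  )
  dec <- stage1_select(recs, threshold_pct = 25)
  frac <- mean(dec$advanced)
  exact <- detection_probability(sc, 0.30)
  se <- sqrt(exact * (1 - exact) / n_high)
  expect_lt(abs(frac - exact), 3 * se)

  # and the low class almost never advances
  low_panel <- tibble::tibble(genotype = sprintf("L%05d", 1:n_high), p_true = 0.10)
  low_recs <- simulate_panel_year(low_panel, sc,
    year_effect_sd = 0,
    diploid_contamination_rate = 0, seed = 23
  )
  low_frac <- mean(stage1_select(low_recs)$advanced)
  exact_fpr <- false_positive_rate(sc, 0.10)
  se_fpr <- sqrt(exact_fpr * (1 - exact_fpr) / n_high)
  expect_lt(abs(low_frac - exact_fpr), 3 * se_fpr + 1e-12)
})
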