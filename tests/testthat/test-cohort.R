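test_that("draw_kinetics is reproducible and honours degenerate designs", {
  d <- cohort_design()
  k1 <- draw_kinetics("full_complement", d, seed = 3)
  k2 <- draw_kinetics("full_complement", d, seed = 3)
  expect_identical(k1$ka, k2$ka)
  expect_identical(k1$kd, k2$kd)
  # zero log-sd: exactly the medians
  d0 <- cohort_design(kinetics = list(
    full_complement = list(median_ka = 5e6, sd_log10_ka = 0,
                           median_kd = 1e-3, sd_log10_kd = 0, rho = 0),
    mismatched = list(median_ka = 5e2, sd_log10_ka = 0,
                      median_kd = 4e-3, sd_log10_kd = 0, rho = 0)))
  k0 <- draw_kinetics("mismatched", d0, seed = 1)
  expect_equal(k0$ka, 5e2)
  expect_equal(k0$kd, 4e-3)
  expect_error(draw_kinetics("nonsense", d, 1))
})

test_that("the class contrast satisfies the >= 1000x median ka ratio", {
  d <- cohort_design()
  ka_full <- vapply(1:2000, function(s)
    draw_kinetics("full_complement", d, seed = s)$ka, numeric(1))
  ka_mis <- vapply(1:2000, function(s)
    draw_kinetics("mismatched", d, seed = 20000 + s)$ka, numeric(1))
  expect_gte(median(ka_full) / median(ka_mis), 1e3)
})

test_that("mass/molar conversion and dilution follow unit arithmetic", {
  # hand arithmetic: 0.13 ng/uL = 0.13e-3 g/L; /(660 * 200 g/mol)
  expect_equal(mass_to_molar(0.13, 200, TRUE), 0.13e-3 / (660 * 200))
  expect_equal(mass_to_molar(0.13, 200, FALSE), 0.13e-3 / (330 * 200))
  expect_equal(mass_to_molar(0, 100), 0)
  expect_equal(mass_to_molar(2, 100), 2 * mass_to_molar(1, 100))
  expect_error(mass_to_molar(-1, 100), "conc")
  expect_error(mass_to_molar(1, 0), "length")
  expect_equal(dilute(25, 200), 0.125)
  expect_equal(round_conc(dilute(25, 200)), 0.13)
  expect_identical(dilute(7, 1), 7)
  expect_equal(dilute(1, 10), 0.1)
  expect_error(dilute(1, 0.5), "factor")
})

test_that("generate_cohort produces labelled, reproducible samples", {
  d <- cohort_design(n_carriers = 3, n_noncarriers = 2, seed = 4)
  co <- generate_cohort(d)
  expect_length(co$samples, 5L)
  expect_identical(sum(co$manifest$true_status == "carrier"), 3L)
  expect_identical(nrow(co$manifest), 5L)
  # empty cohort
  co0 <- generate_cohort(cohort_design(0, 0))
  expect_length(co0$samples, 0L)
  expect_identical(nrow(co0$manifest), 0L)
  # determinism: bit-identical manifests for the same seed
  co2 <- generate_cohort(cohort_design(n_carriers = 3, n_noncarriers = 2,
                                       seed = 4))
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$samples[[2]]$sensorgram$response,
                   co2$samples[[2]]$sensorgram$response)
  # carriers draw from the fully complementary regime (higher ka)
  expect_gt(min(co$manifest$ka_true[co$manifest$true_status == "carrier"]),
            max(co$manifest$ka_true[co$manifest$true_status != "carrier"]))
})

test_that("run_study classifies a small noise-free cohort perfectly", {
  d <- cohort_design(n_carriers = 4, n_noncarriers = 2, seed = 2,
                     noise_sd = 0, qcmd_noise_f = 0, qcmd_noise_D = 0)
  st <- run_study(generate_cohort(d))
  expect_equal(as.numeric(st$summary$spr_selectivity), 100)
  expect_equal(as.numeric(st$summary$spr_specificity), 100)
  # noise-free fits are essentially exact
  expect_lt(median(st$recovery$rel_err_ka), 1e-4)
  expect_lt(median(st$recovery$rel_err_kd), 1e-4)
  expect_error(run_study(generate_cohort(cohort_design(0, 0))), "empty")
})

test_that("a default-design cohort is classified perfectly end to end", {
  # the module-level statement of the end-to-end invariant at one seed;
  # the 50-seed version lives in the acceptance suite
  st <- run_study(generate_cohort(cohort_design(seed = 1)))
  expect_equal(as.numeric(st$summary$spr_specificity), 100)
  expect_equal(as.numeric(st$summary$spr_selectivity), 100)
  expect_equal(as.numeric(st$summary$qcmd_specificity), 100)
  expect_equal(as.numeric(st$summary$qcmd_selectivity), 100)
  expect_identical(nrow(st$calls), 22L)
  # confusion counts are the plain sum of per-sample correctness
  correct <- with(st$calls, sum((true_status == "carrier") ==
                                  (spr_call == "positive")))
  expect_identical(
    correct,
    attr(st$summary$spr_selectivity, "n_correct") +
      attr(st$summary$spr_specificity, "n_correct"))
})

test_that("overlapping classes degrade the metrics", {
  # stress test: mismatched medians raised to the full-complement medians
  d <- cohort_design(n_carriers = 8, n_noncarriers = 8, seed = 9,
                     kinetics = list(
                       full_complement = list(median_ka = 5e6,
                                              sd_log10_ka = 0.7,
                                              median_kd = 1e-3,
                                              sd_log10_kd = 0.7, rho = 0.83),
                       mismatched = list(median_ka = 5e6, sd_log10_ka = 0.7,
                                         median_kd = 1e-3, sd_log10_kd = 0.7,
                                         rho = 0.83)))
  st <- run_study(generate_cohort(d), qcmd = FALSE)
  # with identical class distributions the rule cannot separate: at least
  # one of the two rates must fall well below 100
  expect_lt(min(as.numeric(st$summary$spr_specificity),
                as.numeric(st$summary$spr_selectivity)), 100)
})
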