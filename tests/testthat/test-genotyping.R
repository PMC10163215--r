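test_that("ka_threshold_call applies the inclusive one-decade rule", {
  rule <- classification_rule(2.28e10)  # 5382insC synthetic reference
  expect_identical(ka_threshold_call(7.25e10, rule), "positive")
  expect_identical(ka_threshold_call(4.65e5, rule), "negative")
  # boundary inclusive
  expect_identical(ka_threshold_call(2.28e10 / 10, rule), "positive")
  expect_identical(ka_threshold_call(2.28e10 / 10 - 1, rule), "negative")
  expect_error(ka_threshold_call(0, rule), "ka_sample")
  expect_error(classification_rule(-1), "ka_reference")
  expect_error(classification_rule(1, 0.5), "threshold_factor")
})

test_that("the call is invariant under joint rescaling of Ka", {
  set.seed(5)
  for (i in 1:30) {
    ka_s <- 10^runif(1, 3, 11)
    ka_r <- 10^runif(1, 3, 11)
    base <- ka_threshold_call(ka_s, classification_rule(ka_r))
    for (c_scale in 10^runif(3, -4, 4))
      expect_identical(
        ka_threshold_call(ka_s * c_scale,
                          classification_rule(ka_r * c_scale)),
        base)
  }
})

test_that("raising the threshold factor never flips positive to negative", {
  set.seed(6)
  for (i in 1:30) {
    ka_s <- 10^runif(1, 3, 11)
    ka_r <- 10^runif(1, 3, 11)
    calls <- vapply(c(1, 2, 10, 100),
                    function(f) ka_threshold_call(
                      ka_s, classification_rule(ka_r, f)), character(1))
    # once positive, always positive as the factor grows
    expect_true(all(diff(calls == "positive") >= 0))
  }
})

test_that("classify_cohort maps panels to references and keeps order", {
  fitted <- data.frame(sample_id = c("a", "b"),
                       panel = c("p1", "p2"), Ka = c(1e10, 1e5))
  refs <- c(p1 = 1e10, p2 = 1e10)
  calls <- classify_cohort(fitted, refs)
  expect_identical(vapply(calls, `[[`, "", "sample_id"), c("a", "b"))
  expect_identical(vapply(calls, `[[`, "", "call"),
                   c("positive", "negative"))
  expect_identical(classify_cohort(fitted[0, ], refs), list())
  expect_error(classify_cohort(fitted, refs["p1"]), "no reference")
  # borderline sample at exactly reference/factor
  one <- classify_cohort(data.frame(sample_id = "x", panel = "p1",
                                    Ka = 1e9), refs)
  expect_identical(one[[1]]$call, "positive")
})

test_that("specificity and selectivity follow the paper-style counting", {
  truth <- stats::setNames(rep(c(TRUE, FALSE), c(17, 5)),
                           c(paste0("P", 1:17), paste0("N", 1:5)))
  calls <- data.frame(
    sample_id = names(truth),
    call = rep(c("positive", "negative"), c(17, 5)))
  expect_equal(as.numeric(specificity(calls, truth)), 100.0)
  expect_equal(as.numeric(selectivity(calls, truth)), 100.0)
  # one ambiguous positive -> 16/17 = 94.1%; one ambiguous negative -> 80.0%
  calls$call[1] <- "ambiguous"
  calls$call[18] <- "ambiguous"
  expect_equal(as.numeric(selectivity(calls, truth)), 94.1)
  expect_equal(as.numeric(specificity(calls, truth)), 80.0)
  expect_identical(attr(selectivity(calls, truth), "n_correct"), 16L)
  # all positives miscalled
  calls$call[1:17] <- "negative"
  expect_equal(as.numeric(selectivity(calls, truth)), 0)
  # permutation invariance
  perm <- calls[sample(nrow(calls)), ]
  expect_equal(as.numeric(specificity(perm, truth)),
               as.numeric(specificity(calls, truth)))
  # undefined metrics
  expect_error(specificity(calls[1:17, ], truth), "undefined")
  expect_error(selectivity(calls[18:22, ], truth), "undefined")
  # a negative sample re-tested across panels must be negative in all of them
  truth2 <- c(N1 = FALSE)
  multi <- data.frame(sample_id = c("N1", "N1", "N1"),
                      call = c("negative", "ambiguous", "negative"))
  expect_equal(as.numeric(specificity(multi, truth2)), 0)
})

test_that("genotype_call enforces its invariants", {
  expect_error(genotype_call("s", "p", "PCR", "ambiguous"), "PCR")
  expect_error(genotype_call("s", "p", "SPR", "positive", NA), "evidence")
  expect_silent(genotype_call("s", "p", "PCR", "positive"))
})

test_that("the packaged tables reproduce the study's numbers", {
  res <- reproduce_reference_results()
  # arithmetic audit: every row within 1.5% on both Kd and Ka
  expect_true(res$audit$pass)
  expect_lte(res$audit$max_rel_dev, 0.015)
  expect_identical(nrow(res$audit$table), 50L)  # 25 rows x 2 probe columns
  # the two logged rounding inconsistencies are present but small
  wt_t <- res$audit$table[res$audit$table$probe == "wt" &
                            res$audit$table$row_label == "Target", ]
  expect_gt(max(wt_t$rel_dev_Kd), 0.001)
  # threshold classification concordance: 20/20 patients
  expect_identical(res$concordance$n_concordant, 20L)
  expect_identical(res$concordance$n_total, 20L)
  # four printed performance metrics
  expect_equal(as.numeric(res$metrics$spr_specificity), 100.0)
  expect_equal(as.numeric(res$metrics$spr_selectivity), 100.0)
  expect_equal(as.numeric(res$metrics$qcmd_specificity), 80.0)
  expect_equal(as.numeric(res$metrics$qcmd_selectivity), 94.1)
  expect_identical(attr(res$metrics$qcmd_selectivity, "n_total"), 17L)
  expect_identical(attr(res$metrics$qcmd_specificity, "n_total"), 5L)
})

test_that("fixture integrity is checked", {
  tab <- reference_kinetics()
  expect_identical(nrow(tab), 25L)
  expect_identical(nrow(reference_calls()), 39L)
  expect_error(genosensr:::.check_fixture("no_such_fixture.csv"))
})
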