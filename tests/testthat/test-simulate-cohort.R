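test_that("identical spec and seed reproduce the cohort bytewise", {
  spec <- cohort_spec(n_per_group = 8)
  s1 <- simulate_cohort(spec, seed = 42)
  s2 <- simulate_cohort(spec, seed = 42)
  expect_identical(s1$cohort$duration_yr, s2$cohort$duration_yr)
  expect_identical(s1$sites$E_GPa, s2$sites$E_GPa)
  p1 <- simulate_envelope_primitives(spec, "cancellous", seed = 9)
  p2 <- simulate_envelope_primitives(spec, "cancellous", seed = 9)
  expect_identical(p1$dLS_mm, p2$dLS_mm)
  expect_identical(p1$interlabel_um, p2$interlabel_um)
})

test_that("site counts follow the sampling design", {
  sim <- simulate_cohort(cohort_spec(n_per_group = 4), seed = 1)
  counts <- table(sim$sites$subject_id, sim$sites$compartment)
  expect_true(all(counts[, "cortical"] == 60))
  expect_true(all(counts[, "cancellous"] == 60))  # 5 trabeculae x 12 sites
  expect_equal(dplyr::n_distinct(
    sim$sites$trabecula[sim$sites$compartment == "cancellous"]), 5)
})

test_that("the intraclass correlation of site values matches the spec", {
  # ANOVA ICC estimator on cortical E at 64 subjects
  icc_anova <- function(d) {
    fit <- stats::aov(E_GPa ~ subject_id, data = d)
    ms <- summary(fit)[[1]]$`Mean Sq`
    k <- 60
    (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  }
  sim <- simulate_cohort(cohort_spec(n_per_group = 32, icc = 0.8), seed = 5)
  d <- sim$sites[sim$sites$compartment == "cortical", ]
  expect_lt(abs(icc_anova(d) - 0.8), 0.1)
  sim2 <- simulate_cohort(cohort_spec(n_per_group = 32, icc = 0.3), seed = 6)
  d2 <- sim2$sites[sim2$sites$compartment == "cortical", ]
  expect_lt(abs(icc_anova(d2) - 0.3), 0.1)
})

test_that("wall-thickness group means track the calibration targets", {
  # cancellous W.Th targets: 33.6 +/- 3.69 (non-AFF) vs 29.8 +/- 4.61 (AFF)
  spec <- cohort_spec(n_per_group = 16)
  prim <- simulate_envelope_primitives(spec, "cancellous", seed = 31)
  idx <- histo_indices(prim)
  for (g in c("nonAFF", "AFF")) {
    tg <- spec$histo[spec$histo$parameter == "W.Th" &
                       spec$histo$envelope == "cancellous" &
                       spec$histo$group == g, ]
    got <- mean(idx$W_Th_um[idx$group == g])
    expect_lt(abs(got - tg$mean), 3 * tg$sd / sqrt(16))
  }
})

test_that("forced label-status fractions drive the imputation rules", {
  spec_none <- cohort_spec(n_per_group = 6, fraction_no_label = 1,
                           fraction_single_label = 0)
  idx <- histo_indices(simulate_envelope_primitives(spec_none, "endosteal",
                                                    seed = 3))
  expect_true(all(idx$BFR_BS_um3_um2_yr == 0))
  expect_true(all(idx$Ac_f_per_yr == 0))
  expect_true(all(is.na(idx$MAR_um_day)))

  spec_single <- cohort_spec(n_per_group = 6, fraction_no_label = 0,
                             fraction_single_label = 1)
  idx2 <- histo_indices(simulate_envelope_primitives(spec_single, "endosteal",
                                                     seed = 3))
  expect_true(all(idx2$MAR_um_day == 0.3))
})

test_that("a null generator yields odds ratios near one", {
  # or_per_gpa = 1: the AFF label is independent of the mechanics; the
  # stats stage's site-level clustered fit should sit near OR = 1
  set.seed(11)
  ors <- vapply(1:200, function(i) {
    sim <- simulate_cohort(cohort_spec(n_per_group = 16, or_per_gpa = 1),
                           seed = sample.int(1e6, 1))
    d <- cortical_sites(sim)
    td <- suppressMessages(tidy(fit_aff_or(d, "E_GPa")))
    td$OR[td$variable == "E_GPa"]
  }, numeric(1))
  expect_gte(mean(ors > 0.8 & ors < 1.25), 0.90)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_per_group = 1), class = "ossindent_error_invalid")
  expect_error(cohort_spec(icc = 1), class = "ossindent_error_invalid")
  expect_error(cohort_spec(or_per_gpa = -2), class = "ossindent_error_invalid")
  expect_error(cohort_spec(fraction_no_label = 0.7, fraction_single_label = 0.6),
               class = "ossindent_error_invalid")
})
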