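test_that("exchangeable GEE matches the reference implementation on a frozen fixture", {
  # reference values computed once with statsmodels GEE (binomial, logit)
  # on the exact fixture produced by gee_fixture()
  d <- gee_fixture()
  f <- gee_logit(y ~ x1 + x2, d, id = "cl", corstr = "exchangeable",
                 cov_type = "robust")
  expect_equal(unname(f$coefficients),
               c(-0.29790132, 1.82950311, -0.12364807), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov))),
               c(0.31886454, 0.51206837, 0.16760679), tolerance = 1e-6)
  expect_equal(f$alpha, -0.02828631, tolerance = 1e-6)

  fi <- gee_logit(y ~ x1 + x2, d, id = "cl", corstr = "independence",
                  cov_type = "robust")
  expect_equal(unname(fi$coefficients),
               c(-0.30917195, 1.82128648, -0.11226093), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fi$vcov))),
               c(0.32075261, 0.52149904, 0.17559577), tolerance = 1e-6)
})

test_that("independence GEE equals glm with a cluster-robust sandwich", {
  skip_if_not_installed("sandwich")
  sim <- simulate_cohort(cohort_spec(n_per_group = 16, or_per_gpa = 1.15),
                         seed = 7)
  d <- cortical_sites(sim)
  d$aff <- as.integer(d$group == "AFF")
  f <- gee_logit(aff ~ duration_yr + E_GPa, d, id = "subject_id",
                 corstr = "independence", cov_type = "robust")
  g <- stats::glm(aff ~ duration_yr + E_GPa, data = d, family = binomial())
  v <- sandwich::vcovCL(g, cluster = d$subject_id, type = "HC0",
                        cadjust = FALSE)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(diag(f$vcov)), unname(diag(v)), tolerance = 1e-6)
})

test_that("cluster-constant outcomes trigger the independence fallback", {
  sim <- simulate_cohort(cohort_spec(n_per_group = 8), seed = 2)
  d <- cortical_sites(sim)
  d$aff <- as.integer(d$group == "AFF")
  expect_message(
    f <- gee_logit(aff ~ E_GPa, d, id = "subject_id", corstr = "exchangeable"),
    class = "ossindent_message_cluster_constant")
  expect_identical(f$corstr, "independence")
})

test_that("Firth fit is finite under complete separation and matches known bias behaviour", {
  d <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = 1:6)
  f <- firth_logit(y ~ x, d)
  expect_true(all(is.finite(f$coefficients)))
  expect_true(all(is.finite(sqrt(diag(f$vcov)))))
  # on well-behaved data the Firth estimate shrinks towards zero vs MLE
  set.seed(8)
  d2 <- data.frame(x = rnorm(40))
  d2$y <- rbinom(40, 1, plogis(d2$x))
  fm <- firth_logit(y ~ x, d2)
  g <- stats::glm(y ~ x, data = d2, family = binomial())
  expect_lt(abs(fm$coefficients["x"]), abs(coef(g)["x"]))
})

test_that("degenerate responses are rejected", {
  d <- data.frame(y = rep(1, 20), x = rnorm(20), cl = rep(1:5, 4))
  expect_error(gee_logit(y ~ x, d, id = "cl"),
               class = "ossindent_error_degenerate")
  d2 <- data.frame(y = c(0.5, rep(1, 9)), x = rnorm(10), cl = rep(1:5, 2))
  expect_error(gee_logit(y ~ x, d2, id = "cl"),
               class = "ossindent_error_invalid")
})
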