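test_that("group summaries use the n-1 SD and the mean ± SD label", {
  d <- data.frame(group = c("a", "a", "b", "b"), x = c(10, 14, 7, 7))
  gs <- group_summary(d, "x")
  a <- gs[gs$group == "a", ]
  expect_equal(a$mean, 12)
  expect_equal(a$sd, sqrt(8))  # 2.83
  expect_match(a$label, "12 ± 2.83")
  expect_equal(gs$sd[gs$group == "b"], 0)
})

test_that("an all-missing variable yields a row with n = 0", {
  d <- data.frame(group = c("a", "a", "b", "b"),
                  x = c(1, 2, 3, 4), z = NA_real_)
  gs <- group_summary(d, c("x", "z"))
  z <- gs[gs$variable == "z", ]
  expect_equal(z$n, c(0L, 0L))
  expect_true(all(is.na(z$mean)))
})

test_that("the summary-statistic t test agrees with t.test on raw data", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(sample(4:12, 1), mean = runif(1, -1, 1))
    y <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 2))
    for (welch in c(FALSE, TRUE)) {
      mine <- ttest_from_summary(mean(x), sd(x), length(x),
                                 mean(y), sd(y), length(y), welch = welch)
      ref <- stats::t.test(x, y, var.equal = !welch)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("raw-vector and summary-statistic routes are identical", {
  d <- data.frame(group = rep(c("g1", "g2"), c(7, 9)),
                  v = c(rnorm(7, 1), rnorm(9)))
  raw <- two_group_ttest(d, "v")
  g1 <- d$v[d$group == "g1"]; g2 <- d$v[d$group == "g2"]
  summ <- ttest_from_summary(mean(g1), sd(g1), 7, mean(g2), sd(g2), 9)
  expect_identical(raw$t, summ$t)
  expect_identical(raw$df, summ$df)
  expect_identical(raw$p, summ$p)
})

test_that("the pooled t test agrees with a permutation test on small samples", {
  set.seed(14)
  perm_p <- function(x, y, B = 4000) {
    obs <- abs(mean(x) - mean(y))
    z <- c(x, y); n <- length(x)
    hits <- mean(replicate(B, {
      idx <- sample(length(z), n)
      abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12
    }))
    hits
  }
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, 0, 1.5))
    p_t <- ttest_from_summary(mean(x), sd(x), 8, mean(y), sd(y), 8)$p
    p_perm <- perm_p(x, y)
    expect_lt(abs(p_t - p_perm), 0.06)  # within Monte Carlo error
  }
})

test_that("equal means with zero variance give t = 0, p = 1", {
  res <- ttest_from_summary(5, 0, 4, 5, 0, 4)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("published wall-thickness summaries reproduce the reported significance", {
  # intracortical W.Th: 42.6 +/- 4.66 vs 36.1 +/- 4.22, n = 16 per arm
  res <- ttest_from_summary(42.6, 4.66, 16, 36.1, 4.22, 16)
  expect_lt(res$p, 0.001)
  # cancellous W.Th: 33.6 +/- 3.69 vs 29.8 +/- 4.61, n = 16 per arm
  res2 <- ttest_from_summary(33.6, 3.69, 16, 29.8, 4.61, 16)
  expect_lt(res2$p, 0.05)
})

test_that("a subject-level fit on a saturated binary table matches the cross-product OR", {
  # 2x2 table: exposure x in {0,1}, counts (a,b,c,d) = (9,3,4,8)
  d <- data.frame(
    y = rep(c(1, 0, 1, 0), c(9, 3, 4, 8)),
    x = rep(c(1, 1, 0, 0), c(9, 3, 4, 8)),
    id = seq_len(24), dur = 0)
  fit <- gee_logit(y ~ x, d, id = "id")
  or_fit <- exp(unname(fit$coefficients["x"]))
  or_table <- (9 * 8) / (3 * 4)
  expect_equal(or_fit, or_table, tolerance = 1e-6)
})

test_that("rescaling a property maps the odds ratio to its k-th root", {
  sim <- simulate_cohort(cohort_spec(n_per_group = 16, or_per_gpa = 1.3),
                         seed = 23)
  d <- cortical_sites(sim)
  f1 <- suppressMessages(fit_aff_or(d, "E_GPa"))
  k <- 4
  d$E_scaled <- d$E_GPa * k
  f2 <- suppressMessages(fit_aff_or(d, "E_scaled"))
  or1 <- tidy(f1)$OR[2]
  or2 <- tidy(f2)$OR[2]
  expect_equal(or2, or1^(1 / k), tolerance = 1e-6)
})

test_that("complete separation is flagged with an unbounded interval", {
  d <- data.frame(group = rep(c("AFF", "nonAFF"), each = 6),
                  E_GPa = c(7:12, 1:6) + 0.5,
                  duration_yr = rep(c(10, 5), each = 6),
                  subject_id = 1:12)
  expect_warning(td <- tidy(fit_aff_or(d, "E_GPa")),
                 class = "ossindent_warning_separation")
  expect_equal(td$ci_low, c(0, 0))
  expect_equal(td$ci_high, c(Inf, Inf))
})
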