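test_that("identical cortical sites aggregate to their value with zero SD", {
  d <- tibble::tibble(specimen = "S1", compartment = "cortical",
                      trabecula = NA_integer_, site = 1:60,
                      E_GPa = 17.5, valid = TRUE)
  agg <- aggregate_sites(d, properties = "E_GPa")
  expect_equal(agg$mean, 17.5)
  expect_equal(agg$sd, 0)
  expect_equal(agg$n_sites, 60L)
})

test_that("cancellous aggregation is a mean of per-trabecula means", {
  # 5 trabeculae with means 1..5 GPa; within-trabecula spread is irrelevant
  set.seed(1)
  d <- tidyr::expand_grid(trabecula = 1:5, site = 1:12)
  d$E_GPa <- d$trabecula + rnorm(nrow(d), 0, 0.3)
  # centre the noise so each trabecula mean is exactly its index
  d <- dplyr::group_by(d, trabecula) |>
    dplyr::mutate(E_GPa = .data$E_GPa - mean(.data$E_GPa) + .data$trabecula) |>
    dplyr::ungroup()
  d$specimen <- "S1"; d$compartment <- "cancellous"; d$valid <- TRUE
  agg <- aggregate_sites(d, properties = "E_GPa")
  expect_equal(agg$mean, 3)
  expect_equal(agg$sd, sd(1:5))
})

test_that("an unbalanced trabecula still contributes exactly one mean", {
  d <- tidyr::expand_grid(trabecula = 1:5, site = 1:12)
  d$E_GPa <- as.numeric(d$trabecula)
  d$valid <- TRUE
  # trabecula 3 keeps only 6 valid sites
  d$valid[d$trabecula == 3 & d$site > 6] <- FALSE
  d$specimen <- "S1"; d$compartment <- "cancellous"
  agg <- aggregate_sites(d, properties = "E_GPa")
  # direct computation: per-trabecula means of valid sites are still 1..5
  expect_equal(agg$mean, mean(1:5))
  expect_equal(agg$n_sites, 54L)
  expect_equal(agg$n_failed, 6L)
})

test_that("a specimen with zero valid sites is marked missing", {
  d <- tibble::tibble(specimen = "S1", compartment = "cortical",
                      trabecula = NA_integer_, site = 1:10,
                      E_GPa = NA_real_, valid = FALSE)
  agg <- aggregate_sites(d, properties = "E_GPa")
  expect_equal(agg$n_sites, 0L)
  expect_true(is.na(agg$mean))
})
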