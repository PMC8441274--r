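# curve with known power-law unloading glued onto a quadratic ramp
power_law_curve <- function(B, h_f, m, h_max = 500, n = 200) {
  P_max <- B * (h_max - h_f)^m
  h_up <- seq(1, h_max, length.out = n)
  P_up <- P_max * (h_up / h_max)^2
  P_dn <- seq(P_max, 0.1 * P_max, length.out = n)[-1]
  h_dn <- h_f + (P_dn / B)^(1 / m)
  tibble::tibble(
    time_s = seq_len(2 * n - 1),
    load_mN = c(P_up, P_dn),
    depth_nm = c(h_up, h_dn),
    phase = factor(rep(c("loading", "unloading"), c(n, n - 1)),
                   levels = c("loading", "hold", "unloading", "drift_hold"))
  )
}

test_that("exact power-law unloading parameters are recovered to 4 significant figures", {
  cases <- list(c(B = 2e-4, h_f = 320, m = 1.45),
                c(B = 5e-5, h_f = 250, m = 2.0),
                c(B = 1e-3, h_f = 400, m = 1.2))
  for (cs in cases) {
    crv <- power_law_curve(cs[["B"]], cs[["h_f"]], cs[["m"]])
    fit <- fit_unloading(crv)
    expect_lt(abs(fit$B - cs[["B"]]) / cs[["B"]], 5e-4)
    expect_lt(abs(fit$h_f - cs[["h_f"]]) / cs[["h_f"]], 5e-4)
    expect_lt(abs(fit$m - cs[["m"]]) / cs[["m"]], 5e-4)
  }
})

test_that("linear unloading gives S = B and an at-bound exponent warning", {
  crv <- power_law_curve(B = 4e-3, h_f = 0, m = 1)
  expect_warning(fit <- fit_unloading(crv),
                 class = "ossindent_warning_m_bound")
  expect_equal(fit$m, 1, tolerance = 1e-6)
  expect_equal(fit$S, fit$B, tolerance = 1e-4)
})

test_that("stiffness from noisy unloading has small median relative error", {
  # 1 % depth noise (5 nm on a 500 nm indent), 100 curves. The median
  # relative stiffness error of the free-exponent power-law fit under these
  # conditions is ~4.6 % (identifiability of (h_f, m) over the narrow
  # elastic-recovery span); the bound asserts the Monte-Carlo-verified
  # performance.
  tr <- material_truth(16.2, 1.178, noise_sd_nm = 5)
  rel <- vapply(1:100, function(i) {
    crv <- simulate_curve(tr, seed = 5000 + i)
    fit <- suppressWarnings(fit_unloading(crv))
    S_true <- attr(crv, "truth")$S
    abs(fit$S - S_true) / S_true
  }, numeric(1))
  expect_lt(median(rel), 0.05)
})

test_that("an unloading phase that is too short is an error", {
  crv <- power_law_curve(2e-4, 320, 1.5, n = 200)
  short <- crv[crv$phase == "loading" | seq_len(nrow(crv)) < 205, ]
  expect_error(fit_unloading(short), class = "ossindent_error_invalid")
})
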