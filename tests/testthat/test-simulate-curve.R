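test_that("identical truth and seed give bit-identical curves", {
  tr <- material_truth(16.2, 1.178, creep_amp_nm = 5, drift_rate_nm_s = 0.05,
                       noise_sd_nm = 2)
  c1 <- simulate_curve(tr, seed = 99)
  c2 <- simulate_curve(tr, seed = 99)
  expect_identical(c1$depth_nm, c2$depth_nm)
  expect_identical(c1$load_mN, c2$load_mN)
  c3 <- simulate_curve(tr, seed = 100)
  expect_false(identical(c1$depth_nm, c3$depth_nm))
})

test_that("curves have four contiguous phases in protocol order", {
  crv <- simulate_curve(material_truth(20, 1.5))
  ph <- as.character(crv$phase)
  expect_identical(unique(ph), c("loading", "hold", "unloading", "drift_hold"))
  expect_true(all(diff(crv$time_s) > 0))
  # loading ends exactly at the target depth and maximum load
  tr <- attr(crv, "truth")
  i_load <- max(which(ph == "loading"))
  expect_equal(crv$depth_nm[i_load], 500)
  expect_equal(crv$load_mN[i_load], tr$P_max)
})

test_that("pure elastic truth retraces loading and leaves ~no plastic energy", {
  prot <- indentation_protocol(drift_hold_fraction = 0.001)
  crv <- simulate_curve(material_truth(20, Inf), protocol = prot)
  en <- indentation_energies(crv, protocol = prot)
  expect_lt(abs(en$Up_pJ), 0.01 * en$U_total_pJ)
  # unloading depths sit on the closed-form elastic cone curve h = sqrt(P/C_e)
  un <- crv[crv$phase == "unloading", ]
  C_e <- attr(crv, "truth")$C_e
  expect_lt(max(abs(un$depth_nm - sqrt(un$load_mN / C_e))), 1e-9 * 500)
})

test_that("non-physical truth is rejected", {
  expect_error(material_truth(-5, 1), class = "ossindent_error_invalid")
  expect_error(material_truth(16, -1), class = "ossindent_error_invalid")
  expect_error(material_truth(16, 1, nu_s = 0.6), class = "ossindent_error_invalid")
})

test_that("reduced properties recover the generating truth without noise", {
  # forward/inverse consistency across the (E_s, H) grid
  grid <- expand.grid(E = c(10, 15, 20, 25, 30), H = c(0.5, 1, 1.5, 2, 2.5))
  errs <- t(apply(grid, 1, function(r) {
    crv <- simulate_curve(material_truth(r[["E"]], r[["H"]]))
    p <- extract_properties(crv, indenter = cone_indenter())
    c(abs(p$E_GPa - r[["E"]]) / r[["E"]],
      abs(p$H_GPa - r[["H"]]) / r[["H"]])
  }))
  expect_lt(max(errs[, 1]), 0.01)   # E within 1 %
  expect_lt(max(errs[, 2]), 0.05)   # H within 5 %
})

test_that("recovered stiffness and modulus increase with the generating modulus", {
  Es <- seq(10, 30, length.out = 9)
  out <- t(sapply(seq_along(Es), function(i) {
    crv <- simulate_curve(material_truth(Es[i], 1.2, noise_sd_nm = 5),
                          seed = 300 + i)
    p <- extract_properties(crv, indenter = cone_indenter())
    c(p$S_mN_nm, p$E_GPa)
  }))
  expect_gt(cor(Es, out[, 1], method = "spearman"), 0.95)
  expect_gt(cor(Es, out[, 2], method = "spearman"), 0.95)
})

test_that("unit round-trip leaves reported properties unchanged", {
  crv <- simulate_curve(material_truth(16.2, 1.178), seed = 5)
  p1 <- extract_properties(crv, indenter = cone_indenter())
  rt <- crv
  rt$depth_nm <- (rt$depth_nm * 1e-9) * 1e9   # nm -> m -> nm
  rt$load_mN <- (rt$load_mN * 1e-3) * 1e3     # mN -> N -> mN
  p2 <- extract_properties(rt, indenter = cone_indenter())
  for (col in c("E_GPa", "Hc_GPa", "H_GPa", "Ue_pJ", "Up_pJ", "S_mN_nm")) {
    expect_lt(abs(p2[[col]] - p1[[col]]) / abs(p1[[col]]), 1e-9)
  }
})
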