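test_that("a rigid indenter with nu_s = 0 gives E = E_r", {
  crv <- simulate_curve(material_truth(16.2, 1.178))
  fit <- fit_unloading(crv)
  ind <- indenter_spec(E_i = 1e12, epsilon = cone_epsilon())
  op <- oliver_pharr(fit, indenter = ind, nu_s = 0)
  expect_equal(op$E_GPa, op$E_r_GPa, tolerance = 1e-6)
})

test_that("Sneddon elastic cone curve reduces to the generating reduced modulus", {
  crv <- sneddon_curve(E_r_GPa = 20, h_max = 500)
  fit <- fit_unloading(segment_curve(crv))
  op <- oliver_pharr(fit, indenter = cone_indenter())
  expect_lt(abs(op$E_r_GPa - 20) / 20, 0.01)
})

test_that("doubling the area constant halves Hc and scales E_r by 1/sqrt(2)", {
  crv <- simulate_curve(material_truth(16.2, 1.178))
  fit <- fit_unloading(crv)
  op1 <- oliver_pharr(fit, indenter = cone_indenter())
  op2 <- oliver_pharr(fit, indenter = cone_indenter(area_c0 = 49))
  expect_equal(op2$Hc_GPa, op1$Hc_GPa / 2, tolerance = 1e-9)
  expect_equal(op2$E_r_GPa, op1$E_r_GPa / sqrt(2), tolerance = 1e-9)
})

test_that("contact depth collapse is reported as an error", {
  fit <- structure(list(B = 1, h_f = 0, m = 1, S = 0.001, P_max = 2,
                        h_max = 500, residual_rms = 0, fit_fraction = 0.8,
                        n = 50),
                   class = "unload_fit")
  # eps * P_max / S = 1500 nm > h_max
  expect_error(oliver_pharr(fit), class = "ossindent_error_contact_collapse")
})

test_that("higher-order area coefficients increase the contact area", {
  crv <- simulate_curve(material_truth(16.2, 1.178))
  fit <- fit_unloading(crv)
  op1 <- oliver_pharr(fit, indenter = cone_indenter())
  op2 <- oliver_pharr(fit, indenter = cone_indenter(area_coeffs = c(1000)))
  expect_gt(op2$A_nm2, op1$A_nm2)
  expect_lt(op2$E_r_GPa, op1$E_r_GPa)
})

test_that("loading decomposition recovers H and scales linearly", {
  crv <- simulate_curve(material_truth(16.2, 1.178))
  p <- extract_properties(crv, indenter = cone_indenter())
  expect_lt(abs(p$H_GPa - 1.178) / 1.178, 0.05)
  # halving H_true with E fixed halves the recovered H
  crv2 <- simulate_curve(material_truth(16.2, 1.178 / 2))
  p2 <- extract_properties(crv2, indenter = cone_indenter())
  expect_lt(abs(p2$H_GPa - p$H_GPa / 2) / (p$H_GPa / 2), 0.05)
})

test_that("a purely elastic loading curve reports no measurable plasticity", {
  prot <- indentation_protocol(drift_hold_fraction = 0.001)
  crv <- simulate_curve(material_truth(20, Inf), protocol = prot)
  E_r <- reduced_modulus(20)
  expect_warning(dec <- decompose_loading(crv, E_r = E_r, protocol = prot),
                 class = "ossindent_warning_no_plasticity")
  expect_true(is.na(dec$H_GPa))
})

test_that("loading stiffer than the elastic bound is non-physical", {
  crv <- simulate_curve(material_truth(20, 1.5))
  # pretend the material were much softer than the observed loading allows
  expect_error(decompose_loading(crv, E_r = 5),
               class = "ossindent_error_nonphysical")
})
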