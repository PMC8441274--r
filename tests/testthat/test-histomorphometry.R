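test_that("structural indices follow the stated formulas", {
  prim <- data.frame(bone_area_mm2 = 0.15, tissue_area_mm2 = 1.0,
                     bone_perimeter_mm = 2.8)
  idx <- structural_indices(prim)
  expect_equal(idx$BV_TV_pct, 15)
  expect_equal(idx$Tb_Th_um, 2000 * 0.15 / 2.8)     # ~107.1 um
  expect_equal(idx$Tb_N_per_mm, 0.15 / (idx$Tb_Th_um / 1000))
  # full bone area means BV/TV = 100 %
  full <- structural_indices(data.frame(bone_area_mm2 = 1, tissue_area_mm2 = 1,
                                        bone_perimeter_mm = 2))
  expect_equal(full$BV_TV_pct, 100)
})

test_that("degenerate structural primitives are rejected", {
  expect_error(structural_indices(data.frame(
    bone_area_mm2 = 0.1, tissue_area_mm2 = 0, bone_perimeter_mm = 1)),
    class = "ossindent_error_invalid")
  expect_error(structural_indices(data.frame(
    bone_area_mm2 = 0.1, tissue_area_mm2 = 1, bone_perimeter_mm = 0)),
    class = "ossindent_error_invalid")
})

make_prim <- function(BS = 10, OS = 1, ES = 0.5, ObS = 0.2, OcS = 0,
                      dLS = 0.4, sLS = 0.2, interlabel = c(4.62),
                      w_th = 33.6, o_th = 8) {
  tibble::tibble(
    subject_id = "S1", envelope = "cancellous",
    BS_mm = BS, OS_mm = OS, ES_mm = ES, ObS_mm = ObS, OcS_mm = OcS,
    dLS_mm = dLS, sLS_mm = sLS, label_interval_d = 14,
    o_th_um = list(o_th), w_th_um = list(w_th),
    interlabel_um = list(interlabel))
}

test_that("static indices are surface fractions and reading means", {
  st <- static_indices(make_prim(w_th = c(40, 44, 45.8)))
  expect_equal(st$OS_BS_pct, 10)
  expect_equal(st$ES_BS_pct, 5)
  expect_equal(st$OcS_BS_pct, 0)
  expect_equal(st$W_Th_um, mean(c(40, 44, 45.8)))  # 43.27 um
  # full osteoid coverage is the 100 % bound
  expect_equal(static_indices(make_prim(OS = 10))$OS_BS_pct, 100)
})

test_that("dynamic indices reproduce the worked double-label example", {
  # dLS/BS = 0.04, sLS/BS = 0.02, mean distance 4.62 um, 14-day interval
  prim <- make_prim(BS = 10, dLS = 0.4, sLS = 0.2, interlabel = c(4.62),
                    w_th = 33.6)
  dyn <- dynamic_indices(prim)
  expect_equal(dyn$MS_BS_pct, 5)
  expect_equal(dyn$MAR_um_day, 0.33)
  expect_equal(dyn$BFR_BS_um3_um2_yr, 0.33 * 0.05 * 365)  # 6.0225
  expect_equal(dyn$Ac_f_per_yr, 0.33 * 0.05 * 365 / 33.6) # ~0.179
})

test_that("single-label-only surfaces get the 0.3 um/day MAR floor", {
  prim <- make_prim(dLS = 0, sLS = 0.6, interlabel = numeric(0))
  dyn <- dynamic_indices(prim)
  expect_equal(dyn$MAR_um_day, 0.3)
  expect_equal(dyn$MS_BS_pct, 3)
  expect_equal(dyn$BFR_BS_um3_um2_yr, 0.3 * 0.03 * 365)
})

test_that("no-label surfaces zero the rates and leave MAR missing", {
  prim <- make_prim(dLS = 0, sLS = 0, interlabel = numeric(0))
  dyn <- dynamic_indices(prim)
  expect_true(is.na(dyn$MAR_um_day))
  expect_equal(dyn$MS_BS_pct, 0)
  expect_equal(dyn$BFR_BS_um3_um2_yr, 0)
  expect_equal(dyn$Ac_f_per_yr, 0)
})

test_that("the Ac.f x W.Th = BFR/BS identity holds for every labeled envelope", {
  spec <- cohort_spec(n_per_group = 8)
  for (env in c("cancellous", "intracortical", "endosteal")) {
    prim <- simulate_envelope_primitives(spec, env, seed = 17)
    idx <- histo_indices(prim)
    lab <- !is.na(idx$MAR_um_day)
    expect_equal(idx$Ac_f_per_yr[lab] * idx$W_Th_um[lab],
                 idx$BFR_BS_um3_um2_yr[lab], tolerance = 1e-12)
    expect_true(all(idx$MS_BS_pct >= 0 & idx$MS_BS_pct <= 100))
  }
})

test_that("indices are invariant to uniform rescaling of all surface lengths", {
  prim <- make_prim()
  k <- 3.7
  scaled <- prim
  for (col in c("BS_mm", "OS_mm", "ES_mm", "ObS_mm", "OcS_mm",
                "dLS_mm", "sLS_mm")) {
    scaled[[col]] <- scaled[[col]] * k
  }
  i1 <- histo_indices(prim)
  i2 <- histo_indices(scaled)
  for (col in c("OS_BS_pct", "ES_BS_pct", "MS_BS_pct", "MAR_um_day",
                "BFR_BS_um3_um2_yr", "Ac_f_per_yr")) {
    expect_equal(i2[[col]], i1[[col]], tolerance = 1e-12)
  }
})

test_that("inconsistent primitives are rejected", {
  bad <- make_prim(OS = 20)  # osteoid surface longer than total surface
  expect_error(static_indices(bad), class = "ossindent_error_invalid")
  neg <- make_prim(interlabel = c(-1))
  expect_error(dynamic_indices(neg), class = "ossindent_error_invalid")
  zero_bs <- make_prim(BS = 0, OS = 0, ES = 0, ObS = 0, OcS = 0,
                       dLS = 0, sLS = 0)
  expect_error(static_indices(zero_bs), class = "ossindent_error_invalid")
})
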