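# shared fixtures, all generated in code

# indenter matching the conical forward model exactly
cone_indenter <- function(...) indenter_spec(epsilon = cone_epsilon(), ...)

# closed-form Sneddon elastic cone curve: P = C_e h^2 on loading, retraced
# on unloading down to (almost) zero load
sneddon_curve <- function(E_r_GPa = 20, h_max = 500, psi_deg = 70.3,
                          n = 400, rate = 0.25) {
  C_e <- (2 / pi) * E_r_GPa * 1e-6 * tan(psi_deg * pi / 180)
  P_max <- C_e * h_max^2
  h_up <- seq(0, h_max, length.out = n)
  P_up <- C_e * h_up^2
  t_up <- P_up / rate
  P_dn <- seq(P_max, 0.001 * P_max, length.out = n)[-1]
  h_dn <- sqrt(P_dn / C_e)
  t_dn <- t_up[n] + (P_max - P_dn) / rate
  tibble::tibble(time_s = c(t_up, t_dn),
                 load_mN = c(P_up, P_dn),
                 depth_nm = c(h_up, h_dn))
}

# triangle-wave toy: load to 2 mN at 500 nm, unload linearly to (250 nm, 0)
triangle_curve <- function(n = 101) {
  h_up <- seq(0, 500, length.out = n)
  P_up <- seq(0, 2, length.out = n)
  h_dn <- seq(500, 250, length.out = n)[-1]
  P_dn <- seq(2, 0, length.out = n)[-1]
  tibble::tibble(time_s = seq_len(2 * n - 1),
                 load_mN = c(P_up, P_dn),
                 depth_nm = c(h_up, h_dn))
}

# clustered binary regression fixture; statsmodels GEE reference values are
# frozen in test-gee.R for this exact draw
gee_fixture <- function() {
  set.seed(20260924)
  n_cl <- 12; n_per <- 5
  cl <- rep(1:n_cl, each = n_per)
  x1 <- round(rnorm(n_cl * n_per), 6)
  x2 <- round(rep(rnorm(n_cl), each = n_per) + rnorm(n_cl * n_per, 0, 0.5), 6)
  eta <- -0.2 + 0.8 * x1 - 0.5 * x2 + rep(round(rnorm(n_cl, 0, 0.7), 6), each = n_per)
  y <- as.integer(runif(n_cl * n_per) < plogis(eta))
  data.frame(cl, x1, x2, y)
}

# cortical site rows joined with the cohort table
cortical_sites <- function(sim) {
  merge(sim$sites[sim$sites$compartment == "cortical", ], sim$cohort,
        by = "subject_id")
}
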