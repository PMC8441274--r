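#' Oliver-Pharr reduction of an unloading fit
#'
#' Converts an unloading power-law fit into contact depth, projected contact
#' area, reduced and sample elastic moduli, and contact hardness:
#' `h_c = h_max - epsilon P_max / S`, `A = C0 h_c^2 + ...` (area function),
#' `E_r = sqrt(pi) / (2 beta) * S / sqrt(A)`, sample modulus from
#' `1/E_r = (1 - nu_s^2)/E + (1 - nu_i^2)/E_i`, and `Hc = P_max / A`.
#'
#' Unit contract: the fit carries mN and nm; moduli and hardness are
#' returned in GPa via the exact conversion 1 mN/nm^2 = 1e6 GPa.
#'
#' @param fit An [unload_fit][fit_unloading()].
#' @param indenter An [indenter_spec()].
#' @param nu_s Sample Poisson ratio (0.3 is a standard choice for bone).
#'
#' @return A one-row tibble with columns `E_r_GPa`, `E_GPa`, `h_c_nm`,
#'   `A_nm2`, `Hc_GPa`, `S_mN_nm`, `P_max_mN`, `h_max_nm`.
#' @export
#' @examples
#' crv <- simulate_curve(material_truth(16.2, 1.178))
#' oliver_pharr(fit_unloading(crv), indenter_spec(epsilon = cone_epsilon()))
oliver_pharr <- function(fit, indenter = indenter_spec(), nu_s = 0.3) {
  stopifnot(inherits(fit, "unload_fit"), inherits(indenter, "indenter_spec"))
  check_number(nu_s, "nu_s", min = 0, max = 0.5)
  h_c <- fit$h_max - indenter$epsilon * fit$P_max / fit$S
  if (!is.finite(h_c) || h_c <= 0) {
    abort("oliver_pharr: contact depth collapse (h_c <= 0).",
          class = "ossindent_error_contact_collapse")
  }
  A <- contact_area(h_c, indenter)
  E_r <- sqrt(pi) / (2 * indenter$beta) * fit$S / sqrt(A) * 1e6  # GPa
  inv_sample <- 1 / E_r - (1 - indenter$nu_i^2) / indenter$E_i
  if (inv_sample <= 0) {
    abort("oliver_pharr: sample modulus non-positive after indenter correction.",
          class = "ossindent_error_nonphysical")
  }
  E <- (1 - nu_s^2) / inv_sample
  tibble::tibble(
    E_r_GPa = E_r, E_GPa = E, h_c_nm = h_c, A_nm2 = A,
    Hc_GPa = fit$P_max / A * 1e6,
    S_mN_nm = fit$S, P_max_mN = fit$P_max, h_max_nm = fit$h_max
  )
}

# projected area function A(h_c) in nm^2; optional calibration terms follow
# the standard exponent ladder h_c^1, h_c^(1/2), h_c^(1/4), ...
contact_area <- function(h_c, indenter) {
  A <- indenter$area_c0 * h_c^2
  ac <- indenter$area_coeffs
  if (length(ac)) {
    expo <- 2^(1 - seq_along(ac))
    A <- A + sum(ac * h_c^expo)
  }
  A
}

#' Decompose the loading curve into elastic and plastic resistances
#'
#' For a conical indenter the loading curve of an elastic-plastic contact
#' follows `P = K h^2` with the series decomposition
#' `1/sqrt(K) = 1/sqrt(C_e) + 1/sqrt(C_p)`, where
#' `C_e = (2/pi) E_r tan(psi)` is the purely elastic (Sneddon) coefficient
#' and `C_p` carries the plastic response. The resistance to plastic
#' deformation is `H = C_p / alpha1` with `alpha1` the area-function
#' constant (24.5 for an ideal tip), so that `H` has hardness units (GPa)
#' and coincides with the mean contact pressure a purely plastic contact of
#' the same area function would sustain.
#'
#' @param curve A segmented, drift-corrected indentation curve.
#' @param E_r Reduced modulus (GPa), usually from [oliver_pharr()].
#' @param indenter An [indenter_spec()].
#' @param h_cap Cap (GPa) above which the contact is reported as having no
#'   measurable plasticity (`H = NA` with a warning).
#' @param protocol Protocol used if the curve still needs segmenting.
#'
#' @return A one-row tibble with columns `H_GPa`, `K_mN_nm2`, `C_e_mN_nm2`,
#'   `C_p_mN_nm2`.
#' @export
decompose_loading <- function(curve,
                              E_r,
                              indenter = indenter_spec(),
                              h_cap = 100,
                              protocol = indentation_protocol()) {
  check_number(E_r, "E_r", min = 0, strict_min = TRUE)
  curve <- ensure_segmented(curve, protocol)
  ld <- curve[curve$phase == "loading", ]
  if (nrow(ld) < 5L) {
    abort("decompose_loading: loading phase absent or too short.",
          class = "ossindent_error_missing_phase")
  }
  # P = K h^2  <=>  h = P^(1/2) / sqrt(K); least squares in the depth
  # coordinate (where the noise lives), through the origin
  sq <- sqrt(ld$load_mN)
  slope <- sum(ld$depth_nm * sq) / sum(ld$load_mN)
  K <- slope^-2
  tanpsi <- tan(indenter$psi_deg * pi / 180)
  C_e <- (2 / pi) * E_r * 1e-6 * tanpsi
  slack <- 1 / sqrt(K) - 1 / sqrt(C_e)
  C_p <- if (slack > 0) slack^-2 else Inf
  H <- C_p / indenter$area_c0 * 1e6  # GPa
  if (!is.finite(H) || H > h_cap) {
    if (slack < -0.02 / sqrt(K)) {
      # loading distinctly stiffer than the purely elastic bound
      abort("decompose_loading: non-physical decomposition (K >= C_e).",
            class = "ossindent_error_nonphysical")
    }
    warn(sprintf(
      "decompose_loading: no measurable plasticity (H above %g GPa cap).", h_cap),
      class = "ossindent_warning_no_plasticity")
    H <- NA_real_
  }
  tibble::tibble(H_GPa = H, K_mN_nm2 = K, C_e_mN_nm2 = C_e, C_p_mN_nm2 = C_p)
}
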