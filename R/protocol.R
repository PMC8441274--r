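#' Indentation protocol description
#'
#' Describes the displacement-controlled indentation protocol: ramp to a
#' target depth at a fixed loading rate, hold at maximum load to let creep
#' run out, unload to a small fraction of maximum load, and hold there to
#' measure thermal drift.
#'
#' @param target_depth_nm Target indentation depth (nm).
#' @param loading_rate_mN_s Loading (and unloading) rate (mN/s).
#' @param hold_s Hold duration at maximum load (s).
#' @param drift_hold_s Hold duration at the low-load drift plateau (s).
#' @param drift_hold_fraction Fraction of maximum load held during the drift
#'   plateau (dimensionless, in (0, 1)).
#' @param ramp_hz,hold_hz Sampling rates (Hz) used by the curve simulator for
#'   the ramp phases and for the two constant-load holds.
#'
#' @return An object of class `indent_protocol`.
#' @export
#' @examples
#' indentation_protocol()
indentation_protocol <- function(target_depth_nm = 500,
                                 loading_rate_mN_s = 0.25,
                                 hold_s = 60,
                                 drift_hold_s = 100,
                                 drift_hold_fraction = 0.10,
                                 ramp_hz = 100,
                                 hold_hz = 10) {
  check_number(target_depth_nm, "target_depth_nm", min = 0, strict_min = TRUE)
  check_number(loading_rate_mN_s, "loading_rate_mN_s", min = 0, strict_min = TRUE)
  check_number(hold_s, "hold_s", min = 0)
  check_number(drift_hold_s, "drift_hold_s", min = 0)
  check_number(drift_hold_fraction, "drift_hold_fraction", min = 0, max = 1,
               strict_min = TRUE)
  if (drift_hold_fraction >= 1) {
    abort("`drift_hold_fraction` must be < 1.", class = "ossindent_error_invalid")
  }
  check_number(ramp_hz, "ramp_hz", min = 0, strict_min = TRUE)
  check_number(hold_hz, "hold_hz", min = 0, strict_min = TRUE)
  structure(
    list(target_depth_nm = target_depth_nm,
         loading_rate_mN_s = loading_rate_mN_s,
         hold_s = hold_s,
         drift_hold_s = drift_hold_s,
         drift_hold_fraction = drift_hold_fraction,
         ramp_hz = ramp_hz,
         hold_hz = hold_hz),
    class = "indent_protocol"
  )
}

#' Indenter and contact-mechanics parameters
#'
#' Parameters of the diamond tip and of the Oliver-Pharr reduction: indenter
#' elastic constants, the contact-depth geometry factor epsilon, the optional
#' stiffness correction beta, and the projected-area function
#' `A(h_c) = C0 * h_c^2 + sum_k C_k * h_c^(2^(1-k))`.
#'
#' The default `C0 = 24.5` is the ideal Berkovich/conical value
#' `pi * tan(psi)^2` for an effective cone half-angle of 70.3 degrees.
#'
#' @param E_i Indenter elastic modulus (GPa).
#' @param nu_i Indenter Poisson ratio.
#' @param epsilon Contact-depth geometry factor; 0.75 is the standard value
#'   for a Berkovich/paraboloid contact, [cone_epsilon()] the value for an
#'   ideal cone.
#' @param beta Stiffness correction factor (1.0 by default; 1.034 is a common
#'   Berkovich choice).
#' @param area_c0 Leading area-function coefficient (nm^2 per nm^2).
#' @param area_coeffs Optional higher-order area-function calibration
#'   coefficients `C_1, C_2, ...` applied to `h_c^1, h_c^(1/2), h_c^(1/4), ...`.
#' @param psi_deg Effective cone half-angle (degrees).
#'
#' @return An object of class `indenter_spec`.
#' @export
#' @examples
#' indenter_spec()
indenter_spec <- function(E_i = 1141,
                          nu_i = 0.07,
                          epsilon = 0.75,
                          beta = 1.0,
                          area_c0 = 24.5,
                          area_coeffs = numeric(0),
                          psi_deg = 70.3) {
  check_number(E_i, "E_i", min = 0, strict_min = TRUE)
  check_number(nu_i, "nu_i", min = 0, max = 0.5)
  check_number(epsilon, "epsilon", min = 0, max = 1, strict_min = TRUE)
  check_number(beta, "beta", min = 0, strict_min = TRUE)
  check_number(area_c0, "area_c0", min = 0, strict_min = TRUE)
  check_number(psi_deg, "psi_deg", min = 0, max = 90, strict_min = TRUE)
  stopifnot(is.numeric(area_coeffs))
  structure(
    list(E_i = E_i, nu_i = nu_i, epsilon = epsilon, beta = beta,
         area_c0 = area_c0, area_coeffs = area_coeffs, psi_deg = psi_deg),
    class = "indenter_spec"
  )
}

#' Geometry factor for an ideal conical contact
#'
#' The Oliver-Pharr contact-depth factor epsilon appropriate for a rigid
#' cone, `2 * (pi - 2) / pi` (about 0.727). Use it when reducing curves that
#' follow ideal conical (Sneddon) contact, such as the curves produced by
#' [simulate_curve()]; the package default of 0.75 is the empirical
#' Berkovich/paraboloid convention for instrument data.
#'
#' @return A single number.
#' @export
cone_epsilon <- function() 2 * (pi - 2) / pi

#' Material ground truth for the curve simulator
#'
#' @param E_s Sample elastic modulus (GPa).
#' @param H_true Resistance to plastic deformation (GPa); `Inf` simulates a
#'   purely elastic contact.
#' @param nu_s Sample Poisson ratio.
#' @param creep_amp_nm Creep depth amplitude over the maximum-load hold (nm).
#' @param drift_rate_nm_s Linear thermal drift rate added to depth (nm/s).
#' @param noise_sd_nm Gaussian depth noise standard deviation (nm).
#'
#' @return An object of class `material_truth`.
#' @export
#' @examples
#' material_truth(E_s = 16.2, H_true = 1.178)
material_truth <- function(E_s,
                           H_true,
                           nu_s = 0.3,
                           creep_amp_nm = 0,
                           drift_rate_nm_s = 0,
                           noise_sd_nm = 0) {
  check_number(E_s, "E_s", min = 0, strict_min = TRUE)
  if (!(is.numeric(H_true) && length(H_true) == 1L && H_true > 0)) {
    abort("`H_true` must be a single positive number (Inf allowed).",
          class = "ossindent_error_invalid")
  }
  check_number(nu_s, "nu_s", min = 0, max = 0.5)
  if (nu_s >= 0.5) abort("`nu_s` must be < 0.5.", class = "ossindent_error_invalid")
  check_number(creep_amp_nm, "creep_amp_nm", min = 0)
  if (!is.finite(drift_rate_nm_s)) {
    abort("`drift_rate_nm_s` must be finite.", class = "ossindent_error_invalid")
  }
  check_number(noise_sd_nm, "noise_sd_nm", min = 0)
  structure(
    list(E_s = E_s, H_true = H_true, nu_s = nu_s,
         creep_amp_nm = creep_amp_nm, drift_rate_nm_s = drift_rate_nm_s,
         noise_sd_nm = noise_sd_nm),
    class = "material_truth"
  )
}

#' Reduced modulus from sample and indenter elastic constants
#'
#' `1/E_r = (1 - nu_s^2)/E_s + (1 - nu_i^2)/E_i`, all moduli in GPa.
#'
#' @param E_s Sample modulus (GPa).
#' @param nu_s Sample Poisson ratio.
#' @param indenter An [indenter_spec()].
#' @return Reduced modulus (GPa).
#' @export
reduced_modulus <- function(E_s, nu_s = 0.3, indenter = indenter_spec()) {
  1 / ((1 - nu_s^2) / E_s + (1 - indenter$nu_i^2) / indenter$E_i)
}

# loading-curve coefficients (mN/nm^2) of the elastic-plastic series model:
# h(P) = sqrt(P/C_e) + sqrt(P/C_p), P = K h^2
ep_coefficients <- function(truth, indenter = indenter_spec()) {
  E_r <- reduced_modulus(truth$E_s, truth$nu_s, indenter)
  tanpsi <- tan(indenter$psi_deg * pi / 180)
  C_e <- (2 / pi) * E_r * 1e-6 * tanpsi        # GPa -> mN/nm^2
  C_p <- indenter$area_c0 * truth$H_true * 1e-6
  if (!is.finite(C_e) || C_e <= 0) {
    abort("non-physical material truth: elastic loading coefficient <= 0.",
          class = "ossindent_error_nonphysical")
  }
  if (!is.nan(C_p) && !is.na(C_p) && C_p <= 0) {
    abort("non-physical material truth: plastic loading coefficient <= 0.",
          class = "ossindent_error_nonphysical")
  }
  K <- if (is.finite(C_p)) (1 / sqrt(C_e) + 1 / sqrt(C_p))^-2 else C_e
  list(E_r = E_r, C_e = C_e, C_p = C_p, K = K)
}
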