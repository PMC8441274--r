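#' Elastic and plastic indentation energies
#'
#' Partitions the work of indentation: the total energy is the trapezoidal
#' integral of load over depth across the loading ramp and the maximum-load
#' creep hold (work is still done while depth grows at constant load); the
#' elastic (recovered) energy is the area under the unloading branch; the
#' plastic (dissipated) energy is their difference,
#' `Up = U_total - Ue`. With load in mN and depth in nm the integrals are
#' reported in picojoules via the exact identity 1 mN nm = 1 pJ.
#'
#' The unloading integral starts from the sample at unloading onset (the
#' last hold sample), so the elastic and total integrals share that
#' boundary point and `Ue + Up = U_total` holds exactly by construction.
#'
#' @param curve A segmented, drift-corrected indentation curve.
#' @param monotone_tol Fractional tolerance on retrograde depth steps within
#'   the loading/hold span before a warning is raised (integration then
#'   proceeds on the time-ordered samples regardless).
#' @param protocol Protocol used if the curve still needs segmenting.
#'
#' @return A one-row tibble with `U_total_pJ`, `Ue_pJ`, `Up_pJ`.
#' @export
#' @examples
#' crv <- simulate_curve(material_truth(16.2, 1.178))
#' indentation_energies(crv)
indentation_energies <- function(curve,
                                 monotone_tol = 0.02,
                                 protocol = indentation_protocol()) {
  curve <- ensure_segmented(curve, protocol)
  fwd <- curve[curve$phase %in% c("loading", "hold"), ]
  i_unl <- which(curve$phase == "unloading")
  if (nrow(fwd) < 2L || length(i_unl) < 2L) {
    abort("indentation_energies: loading or unloading phase missing.",
          class = "ossindent_error_missing_phase")
  }
  drops <- diff(fwd$depth_nm)
  noise_scale <- stats::mad(drops)  # tolerates sampling noise in depth
  if (any(drops < -(monotone_tol * max(fwd$depth_nm) + 6 * noise_scale))) {
    warn("indentation_energies: depth not monotone within loading/hold beyond tolerance; integrating in time order.",
         class = "ossindent_warning_nonmonotone")
  }
  U_total <- trapz(fwd$depth_nm, fwd$load_mN)
  # prepend the unloading-onset sample so both integrals share the peak
  i0 <- i_unl[1L] - 1L
  unl <- if (i0 >= 1L) curve[c(i0, i_unl), ] else curve[i_unl, ]
  Ue <- -trapz(unl$depth_nm, unl$load_mN)
  tibble::tibble(U_total_pJ = U_total, Ue_pJ = Ue, Up_pJ = U_total - Ue)
}
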