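#' Simulate one indentation force-depth curve
#'
#' Generates a four-phase displacement-controlled indentation curve from an
#' elastic-plastic conical contact model. The loading phase follows the
#' series decomposition `h(P) = sqrt(P/C_e) + sqrt(P/C_p)`, with
#' `C_e = (2/pi) E_r tan(psi)` the elastic (Sneddon cone) coefficient and
#' `C_p = C0 * H_true` the plastic coefficient (both converted to mN/nm^2).
#' The maximum-load hold adds logarithmic creep
#' `creep_amp * log(1 + t/10 s)`; unloading follows a power law
#' `P = B (h - h_f)^m` whose tangent at maximum load equals the elastic
#' contact stiffness implied by `E_s` and the contact area at maximum load
#' (`S = 2 sqrt(C_e P_max)` for the conical model); the final low-load hold
#' is flat. All phases carry additive linear depth drift `drift_rate * t`
#' and Gaussian depth noise.
#'
#' @param truth A [material_truth()].
#' @param protocol An [indentation_protocol()].
#' @param indenter An [indenter_spec()]; supplies the cone half-angle and
#'   area-function constant used by the forward model.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param unload_m Unloading exponent used for generation. The default 2 is
#'   the exponent of ideal conical elastic recovery.
#'
#' @return A tibble of class `indent_curve` with columns `time_s`,
#'   `load_mN`, `depth_nm` and a `phase` factor
#'   (`loading`, `hold`, `unloading`, `drift_hold`). The generating truth
#'   (including true phase boundaries, stiffness, `P_max` and `h_max`) is
#'   attached as attribute `"truth"`.
#' @export
#' @examples
#' crv <- simulate_curve(material_truth(E_s = 16.2, H_true = 1.178), seed = 1)
#' head(crv)
simulate_curve <- function(truth,
                           protocol = indentation_protocol(),
                           indenter = indenter_spec(),
                           seed = NULL,
                           unload_m = 2) {
  stopifnot(inherits(truth, "material_truth"),
            inherits(protocol, "indent_protocol"),
            inherits(indenter, "indenter_spec"))
  check_number(unload_m, "unload_m", min = 1, max = 2.5)
  cf <- ep_coefficients(truth, indenter)
  h_t <- protocol$target_depth_nm
  P_max <- cf$K * h_t^2
  rate <- protocol$loading_rate_mN_s
  tau_creep <- 10  # s, fixed creep time constant

  # --- loading ramp: P = rate * t up to and including P_max
  t_load <- P_max / rate
  n_load <- max(2L, ceiling(t_load * protocol$ramp_hz))
  tl <- seq(0, t_load, length.out = n_load + 1L)
  Pl <- rate * tl
  hl <- sqrt(Pl / cf$C_e) +
    if (is.finite(cf$C_p)) sqrt(Pl / cf$C_p) else 0

  # --- hold at P_max with logarithmic creep
  if (protocol$hold_s > 0) {
    n_hold <- max(1L, ceiling(protocol$hold_s * protocol$hold_hz))
    th <- seq(0, protocol$hold_s, length.out = n_hold + 1L)[-1L]
    Ph <- rep(P_max, n_hold)
    hh <- h_t + truth$creep_amp_nm * log1p(th / tau_creep)
  } else {
    th <- Ph <- hh <- numeric(0)
  }
  h_max <- if (length(hh)) hh[length(hh)] else h_t
  t_hold_end <- t_load + protocol$hold_s

  # --- unloading power law. The tangent at (h_max, P_max) is the elastic
  # stiffness implied by E_s and the contact area at maximum load:
  # S = 2 E_r tan(psi) h_c with h_c = h_max - eps * P_max / S (conical
  # geometry factor), i.e. the larger root of
  # S^2 - c h_max S + c eps P_max = 0 with c = pi C_e. In the purely
  # elastic limit this reduces exactly to the Sneddon cone stiffness
  # S = 2 sqrt(C_e P_max).
  cS <- pi * cf$C_e
  epsg <- cone_epsilon()
  disc <- (cS * h_max)^2 - 4 * cS * epsg * P_max
  S_true <- (cS * h_max + sqrt(disc)) / 2
  h_f <- h_max - unload_m * P_max / S_true
  B <- P_max / (h_max - h_f)^unload_m
  P_end <- protocol$drift_hold_fraction * P_max
  t_unload <- (P_max - P_end) / rate
  n_unl <- max(2L, ceiling(t_unload * protocol$ramp_hz))
  tu <- seq(0, t_unload, length.out = n_unl + 1L)[-1L]
  Pu <- P_max - rate * tu
  hu <- h_f + (Pu / B)^(1 / unload_m)

  # --- low-load drift hold (constant load, constant model depth)
  if (protocol$drift_hold_s > 0) {
    n_dh <- max(1L, ceiling(protocol$drift_hold_s * protocol$hold_hz))
    td <- seq(0, protocol$drift_hold_s, length.out = n_dh + 1L)[-1L]
    Pd <- rep(P_end, n_dh)
    hd <- rep(hu[length(hu)], n_dh)
  } else {
    td <- Pd <- hd <- numeric(0)
  }

  time_s <- c(tl, t_load + th, t_hold_end + tu, t_hold_end + t_unload + td)
  load_mN <- c(Pl, Ph, Pu, Pd)
  depth_nm <- c(hl, hh, hu, hd) + truth$drift_rate_nm_s * time_s
  if (truth$noise_sd_nm > 0) {
    depth_nm <- depth_nm + with_seed(seed, rnorm(length(depth_nm), 0, truth$noise_sd_nm))
  }
  phase <- factor(
    rep(c("loading", "hold", "unloading", "drift_hold"),
        c(length(tl), length(th), length(tu), length(td))),
    levels = phase_levels()
  )
  out <- tibble::tibble(time_s = time_s, load_mN = load_mN,
                        depth_nm = depth_nm, phase = phase)
  attr(out, "truth") <- c(
    unclass(truth),
    list(E_r = cf$E_r, C_e = cf$C_e, C_p = cf$C_p, K = cf$K,
         P_max = P_max, h_max = h_max, S = S_true,
         B = B, h_f = h_f, m = unload_m,
         boundaries_s = c(load_end = t_load, hold_end = t_hold_end,
                          unload_end = t_hold_end + t_unload),
         seed = seed)
  )
  class(out) <- c("indent_curve", class(out))
  out
}

phase_levels <- function() c("loading", "hold", "unloading", "drift_hold")

#' @export
print.indent_curve <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("<indent_curve> %d samples, %.1f s, P_max %.3g mN\n",
              nrow(x), max(x$time_s), max(x$load_mN)))
  if (!is.null(tr)) {
    cat(sprintf("  simulated truth: E_s %.3g GPa, H %.3g GPa\n", tr$E_s, tr$H_true))
  }
  NextMethod()
}
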