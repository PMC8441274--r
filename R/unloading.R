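#' Fit the Oliver-Pharr unloading power law
#'
#' Fits `P = B (h - h_f)^m` to the upper part of the unloading branch by
#' nonlinear least squares, with a multistart over the exponent
#' (`m = 1.2, 1.5, 2.0`; the candidate with the lowest residual sum of
#' squares wins) and `m` constrained to `[1, 2.5]`. The fitted span covers
#' `fit_fraction` of the unloading load range downward from maximum load.
#'
#' The unloading contact stiffness is the tangent at maximum load,
#' `S = B m (h_max - h_f)^(m-1)`, where `h_max` is the unloading-onset depth
#' evaluated from the fitted law at `P_max` (robust to single-sample depth
#' noise at the onset).
#'
#' @param curve A segmented (and ideally drift-corrected) indentation curve.
#' @param fit_fraction Fraction of the unloading load range, from `P_max`
#'   downward, used in the fit (default 0.8).
#' @param protocol Protocol used if the curve still needs segmenting.
#'
#' @return An object of class `unload_fit`: a list with elements `B`
#'   (mN/nm^m), `h_f` (nm), `m`, `S` (mN/nm), `P_max` (mN), `h_max` (nm),
#'   `residual_rms` (nm; the fit is least squares in the depth coordinate,
#'   which carries the measurement noise), `fit_fraction`, `n`. Supports
#'   [tidy()][generics::tidy] and [glance()][generics::glance].
#' @export
#' @examples
#' crv <- simulate_curve(material_truth(16.2, 1.178))
#' fit_unloading(crv)
fit_unloading <- function(curve,
                          fit_fraction = 0.8,
                          protocol = indentation_protocol()) {
  check_number(fit_fraction, "fit_fraction", min = 0, max = 1, strict_min = TRUE)
  curve <- ensure_segmented(curve, protocol)
  pk <- curve_peaks(curve)
  unl <- curve[pk$i_unload, ]
  if (nrow(unl) < 10L) {
    abort("fit_unloading: unloading phase has fewer than 10 samples.",
          class = "ossindent_error_invalid")
  }
  P_max <- pk$P_max
  P_lo <- min(unl$load_mN)
  P_cut <- P_max - fit_fraction * (P_max - P_lo)
  sel <- unl[unl$load_mN >= P_cut, ]
  if (nrow(sel) < 5L) sel <- unl

  h <- sel$depth_nm
  P <- sel$load_mN
  h_min <- min(h)
  span <- max(h) - h_min

  # Least squares in the depth coordinate (depth carries the measurement
  # noise; load is the controlled quantity): the inverse form of the power
  # law is h = h_f + a P^(1/m) with a = B^(-1/m).
  fits <- lapply(c(1.2, 1.5, 2.0), function(m0) {
    hf0 <- h_min - 0.25 * span
    a0 <- (max(h) - hf0) / P_max^(1 / m0)
    tryCatch(
      minpack.lm::nlsLM(
        h ~ h_f + a * P^(1 / m),
        start = list(a = a0, h_f = hf0, m = m0),
        lower = c(a = 1e-300, h_f = -Inf, m = 1),
        upper = c(a = Inf, h_f = Inf, m = 2.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) {
    abort("fit_unloading: power-law fit failed to converge from any start.",
          class = "ossindent_error_fit")
  }
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  a <- unname(cf["a"]); h_f <- unname(cf["h_f"]); m <- unname(cf["m"])
  B <- a^(-m)
  if (m <= 1 + 1e-6 || m >= 2.5 - 1e-6) {
    warn(sprintf("fit_unloading: exponent m = %.4f is at a bound.", m),
         class = "ossindent_warning_m_bound")
  }
  h_max <- h_f + (P_max / B)^(1 / m)
  structure(
    list(B = B, h_f = h_f, m = m,
         S = B * m * (h_max - h_f)^(m - 1),
         P_max = P_max, h_max = h_max,
         residual_rms = sqrt(min(rss) / nrow(sel)),
         fit_fraction = fit_fraction, n = nrow(sel)),
    class = "unload_fit"
  )
}

#' @export
print.unload_fit <- function(x, ...) {
  cat(sprintf(
    "<unload_fit> P = B (h - h_f)^m: B = %.4g mN/nm^m, h_f = %.4g nm, m = %.4g\n",
    x$B, x$h_f, x$m))
  cat(sprintf("  S = %.4g mN/nm at P_max = %.4g mN, h_max = %.4g nm (RMS %.3g nm, n = %d)\n",
              x$S, x$P_max, x$h_max, x$residual_rms, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.unload_fit <- function(x, ...) {
  tibble::tibble(
    term = c("B", "h_f", "m", "S"),
    estimate = c(x$B, x$h_f, x$m, x$S),
    unit = c("mN/nm^m", "nm", "", "mN/nm")
  )
}

#' @export
glance.unload_fit <- function(x, ...) {
  tibble::tibble(
    P_max_mN = x$P_max, h_max_nm = x$h_max, S_mN_nm = x$S,
    residual_rms_nm = x$residual_rms, fit_fraction = x$fit_fraction, n = x$n
  )
}
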