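#' Estimate and remove thermal drift from an indentation curve
#'
#' Thermal drift is estimated as the least-squares slope of depth versus time
#' over the low-load drift hold, excluding the first `exclude_s` seconds of
#' the hold (which can still contain viscoelastic recovery), and
#' `rate * time` is subtracted from every depth sample.
#'
#' @param curve A segmented [indent_curve][segment_curve()] (a raw record is
#'   segmented first).
#' @param exclude_s Seconds at the start of the drift hold excluded from the
#'   slope fit.
#' @param min_samples Minimum number of drift-hold samples (after exclusion)
#'   required to attempt a correction.
#' @param protocol Protocol used if the curve still needs segmenting.
#'
#' @return The curve with corrected depths; the estimated rate (nm/s) is
#'   attached as attribute `drift_rate_nm_s`. If the drift hold is absent or
#'   too short, a warning is issued and the curve is returned uncorrected
#'   (attribute `NA`).
#' @export
#' @examples
#' crv <- simulate_curve(material_truth(16.2, 1.178, drift_rate_nm_s = 0.05))
#' attr(correct_drift(crv), "drift_rate_nm_s")
correct_drift <- function(curve,
                          exclude_s = 20,
                          min_samples = 10L,
                          protocol = indentation_protocol()) {
  curve <- ensure_segmented(curve, protocol)
  idx <- which(curve$phase == "drift_hold")
  if (length(idx) < min_samples) {
    warn("correct_drift: drift hold absent or too short; no correction applied.",
         class = "ossindent_warning_no_drift_hold")
    attr(curve, "drift_rate_nm_s") <- NA_real_
    return(curve)
  }
  t0 <- curve$time_s[idx[1L]]
  keep <- idx[curve$time_s[idx] - t0 >= exclude_s]
  if (length(keep) < min_samples) {
    warn("correct_drift: drift hold shorter than the exclusion window; no correction applied.",
         class = "ossindent_warning_no_drift_hold")
    attr(curve, "drift_rate_nm_s") <- NA_real_
    return(curve)
  }
  fit <- lm(depth_nm ~ time_s, data = curve[keep, ])
  rate <- unname(coef(fit)[2L])
  curve$depth_nm <- curve$depth_nm - rate * curve$time_s
  attr(curve, "drift_rate_nm_s") <- rate
  curve
}
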