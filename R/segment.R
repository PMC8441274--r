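#' Segment a raw indentation record into protocol phases
#'
#' Assigns each sample of a raw (time, load, depth) record to one of the four
#' protocol phases — `loading`, `hold` (creep hold at maximum load),
#' `unloading`, `drift_hold` (low-load thermal-drift hold) — using the sign
#' of the load rate. Runs shorter than `min_run` samples are absorbed into
#' their neighbours so that isolated rate-sign flips from noise do not split
#' a phase. Maximum load is the hold-plateau load and maximum depth is the
#' depth at unloading onset (depth keeps growing by creep during the hold).
#'
#' @param data A data frame with numeric columns `time_s`, `load_mN`,
#'   `depth_nm`, in time order. Extra columns are preserved.
#' @param protocol An [indentation_protocol()]; used only for the load-rate
#'   scale that separates "ramping" from "constant load".
#' @param rate_tol Fraction of the protocol loading rate below which the
#'   local load rate counts as constant-load.
#' @param min_run Minimum run length (samples) for a phase segment.
#'
#' @return The input tibble with a `phase` factor column, classed
#'   `indent_curve`. A curve that never unloads is an error; an absent hold
#'   or drift hold is allowed (the phase is simply empty).
#' @export
#' @examples
#' crv <- simulate_curve(material_truth(16.2, 1.178), seed = 1)
#' raw <- crv[, c("time_s", "load_mN", "depth_nm")]
#' table(segment_curve(raw)$phase)
segment_curve <- function(data,
                          protocol = indentation_protocol(),
                          rate_tol = 0.2,
                          min_run = 3L) {
  check_columns(data, c("time_s", "load_mN", "depth_nm"), "segment_curve")
  n <- nrow(data)
  if (n < 50L) {
    abort("segment_curve: need at least 50 samples.",
          class = "ossindent_error_invalid")
  }
  if (!all(is.finite(data$time_s)) || !all(is.finite(data$load_mN)) ||
      !all(is.finite(data$depth_nm))) {
    abort("segment_curve: non-finite load, depth or time.",
          class = "ossindent_error_invalid")
  }
  if (any(diff(data$time_s) <= 0)) {
    abort("segment_curve: time must be strictly increasing.",
          class = "ossindent_error_invalid")
  }

  # classify each inter-sample step by load rate: +1 rising, -1 falling, 0
  # flat; the rate scale adapts to curves ramped slower than the protocol
  dP <- diff(data$load_mN) / diff(data$time_s)
  rate_scale <- min(protocol$loading_rate_mN_s,
                    stats::quantile(abs(dP), 0.95, names = FALSE))
  thr <- rate_tol * rate_scale
  step <- ifelse(dP > thr, 1L, ifelse(dP < -thr, -1L, 0L))

  # absorb runs shorter than min_run into the previous run
  r <- rle(step)
  while (length(r$lengths) > 1L && any(r$lengths < min_run)) {
    i <- which(r$lengths < min_run)[1L]
    j <- if (i == 1L) 2L else i - 1L
    r$lengths[j] <- r$lengths[j] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    r <- rle(inverse.rle(r))
  }
  runs <- tibble::tibble(
    value = r$values,
    len = r$lengths,
    end = cumsum(r$lengths),
    start = end - len + 1L
  )

  if (!length(runs$value) || runs$value[1L] != 1L) {
    abort("segment_curve: curve does not start with a loading ramp.",
          class = "ossindent_error_missing_phase")
  }
  fall <- which(runs$value == -1L)
  if (!length(fall)) {
    abort("segment_curve: missing unloading phase.",
          class = "ossindent_error_missing_phase")
  }
  i_unload <- fall[1L]

  # steps 1..n-1 map to samples: a sample takes the phase of the step before
  # it; sample 1 is loading.
  phase_of_step <- rep("loading", n - 1L)
  load_end_step <- runs$end[1L]
  unl_start <- runs$start[i_unload]
  unl_end <- runs$end[i_unload]
  # anything flat between the loading run and the unloading run is the hold
  if (unl_start > load_end_step + 1L) {
    phase_of_step[seq(load_end_step + 1L, unl_start - 1L)] <- "hold"
  }
  phase_of_step[seq(unl_start, unl_end)] <- "unloading"
  if (unl_end < n - 1L) {
    phase_of_step[seq(unl_end + 1L, n - 1L)] <- "drift_hold"
  }
  phase <- factor(c("loading", phase_of_step), levels = phase_levels())

  out <- tibble::as_tibble(data)
  out$phase <- phase
  # preserve simulator ground truth if present
  attr(out, "truth") <- attr(data, "truth", exact = TRUE)
  attr(out, "drift_rate_nm_s") <- attr(data, "drift_rate_nm_s", exact = TRUE)
  class(out) <- c("indent_curve", class(tibble::tibble()))
  out
}

# segmented curve or raw data -> segmented, idempotent
ensure_segmented <- function(data, protocol = indentation_protocol()) {
  if (!is.null(data$phase)) {
    out <- tibble::as_tibble(data)
    out$phase <- factor(as.character(out$phase), levels = phase_levels())
    attr(out, "truth") <- attr(data, "truth", exact = TRUE)
    attr(out, "drift_rate_nm_s") <- attr(data, "drift_rate_nm_s", exact = TRUE)
    class(out) <- c("indent_curve", class(tibble::tibble()))
    return(out)
  }
  segment_curve(data, protocol)
}

# peak summary of a segmented curve: P_max from the hold plateau (or ramp
# peak when the hold is empty), unloading-onset depth from the sample just
# before the unloading phase
curve_peaks <- function(curve) {
  ph <- curve$phase
  i_unl <- which(ph == "unloading")
  if (!length(i_unl)) {
    abort("missing unloading phase.", class = "ossindent_error_missing_phase")
  }
  i_hold <- which(ph == "hold")
  P_max <- if (length(i_hold)) median(curve$load_mN[i_hold]) else
    max(curve$load_mN[ph == "loading"])
  i_onset <- i_unl[1L] - 1L
  h_onset <- if (i_onset >= 1L) curve$depth_nm[i_onset] else curve$depth_nm[i_unl[1L]]
  list(P_max = P_max, h_onset = h_onset, i_unload = i_unl)
}
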