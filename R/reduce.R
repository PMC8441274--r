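#' Reduce one indentation curve to its nanomechanical properties
#'
#' Runs the full per-site reduction chain: segmentation (if needed), thermal
#' drift correction, unloading power-law fit, Oliver-Pharr contact
#' mechanics, elastic-plastic loading decomposition, and energy
#' integration.
#'
#' @param curve A raw or segmented indentation record (`time_s`, `load_mN`,
#'   `depth_nm`, optionally `phase`).
#' @param indenter An [indenter_spec()].
#' @param nu_s Sample Poisson ratio.
#' @param fit_fraction Unloading fit fraction, see [fit_unloading()].
#' @param protocol An [indentation_protocol()].
#' @param drift_exclude_s Seconds excluded at the start of the drift hold.
#'
#' @return A one-row tibble: `E_GPa`, `Hc_GPa`, `H_GPa`, `Ue_pJ`, `Up_pJ`,
#'   `U_total_pJ`, `S_mN_nm`, `h_c_nm`, `P_max_mN`, `h_max_nm`, `E_r_GPa`,
#'   `m`, `drift_rate_nm_s`, `valid` (logical), `note` (failure/warning
#'   text, `NA` when clean).
#' @export
#' @examples
#' crv <- simulate_curve(material_truth(16.2, 1.178), seed = 7)
#' extract_properties(crv, indenter = indenter_spec(epsilon = cone_epsilon()))
extract_properties <- function(curve,
                               indenter = indenter_spec(),
                               nu_s = 0.3,
                               fit_fraction = 0.8,
                               protocol = indentation_protocol(),
                               drift_exclude_s = 20) {
  notes <- character(0)
  res <- tryCatch(
    withCallingHandlers(
      {
        seg <- ensure_segmented(curve, protocol)
        seg <- correct_drift(seg, exclude_s = drift_exclude_s, protocol = protocol)
        fit <- fit_unloading(seg, fit_fraction = fit_fraction, protocol = protocol)
        op <- oliver_pharr(fit, indenter = indenter, nu_s = nu_s)
        dec <- decompose_loading(seg, E_r = op$E_r_GPa, indenter = indenter,
                                 protocol = protocol)
        en <- indentation_energies(seg, protocol = protocol)
        tibble::tibble(
          E_GPa = op$E_GPa, Hc_GPa = op$Hc_GPa, H_GPa = dec$H_GPa,
          Ue_pJ = en$Ue_pJ, Up_pJ = en$Up_pJ, U_total_pJ = en$U_total_pJ,
          S_mN_nm = op$S_mN_nm, h_c_nm = op$h_c_nm,
          P_max_mN = op$P_max_mN, h_max_nm = op$h_max_nm,
          E_r_GPa = op$E_r_GPa, m = fit$m,
          drift_rate_nm_s = attr(seg, "drift_rate_nm_s") %||% NA_real_,
          valid = TRUE, note = NA_character_
        )
      },
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) {
      tibble::tibble(
        E_GPa = NA_real_, Hc_GPa = NA_real_, H_GPa = NA_real_,
        Ue_pJ = NA_real_, Up_pJ = NA_real_, U_total_pJ = NA_real_,
        S_mN_nm = NA_real_, h_c_nm = NA_real_, P_max_mN = NA_real_,
        h_max_nm = NA_real_, E_r_GPa = NA_real_, m = NA_real_,
        drift_rate_nm_s = NA_real_,
        valid = FALSE, note = conditionMessage(e)
      )
    }
  )
  if (res$valid && length(notes)) res$note <- paste(notes, collapse = " | ")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce a long table of indentation curves site by site
#'
#' @param data A long data frame of curve samples with id columns
#'   (`specimen`, `compartment`, `trabecula`, `site` — any subset present is
#'   used) plus `time_s`, `load_mN`, `depth_nm` and optionally `phase`.
#' @param ... Passed to [extract_properties()].
#'
#' @return A tibble with one row per site: the id columns followed by the
#'   property columns of [extract_properties()].
#' @export
reduce_curves <- function(data, ...) {
  check_columns(data, c("time_s", "load_mN", "depth_nm"), "reduce_curves")
  ids <- intersect(c("specimen", "compartment", "trabecula", "site"), names(data))
  if (!length(ids)) {
    abort("reduce_curves: no site id columns (specimen/compartment/trabecula/site).",
          class = "ossindent_error_invalid")
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_modify(function(d, key) extract_properties(d, ...)) |>
    dplyr::ungroup()
}

#' Aggregate site-level properties to the specimen level
#'
#' Cortical sites are averaged directly (mean and SD over valid sites).
#' Cancellous sites are averaged hierarchically: each trabecula's sites are
#' averaged first, then the specimen mean is the mean of per-trabecula
#' means and the SD is taken across trabecula means, so an unbalanced
#' trabecula still contributes exactly one mean.
#'
#' @param data Site-level property tibble (e.g. from [reduce_curves()] or
#'   [simulate_cohort()]); needs `specimen` (or `subject_id`),
#'   `compartment` (`"cortical"`/`"cancellous"`), `trabecula` for
#'   cancellous rows, a logical `valid` column (optional; `NA` property
#'   rows are dropped), and the property columns named in `properties`.
#' @param properties Character vector of property column names to
#'   aggregate.
#'
#' @return A tibble with one row per specimen x compartment x property:
#'   `mean`, `sd`, `n_sites`, `n_failed`. Specimens whose compartment has
#'   zero valid sites appear with `n_sites = 0` and `NA` summaries.
#' @export
aggregate_sites <- function(data,
                            properties = intersect(
                              c("E_GPa", "Hc_GPa", "H_GPa", "Ue_pJ", "Up_pJ"),
                              names(data))) {
  id_col <- if ("specimen" %in% names(data)) "specimen" else "subject_id"
  check_columns(data, c(id_col, "compartment"), "aggregate_sites")
  if (!length(properties)) {
    abort("aggregate_sites: no property columns found.",
          class = "ossindent_error_invalid")
  }
  long <- data |>
    tidyr::pivot_longer(dplyr::all_of(properties),
                        names_to = "property", values_to = "value") |>
    dplyr::mutate(ok = if ("valid" %in% names(data)) .data$valid & !is.na(.data$value)
                  else !is.na(.data$value))

  summarize_flat <- function(d) {
    v <- d$value[d$ok]
    tibble::tibble(mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1L) sd(v) else if (length(v)) 0 else NA_real_,
                   n_sites = length(v), n_failed = sum(!d$ok))
  }

  cort <- long |> dplyr::filter(.data$compartment == "cortical")
  cort <- if (nrow(cort)) {
    cort |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(id_col, "compartment", "property")))) |>
      dplyr::group_modify(function(d, key) summarize_flat(d)) |>
      dplyr::ungroup()
  } else NULL

  canc <- long |> dplyr::filter(.data$compartment == "cancellous")
  canc <- if (nrow(canc)) {
    if (!"trabecula" %in% names(canc)) {
      abort("aggregate_sites: cancellous rows need a `trabecula` column.",
            class = "ossindent_error_invalid")
    }
    canc <- canc |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c(id_col, "compartment", "property", "trabecula")))) |>
      dplyr::summarise(
        tmean = if (any(.data$ok)) mean(.data$value[.data$ok]) else NA_real_,
        n_ok = sum(.data$ok), n_bad = sum(!.data$ok), .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(id_col, "compartment", "property")))) |>
      dplyr::summarise(
        mean = if (any(!is.na(.data$tmean))) mean(.data$tmean, na.rm = TRUE) else NA_real_,
        sd = if (sum(!is.na(.data$tmean)) > 1L) sd(.data$tmean, na.rm = TRUE)
             else if (any(!is.na(.data$tmean))) 0 else NA_real_,
        n_sites = sum(.data$n_ok), n_failed = sum(.data$n_bad), .groups = "drop")
  } else NULL
  dplyr::bind_rows(cort, canc) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(id_col, "compartment", "property"))))
}
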