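#' Structural histomorphometry indices
#'
#' Derives the structural indices from area/perimeter primitives:
#' `BV/TV = 100 * bone_area / tissue_area` (%),
#' `Tb.Th = 2000 * bone_area / bone_perimeter` (um, plate model, areas in
#' mm^2 and perimeter in mm), `Tb.N = (BV/TV / 100) / (Tb.Th / 1000)`
#' (per mm), and `Ct.Th` (mm) as the mean of the cortical thickness
#' readings (um) divided by 1000.
#'
#' @param data A data frame with columns `bone_area_mm2`, `tissue_area_mm2`,
#'   `bone_perimeter_mm`, and either a list-column `ct_th_um` of readings or
#'   a numeric column of per-subject means. Id columns are preserved.
#'
#' @return The input id columns plus `BV_TV_pct`, `Tb_Th_um`, `Tb_N_per_mm`,
#'   `Ct_Th_mm`.
#' @export
#' @examples
#' structural_indices(data.frame(bone_area_mm2 = 0.15, tissue_area_mm2 = 1,
#'                               bone_perimeter_mm = 2.8, ct_th_um = 987))
structural_indices <- function(data) {
  check_columns(data, c("bone_area_mm2", "tissue_area_mm2", "bone_perimeter_mm"),
                "structural_indices")
  if (any(data$tissue_area_mm2 <= 0)) {
    abort("structural_indices: tissue area must be positive.",
          class = "ossindent_error_invalid")
  }
  if (any(data$bone_area_mm2 < 0 | data$bone_area_mm2 > data$tissue_area_mm2)) {
    abort("structural_indices: bone area must lie in [0, tissue area].",
          class = "ossindent_error_invalid")
  }
  if (any(data$bone_perimeter_mm <= 0 & data$bone_area_mm2 > 0)) {
    abort("structural_indices: bone perimeter must be positive when bone is present.",
          class = "ossindent_error_invalid")
  }
  ct <- if ("ct_th_um" %in% names(data)) {
    vapply(data$ct_th_um, function(x) mean(as.numeric(x)), numeric(1))
  } else NA_real_
  bvtv <- 100 * data$bone_area_mm2 / data$tissue_area_mm2
  tbth <- 2000 * data$bone_area_mm2 / data$bone_perimeter_mm
  out <- tibble::as_tibble(data[, setdiff(names(data),
    c("bone_area_mm2", "tissue_area_mm2", "bone_perimeter_mm", "ct_th_um")),
    drop = FALSE])
  out$BV_TV_pct <- bvtv
  out$Tb_Th_um <- tbth
  out$Tb_N_per_mm <- (bvtv / 100) / (tbth / 1000)
  out$Ct_Th_mm <- ct / 1000
  out
}

check_envelope_primitives <- function(data, fn) {
  check_columns(data, c("BS_mm", "OS_mm", "ES_mm", "ObS_mm", "OcS_mm",
                        "dLS_mm", "sLS_mm", "label_interval_d"), fn)
  if (any(data$BS_mm <= 0)) {
    abort(sprintf("%s: bone surface BS must be positive.", fn),
          class = "ossindent_error_invalid")
  }
  lens <- data[, c("OS_mm", "ES_mm", "ObS_mm", "OcS_mm", "dLS_mm", "sLS_mm")]
  if (any(as.matrix(lens) < 0)) {
    abort(sprintf("%s: surface lengths must be non-negative.", fn),
          class = "ossindent_error_invalid")
  }
  if (any(as.matrix(lens) > data$BS_mm + 1e-9)) {
    abort(sprintf("%s: a surface length exceeds the total bone surface.", fn),
          class = "ossindent_error_invalid")
  }
  if (any(data$dLS_mm + data$sLS_mm > data$BS_mm + 1e-9)) {
    abort(sprintf("%s: double plus single label length exceeds the bone surface.", fn),
          class = "ossindent_error_invalid")
  }
  invisible(data)
}

list_mean <- function(col) {
  vapply(col, function(x) {
    x <- as.numeric(x)
    if (!length(x)) NA_real_ else mean(x)
  }, numeric(1))
}

#' Static histomorphometry indices for one envelope
#'
#' Each surface index is the measured surface length as a percent of the
#' total bone surface (`100 * length / BS`); osteoid thickness `O.Th` and
#' wall thickness `W.Th` are the means of their reading lists (um).
#'
#' @param data A primitives data frame (see
#'   [simulate_envelope_primitives()] for the column contract). Thickness
#'   readings may be list-columns (`o_th_um`, `w_th_um`) or numeric means.
#'
#' @return Id columns plus `ES_BS_pct`, `OS_BS_pct`, `ObS_BS_pct`,
#'   `OcS_BS_pct`, `O_Th_um`, `W_Th_um`.
#' @export
static_indices <- function(data) {
  check_envelope_primitives(data, "static_indices")
  o_th <- if (is.list(data$o_th_um)) list_mean(data$o_th_um) else data$o_th_um
  w_th <- if (is.list(data$w_th_um)) list_mean(data$w_th_um) else data$w_th_um
  keep <- setdiff(names(data), c("OS_mm", "ES_mm", "ObS_mm", "OcS_mm",
                                 "o_th_um", "w_th_um"))
  out <- tibble::as_tibble(data[, keep, drop = FALSE])
  out$ES_BS_pct <- 100 * data$ES_mm / data$BS_mm
  out$OS_BS_pct <- 100 * data$OS_mm / data$BS_mm
  out$ObS_BS_pct <- 100 * data$ObS_mm / data$BS_mm
  out$OcS_BS_pct <- 100 * data$OcS_mm / data$BS_mm
  out$O_Th_um <- o_th
  out$W_Th_um <- w_th
  out
}

#' Tetracycline-based dynamic histomorphometry indices
#'
#' Derives the dynamic remodeling indices with the standard imputation
#' rules:
#' * `MS/BS = 100 * (dLS + sLS/2) / BS` (%), the double-label plus
#'   half-single-label convention;
#' * `MAR` is the mean interlabel distance divided by the label interval
#'   when double labels are present; for single-label-only surfaces a floor
#'   of 0.3 um/day is assigned; with no label at all `MAR` is missing and
#'   `MS/BS`, `BFR/BS`, and `Ac.f` are set to zero;
#' * `BFR/BS = MAR * (MS/BS / 100) * 365` (um^3/um^2/year);
#' * `Ac.f = (BFR/BS) / W.Th` (per year).
#'
#' @param data A primitives data frame (list-column `interlabel_um` holds
#'   the interlabel distance readings in um).
#' @param w_th_um Wall thickness per row (um); defaults to the mean of the
#'   `w_th_um` column.
#' @param mar_floor MAR floor (um/day) assigned to single-label-only
#'   surfaces.
#'
#' @return Id columns plus `MS_BS_pct`, `MAR_um_day` (NA when no label),
#'   `BFR_BS_um3_um2_yr`, `Ac_f_per_yr`.
#' @export
#' @examples
#' prim <- simulate_envelope_primitives(cohort_spec(n_per_group = 4),
#'                                      "cancellous", seed = 2)
#' dynamic_indices(prim)[, c("subject_id", "MS_BS_pct", "MAR_um_day")]
dynamic_indices <- function(data, w_th_um = NULL, mar_floor = 0.3) {
  check_envelope_primitives(data, "dynamic_indices")
  check_columns(data, "interlabel_um", "dynamic_indices")
  if (is.null(w_th_um)) {
    check_columns(data, "w_th_um", "dynamic_indices")
    w_th_um <- if (is.list(data$w_th_um)) list_mean(data$w_th_um) else data$w_th_um
  }
  if (any(!is.na(w_th_um) & w_th_um <= 0)) {
    abort("dynamic_indices: wall thickness must be positive.",
          class = "ossindent_error_invalid")
  }
  dists <- data$interlabel_um
  if (any(vapply(dists, function(x) any(as.numeric(x) < 0), logical(1)))) {
    abort("dynamic_indices: negative interlabel distances.",
          class = "ossindent_error_invalid")
  }
  n <- nrow(data)
  ms <- 100 * (data$dLS_mm + data$sLS_mm / 2) / data$BS_mm
  mar <- numeric(n)
  for (i in seq_len(n)) {
    if (data$dLS_mm[i] > 0) {
      d <- as.numeric(dists[[i]])
      if (!length(d)) {
        abort(sprintf(
          "dynamic_indices: row %d has double labels but no interlabel readings.", i),
          class = "ossindent_error_invalid")
      }
      mar[i] <- mean(d) / data$label_interval_d[i]
    } else if (data$sLS_mm[i] > 0) {
      mar[i] <- mar_floor
    } else {
      mar[i] <- NA_real_   # no label: MAR missing, rates zeroed
      ms[i] <- 0
    }
  }
  bfr <- ifelse(is.na(mar), 0, mar * (ms / 100) * 365)
  acf <- ifelse(is.na(mar), 0, bfr / w_th_um)
  keep <- setdiff(names(data), c("dLS_mm", "sLS_mm", "interlabel_um",
                                 "w_th_um", "label_interval_d",
                                 "OS_mm", "ES_mm", "ObS_mm", "OcS_mm",
                                 "o_th_um"))
  out <- tibble::as_tibble(data[, keep, drop = FALSE])
  out$MS_BS_pct <- ms
  out$MAR_um_day <- mar
  out$BFR_BS_um3_um2_yr <- bfr
  out$Ac_f_per_yr <- acf
  out
}

#' All static and dynamic indices for a primitives table
#'
#' Convenience wrapper running [static_indices()] and [dynamic_indices()]
#' on a per-subject-envelope primitives table and joining the results.
#'
#' @inheritParams dynamic_indices
#' @return One row per input row with all derived index columns.
#' @export
histo_indices <- function(data, mar_floor = 0.3) {
  st <- static_indices(data)
  dyn <- dynamic_indices(data, w_th_um = st$W_Th_um, mar_floor = mar_floor)
  dyn_cols <- c("MS_BS_pct", "MAR_um_day", "BFR_BS_um3_um2_yr", "Ac_f_per_yr")
  dplyr::bind_cols(st[, setdiff(names(st), c("BS_mm", "dLS_mm", "sLS_mm",
                                             "interlabel_um", "label_interval_d"))],
                   dyn[, dyn_cols])
}
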