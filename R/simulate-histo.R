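#' Simulate per-subject envelope primitives for one bone envelope
#'
#' Emulates the raw measurements behind a histomorphometry report for one
#' envelope: total bone surface length, osteoid/eroded/osteoblast/osteoclast
#' surface lengths, osteoid and wall thickness readings, tetracycline
#' double/single label lengths, and interlabel distance readings.
#' Per-subject index targets are drawn from the group summaries in
#' `spec$histo`, then converted to mutually consistent primitives (surface
#' lengths never exceed the total surface; double plus single label length
#' never exceeds the surface). A configurable fraction of subjects receives
#' single-label-only or unlabeled envelopes so that downstream imputation
#' rules are exercised.
#'
#' @param spec A [cohort_spec()].
#' @param envelope `"cancellous"`, `"intracortical"`, or `"endosteal"`.
#' @param seed Optional integer seed.
#' @param cohort Optional cohort tibble from [simulate_cohort()]; when
#'   omitted, a balanced cohort of `2 * n_per_group` subjects is assumed.
#' @param label_interval_d Interlabel interval in days (14 by default, the
#'   usual in vivo double-labeling schedule).
#'
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `envelope`, `BS_mm`, `OS_mm`, `ES_mm`, `ObS_mm`, `OcS_mm`, `dLS_mm`,
#'   `sLS_mm`, `label_interval_d`, and list-columns `o_th_um`, `w_th_um`,
#'   `interlabel_um` holding the individual readings.
#' @export
#' @examples
#' prim <- simulate_envelope_primitives(cohort_spec(n_per_group = 4),
#'                                      "cancellous", seed = 1)
#' prim[1:3, c("subject_id", "BS_mm", "dLS_mm", "sLS_mm")]
simulate_envelope_primitives <- function(spec = cohort_spec(),
                                         envelope = c("cancellous",
                                                      "intracortical",
                                                      "endosteal"),
                                         seed = NULL,
                                         cohort = NULL,
                                         label_interval_d = 14) {
  stopifnot(inherits(spec, "cohort_spec"))
  envelope <- match.arg(envelope)
  check_number(label_interval_d, "label_interval_d", min = 0, strict_min = TRUE)
  if (is.null(cohort)) {
    n <- 2L * spec$n_per_group
    cohort <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = factor(rep(c("nonAFF", "AFF"), each = spec$n_per_group),
                     levels = c("nonAFF", "AFF")))
  }
  n <- nrow(cohort)
  ht <- spec$histo[spec$histo$envelope == envelope, ]
  tgt <- function(par, grp, what) {
    r <- ht[ht$parameter == par & ht$group == grp, ]
    if (!nrow(r)) return(NA_real_)
    r[[what]][1L]
  }
  g <- as.character(cohort$group)
  draw <- function(par, lower = 0, upper = Inf) {
    rnorm_trunc(n,
                vapply(g, function(gg) tgt(par, gg, "mean"), numeric(1)),
                vapply(g, function(gg) tgt(par, gg, "sd"), numeric(1)),
                lower, upper)
  }

  with_seed(seed, {
    bs_mean <- switch(envelope, cancellous = 20, intracortical = 15, endosteal = 8)
    BS <- rnorm_trunc(n, bs_mean, 0.1 * bs_mean, lower = 0.2 * bs_mean)

    os_pct <- draw("OS/BS", 0, 95)
    es_pct <- draw("ES/BS", 0, 95)
    obs_pct <- draw("Ob.S/BS", 0, 95)
    ocs_pct <- draw("Oc.S/BS", 0, 95)
    o_th <- draw("O.Th", 0.5)
    w_th <- draw("W.Th", 5)

    # label status: none / single-only / double
    u <- runif(n)
    status <- ifelse(u < spec$fraction_no_label, "none",
                     ifelse(u < spec$fraction_no_label + spec$fraction_single_label,
                            "single", "double"))

    mar <- draw("MAR", 0.305)
    bfr <- draw("BFR/BS", 0.05)
    ms_pct <- pmin(100 * bfr / (mar * 365), 60)

    dLS <- sLS <- numeric(n)
    interlabel <- vector("list", n)
    n_read <- 5L
    for (i in seq_len(n)) {
      if (status[i] == "double") {
        # dLS + sLS/2 = (MS/BS) * BS, with single length 60% of double
        dLS[i] <- (ms_pct[i] / 100) * BS[i] / 1.3
        sLS[i] <- 0.6 * dLS[i]
        interlabel[[i]] <- rnorm_trunc(n_read, mar[i] * label_interval_d,
                                       0.10 * mar[i] * label_interval_d,
                                       lower = 0.1)
      } else if (status[i] == "single") {
        sLS[i] <- 2 * (ms_pct[i] / 100) * BS[i]
        interlabel[[i]] <- numeric(0)
      } else {
        interlabel[[i]] <- numeric(0)
      }
    }

    tibble::tibble(
      subject_id = cohort$subject_id,
      group = cohort$group,
      envelope = envelope,
      BS_mm = BS,
      OS_mm = os_pct / 100 * BS,
      ES_mm = es_pct / 100 * BS,
      ObS_mm = obs_pct / 100 * BS,
      OcS_mm = ocs_pct / 100 * BS,
      dLS_mm = dLS,
      sLS_mm = pmin(sLS, BS - dLS),
      label_interval_d = label_interval_d,
      o_th_um = lapply(o_th, function(m) rnorm_trunc(4L, m, 0.15 * m, lower = 0.1)),
      w_th_um = lapply(w_th, function(m) rnorm_trunc(5L, m, 0.12 * m, lower = 1)),
      interlabel_um = interlabel
    )
  })
}

#' Simulate per-subject structural primitives
#'
#' Generates the area/perimeter measurements behind the structural indices:
#' cancellous bone area and tissue area (giving BV/TV), bone perimeter
#' (giving trabecular thickness under the plate model), and cortical
#' thickness readings.
#'
#' @inheritParams simulate_envelope_primitives
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `bone_area_mm2`, `tissue_area_mm2`, `bone_perimeter_mm`, and
#'   list-column `ct_th_um` of cortical thickness readings (um).
#' @export
simulate_structural_primitives <- function(spec = cohort_spec(),
                                           seed = NULL,
                                           cohort = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(cohort)) {
    n <- 2L * spec$n_per_group
    cohort <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = factor(rep(c("nonAFF", "AFF"), each = spec$n_per_group),
                     levels = c("nonAFF", "AFF")))
  }
  n <- nrow(cohort)
  ht <- spec$histo
  tgt <- function(par, env, grp, what) {
    r <- ht[ht$parameter == par & ht$envelope == env & ht$group == grp, ]
    if (!nrow(r)) return(NA_real_)
    r[[what]][1L]
  }
  g <- as.character(cohort$group)
  with_seed(seed, {
    tissue <- rnorm_trunc(n, 30, 1.5, lower = 10)  # mm^2 of cancellous tissue
    bvtv <- rnorm_trunc(n,
                        vapply(g, function(gg) tgt("BV/TV", "cancellous", gg, "mean"), numeric(1)),
                        vapply(g, function(gg) tgt("BV/TV", "cancellous", gg, "sd"), numeric(1)),
                        2, 60)
    tbth <- rnorm_trunc(n,
                        vapply(g, function(gg) tgt("Tb.Th", "cancellous", gg, "mean"), numeric(1)),
                        vapply(g, function(gg) tgt("Tb.Th", "cancellous", gg, "sd"), numeric(1)),
                        30)
    ctth_mm <- rnorm_trunc(n,
                           vapply(g, function(gg) tgt("Ct.Th", "intracortical", gg, "mean"), numeric(1)),
                           vapply(g, function(gg) tgt("Ct.Th", "intracortical", gg, "sd"), numeric(1)),
                           0.2)
    bone_area <- bvtv / 100 * tissue
    perimeter <- 2000 * bone_area / tbth  # plate model inverted
    tibble::tibble(
      subject_id = cohort$subject_id,
      group = cohort$group,
      bone_area_mm2 = bone_area,
      tissue_area_mm2 = tissue,
      bone_perimeter_mm = perimeter,
      ct_th_um = lapply(ctth_mm * 1000,
                        function(m) rnorm_trunc(4L, m, 0.08 * m, lower = 50))
    )
  })
}
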