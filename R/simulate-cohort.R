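#' Reference group summaries for the synthetic cohort generator
#'
#' Calibration targets (per-group mean and SD) for the histomorphometry
#' generator, representative of postmenopausal women on long-term
#' bisphosphonate therapy with and without an atypical femur fracture
#' (AFF): structural indices, static and tetracycline-based dynamic indices
#' on the cancellous, intracortical, and endosteal envelopes.
#'
#' @return A tibble with columns `parameter`, `envelope`, `group`, `mean`,
#'   `sd`. Units follow the conventional index units: percentages for
#'   surface fractions and BV/TV, micrometres for thicknesses (`Ct.Th` in
#'   mm), `MAR` in um/day, `BFR/BS` in um^3/um^2/year, `Ac.f` per year.
#' @export
histo_targets <- function() {
  rows <- list(
    # parameter,   envelope,        nonAFF mean, sd,   AFF mean, sd
    c("BV/TV",     "cancellous",    15.2, 5.10,  14.1, 5.47),
    c("BV/TV",     "intracortical", 95.3, 1.41,  93.9, 3.75),
    c("Tb.Th",     "cancellous",    107,  24.5,  103,  25.9),
    c("Ct.Th",     "intracortical", 0.987, 0.278, 1.02, 0.302),
    c("W.Th",      "cancellous",    33.6, 3.69,  29.8, 4.61),
    c("W.Th",      "intracortical", 42.6, 4.66,  36.1, 4.22),
    c("W.Th",      "endosteal",     37.2, 4.36,  33.3, 5.50),
    c("ES/BS",     "cancellous",    2.10, 1.80,  3.62, 3.22),
    c("ES/BS",     "intracortical", 2.26, 2.78,  3.57, 1.97),
    c("ES/BS",     "endosteal",     3.44, 3.70,  7.44, 8.66),
    c("Oc.S/BS",   "cancellous",    0.298, 0.328, 0.979, 1.21),
    c("Oc.S/BS",   "intracortical", 0.288, 0.479, 0.567, 0.342),
    c("Oc.S/BS",   "endosteal",     0.604, 0.932, 2.19, 2.72),
    c("OS/BS",     "cancellous",    1.96, 2.42,  5.21, 7.70),
    c("OS/BS",     "intracortical", 5.10, 3.98,  8.09, 6.35),
    c("OS/BS",     "endosteal",     5.18, 4.39,  7.75, 7.20),
    c("O.Th",      "cancellous",    8.08, 5.00,  7.40, 3.18),
    c("O.Th",      "intracortical", 6.51, 2.34,  7.40, 3.32),
    c("O.Th",      "endosteal",     5.38, 3.40,  5.87, 2.95),
    c("Ob.S/BS",   "cancellous",    0.357, 0.697, 1.05, 1.63),
    c("Ob.S/BS",   "intracortical", 0.867, 1.16,  1.77, 2.22),
    c("Ob.S/BS",   "endosteal",     0.803, 0.733, 2.41, 3.35),
    c("MAR",       "cancellous",    0.323, 0.148, 0.359, 0.179),
    c("MAR",       "intracortical", 0.331, 0.216, 0.356, 0.139),
    c("MAR",       "endosteal",     0.311, 0.263, 0.268, 0.129),
    c("BFR/BS",    "cancellous",    1.51, 2.35,  2.01, 2.81),
    c("BFR/BS",    "intracortical", 5.02, 5.36,  5.10, 6.23),
    c("BFR/BS",    "endosteal",     2.63, 3.58,  3.36, 5.43)
  )
  m <- do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(parameter = r[1], envelope = r[2],
                   group = c("nonAFF", "AFF"),
                   mean = as.numeric(r[c(3, 5)]),
                   sd = as.numeric(r[c(4, 6)]))
  }))
  m
}

#' Reference nanomechanical group summaries for the generator
#'
#' Per-group site-level means and SDs of elastic modulus (`E`, GPa),
#' resistance to plastic deformation (`H`, GPa), and contact hardness
#' (`Hc`, GPa) in cortical and cancellous bone. Group means for cortical
#' bone follow representative AFF/non-AFF indentation values; the SDs are
#' typical site-to-site scatter for bone nanoindentation.
#'
#' @return A tibble with columns `property`, `compartment`, `group`,
#'   `mean`, `sd`.
#' @export
mech_targets <- function() {
  rows <- list(
    c("E_GPa",  "cortical",   16.2, 18.6, 3.0),
    c("E_GPa",  "cancellous", 16.0, 16.0, 3.0),
    c("H_GPa",  "cortical",   1.178, 1.63, 0.35),
    c("H_GPa",  "cancellous", 1.80, 1.80, 0.40),
    c("Hc_GPa", "cortical",   0.77, 0.56, 0.20),
    c("Hc_GPa", "cancellous", 0.70, 0.70, 0.20)
  )
  do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(property = r[1], compartment = r[2],
                   group = c("nonAFF", "AFF"),
                   mean = as.numeric(r[3:4]), sd = as.numeric(r[5]))
  }))
}

#' Specification of a synthetic nested case-control cohort
#'
#' @param n_per_group Subjects per arm (AFF / non-AFF).
#' @param or_per_gpa True odds ratio for AFF per 1 GPa of subject-mean
#'   cortical elastic modulus. With 1.0 the AFF label is independent of the
#'   mechanics (balanced arms); otherwise the label is drawn from a
#'   logistic model with slope `log(or_per_gpa)`.
#' @param icc Intraclass correlation of site-level properties within a
#'   subject (subject random-intercept share of the total variance).
#' @param duration_mean,duration_sd Named vectors (`nonAFF`, `AFF`) of
#'   bisphosphonate treatment duration (years); durations are truncated at
#'   2 years (the cohort's entry criterion).
#' @param mech Property targets, see [mech_targets()].
#' @param histo Histomorphometry targets, see [histo_targets()].
#' @param n_cortical_sites Indentation sites per specimen in cortical bone.
#' @param n_trabeculae,n_sites_per_trabecula Cancellous sampling design.
#' @param fraction_single_label,fraction_no_label Expected fraction of
#'   subject-envelopes with only single tetracycline labels / with no label
#'   (exercises the MAR imputation rules).
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 16,
                        or_per_gpa = 1.13,
                        icc = 0.5,
                        duration_mean = c(nonAFF = 7.5, AFF = 11.5),
                        duration_sd = c(nonAFF = 4.7, AFF = 4.9),
                        mech = mech_targets(),
                        histo = histo_targets(),
                        n_cortical_sites = 60,
                        n_trabeculae = 5,
                        n_sites_per_trabecula = 12,
                        fraction_single_label = 0.15,
                        fraction_no_label = 0.15) {
  check_number(n_per_group, "n_per_group", min = 2)
  check_number(or_per_gpa, "or_per_gpa", min = 0, strict_min = TRUE)
  check_number(icc, "icc", min = 0, max = 1)
  if (icc >= 1) abort("`icc` must be < 1.", class = "ossindent_error_invalid")
  stopifnot(all(c("nonAFF", "AFF") %in% names(duration_mean)),
            all(c("nonAFF", "AFF") %in% names(duration_sd)),
            all(duration_sd >= 0), all(mech$sd >= 0), all(histo$sd >= 0))
  check_number(fraction_single_label, "fraction_single_label", min = 0, max = 1)
  check_number(fraction_no_label, "fraction_no_label", min = 0, max = 1)
  if (fraction_single_label + fraction_no_label > 1) {
    abort("label fractions must sum to at most 1.",
          class = "ossindent_error_invalid")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), or_per_gpa = or_per_gpa,
         icc = icc, duration_mean = duration_mean, duration_sd = duration_sd,
         mech = mech, histo = histo,
         n_cortical_sites = as.integer(n_cortical_sites),
         n_trabeculae = as.integer(n_trabeculae),
         n_sites_per_trabecula = as.integer(n_sites_per_trabecula),
         fraction_single_label = fraction_single_label,
         fraction_no_label = fraction_no_label),
    class = "cohort_spec"
  )
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lower | x > upper)
    guard <- guard + 1L
  }
  pmin(pmax(x, lower), upper)
}

#' Simulate a nested case-control cohort with site-level properties
#'
#' Generates subject group labels, treatment durations, and site-level
#' nanomechanical property values under a subject random-intercept model:
#' each site value is `subject_mean + residual`, with the subject-level and
#' residual variances split so that the within-subject intraclass
#' correlation equals `spec$icc`. When `spec$or_per_gpa != 1`, AFF status
#' is drawn from a logistic model on the subject-mean cortical elastic
#' modulus with slope `log(or_per_gpa)` (per GPa), so the generating odds
#' ratio is directly interpretable; other properties then take their
#' group-specific means given the drawn label.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed (caller RNG state restored).
#'
#' @return A list with `cohort` (tibble: `subject_id`, `group`,
#'   `duration_yr`) and `sites` (tibble: `subject_id`, `compartment`,
#'   `trabecula`, `site`, `E_GPa`, `H_GPa`, `Hc_GPa`). The spec and seed
#'   are attached as attributes of `cohort`.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_per_group = 4), seed = 1)
#' sim$cohort
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- 2L * spec$n_per_group
    ids <- sprintf("S%03d", seq_len(n))
    mech <- spec$mech

    target <- function(prop, comp, grp, what) {
      m <- mech[mech$property == prop & mech$compartment == comp &
                  mech$group == grp, ]
      m[[what]][1L]
    }

    # Subject-mean cortical E and the AFF mechanism. The AFF-cortical E
    # association is encoded solely by or_per_gpa (the target table's two
    # cortical-E entries define the pooled centre), so or_per_gpa = 1 is an
    # exact null: the label is independent of the mechanics.
    sdE <- target("E_GPa", "cortical", "nonAFF", "sd")
    tauE <- sqrt(spec$icc) * sdE
    mu0 <- mean(c(target("E_GPa", "cortical", "nonAFF", "mean"),
                  target("E_GPa", "cortical", "AFF", "mean")))
    subjE <- rnorm(n, mu0, tauE)
    if (spec$or_per_gpa == 1) {
      group <- rep(c("nonAFF", "AFF"), each = spec$n_per_group)
    } else {
      p <- plogis(log(spec$or_per_gpa) * (subjE - mu0))
      group <- ifelse(rbinom(n, 1L, p) == 1L, "AFF", "nonAFF")
      if (length(unique(group)) < 2L) {
        abort("simulate_cohort: a group came out empty; increase n_per_group.",
              class = "ossindent_error_degenerate")
      }
    }
    group <- factor(group, levels = c("nonAFF", "AFF"))
    duration <- rnorm_trunc(n, spec$duration_mean[as.character(group)],
                            spec$duration_sd[as.character(group)], lower = 2)
    cohort <- tibble::tibble(subject_id = ids, group = group,
                             duration_yr = duration)

    # site table: subject intercept + residual per property and compartment
    site_design <- dplyr::bind_rows(
      tibble::tibble(compartment = "cortical", trabecula = NA_integer_,
                     site = seq_len(spec$n_cortical_sites)),
      tidyr::expand_grid(compartment = "cancellous",
                         trabecula = seq_len(spec$n_trabeculae),
                         site = seq_len(spec$n_sites_per_trabecula))
    )
    sites <- tidyr::expand_grid(subject_id = ids, site_design) |>
      dplyr::left_join(cohort[, c("subject_id", "group")], by = "subject_id")

    draw_property <- function(prop) {
      out <- numeric(nrow(sites))
      for (comp in c("cortical", "cancellous")) {
        sd_tot <- target(prop, comp, "nonAFF", "sd")
        tau <- sqrt(spec$icc) * sd_tot
        sig <- sqrt(1 - spec$icc) * sd_tot
        mu_g <- vapply(as.character(cohort$group), function(g)
          target(prop, comp, g, "mean"), numeric(1))
        subj_mean <- if (prop == "E_GPa" && comp == "cortical") subjE
          else rnorm(n, mu_g, tau)
        idx <- which(sites$compartment == comp)
        sm <- subj_mean[match(sites$subject_id[idx], ids)]
        out[idx] <- sm + rnorm(length(idx), 0, sig)
      }
      out
    }
    sites$E_GPa <- draw_property("E_GPa")
    sites$H_GPa <- draw_property("H_GPa")
    sites$Hc_GPa <- draw_property("Hc_GPa")
    sites$group <- NULL

    attr(cohort, "spec") <- spec
    attr(cohort, "seed") <- seed
    attr(cohort, "subject_mean_cortical_E") <-
      setNames(subjE, ids)
    list(cohort = cohort, sites = sites)
  })
}
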