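#' Configuration for a full pipeline run
#'
#' Bundles seeds, protocol and indenter constants, fit and imputation
#' options, the statistics level, and paths. The configuration serializes
#' losslessly to JSON (see [run_pipeline()]'s manifest).
#'
#' @param out_dir Output directory for the run.
#' @param seed Integer master seed for all random draws.
#' @param spec A [cohort_spec()] describing the synthetic cohort.
#' @param protocol An [indentation_protocol()].
#' @param indenter An [indenter_spec()]. For reducing curves produced by
#'   the package's own conical simulator, the conical geometry factor
#'   [cone_epsilon()] is the consistent choice of `epsilon`.
#' @param nu_s Sample Poisson ratio for the reduction.
#' @param fit_fraction Unloading fit fraction.
#' @param mar_floor MAR floor (um/day) for single-label-only surfaces.
#' @param stats_level `"site"` (GEE on site-level rows) or `"subject"`
#'   (logistic fit on subject means with cluster-robust variance).
#' @param curves_dir Optional directory of user-supplied curves (read with
#'   [read_curves()]); when `NULL` curves are simulated.
#' @param write_curve_files Also write every simulated curve to disk.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       spec = cohort_spec(n_per_group = 8,
                                          n_cortical_sites = 6,
                                          n_trabeculae = 2,
                                          n_sites_per_trabecula = 3),
                       protocol = indentation_protocol(),
                       indenter = indenter_spec(epsilon = cone_epsilon()),
                       nu_s = 0.3,
                       fit_fraction = 0.8,
                       mar_floor = 0.3,
                       stats_level = c("site", "subject"),
                       curves_dir = NULL,
                       write_curve_files = FALSE) {
  stats_level <- match.arg(stats_level)
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(protocol, "indent_protocol"),
            inherits(indenter, "indenter_spec"))
  if (!is.null(curves_dir) && !dir.exists(curves_dir)) {
    abort(sprintf("run_config: curves_dir does not exist: %s", curves_dir),
          class = "ossindent_error_io")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
         protocol = protocol, indenter = indenter, nu_s = nu_s,
         fit_fraction = fit_fraction, mar_floor = mar_floor,
         stats_level = stats_level, curves_dir = curves_dir,
         write_curve_files = write_curve_files),
    class = "run_config"
  )
}

#' Run the full synthetic pipeline
#'
#' Executes the four stages end to end: (1) synthetic cohort,
#' histomorphometry primitives, and one simulated indentation curve per
#' site (or user curves from `config$curves_dir`); (2) curve reduction to
#' per-site properties and specimen aggregation; (3) histomorphometry index
#' derivation; (4) case-control statistics (group summaries, t tests, odds
#' ratios). All tables are written as comma-separated UTF-8 text with
#' missing values as empty fields, together with a JSON manifest (seed,
#' config, versions) and a short human-readable report. Identical config
#' and seed reproduce identical tables byte for byte.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return The output directory, invisibly; stage outputs are also
#'   returned as the attribute `"results"`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  spec <- config$spec
  stage <- "synthetic cohort"
  res <- tryCatch({
    say("stage 1/4: synthetic data (seed %d)", config$seed)
    sim <- simulate_cohort(spec, seed = config$seed)
    envs <- c("cancellous", "intracortical", "endosteal")
    prims <- purrr::map(setNames(envs, envs), function(e)
      simulate_envelope_primitives(spec, e, seed = config$seed + match(e, envs),
                                   cohort = sim$cohort))
    struct <- simulate_structural_primitives(spec, seed = config$seed + 10L,
                                             cohort = sim$cohort)

    stage <- "indentation"
    say("stage 2/4: curve simulation and reduction (%d sites)", nrow(sim$sites))
    curves <- if (is.null(config$curves_dir)) {
      purrr::pmap_dfr(
        dplyr::mutate(sim$sites, .row = dplyr::row_number()),
        function(subject_id, compartment, trabecula, site, E_GPa, H_GPa, Hc_GPa, .row) {
          crv <- simulate_curve(
            material_truth(E_s = E_GPa, H_true = H_GPa,
                           creep_amp_nm = 5, drift_rate_nm_s = 0.05,
                           noise_sd_nm = 2),
            protocol = config$protocol,
            indenter = config$indenter,
            seed = config$seed * 1000L + .row)
          dplyr::bind_cols(
            tibble::tibble(specimen = subject_id, compartment = compartment,
                           trabecula = trabecula, site = site),
            crv[, c("time_s", "load_mN", "depth_nm")])
        })
    } else {
      read_curves(config$curves_dir)
    }
    if (config$write_curve_files) {
      write_curves(curves, file.path(config$out_dir, "curves"),
                   metadata = list(seed = config$seed))
    }
    props <- reduce_curves(curves,
                           indenter = config$indenter, nu_s = config$nu_s,
                           fit_fraction = config$fit_fraction,
                           protocol = config$protocol)
    agg <- aggregate_sites(props)

    stage <- "histomorphometry"
    say("stage 3/4: histomorphometry indices")
    indices <- purrr::map_dfr(prims, histo_indices, mar_floor = config$mar_floor)
    struct_idx <- structural_indices(struct)

    stage <- "statistics"
    say("stage 4/4: case-control statistics")
    cohort <- sim$cohort
    mech_wide <- agg |>
      dplyr::mutate(var = paste(.data$property, .data$compartment, sep = "_")) |>
      dplyr::select(dplyr::all_of(c("specimen", "var", "mean"))) |>
      tidyr::pivot_wider(names_from = "var", values_from = "mean") |>
      dplyr::rename(subject_id = "specimen")
    subj <- cohort |> dplyr::left_join(mech_wide, by = "subject_id")
    mech_vars <- setdiff(names(mech_wide), "subject_id")
    summaries <- group_summary(subj, c("duration_yr", mech_vars))
    index_cols <- c("W_Th_um", "ES_BS_pct", "OS_BS_pct", "ObS_BS_pct",
                    "OcS_BS_pct", "O_Th_um", "MS_BS_pct", "MAR_um_day",
                    "BFR_BS_um3_um2_yr", "Ac_f_per_yr")
    histo_summary <- indices |>
      dplyr::group_by(.data$envelope) |>
      dplyr::group_modify(function(d, key) group_summary(d, index_cols)) |>
      dplyr::ungroup()
    tt <- purrr::map_dfr(mech_vars, function(v) {
      d <- subj[!is.na(subj[[v]]), ]
      if (length(unique(d$group[!is.na(d$group)])) < 2L) return(NULL)
      two_group_ttest(d, v)
    })

    # statistics run on the *measured* (curve-reduced) properties
    site_stats <- props |>
      dplyr::rename(subject_id = "specimen") |>
      dplyr::left_join(cohort, by = "subject_id")
    or_tab <- purrr::map_dfr(c("cortical", "cancellous"), function(comp) {
      purrr::map_dfr(c("E_GPa", "H_GPa", "Hc_GPa"), function(pr) {
        d <- if (config$stats_level == "site") {
          dplyr::filter(site_stats, .data$compartment == comp)
        } else {
          v <- paste(pr, comp, sep = "_")
          dplyr::transmute(subj, subject_id = .data$subject_id,
                           group = .data$group,
                           duration_yr = .data$duration_yr,
                           !!pr := .data[[v]])
        }
        fit <- fit_aff_or(d, pr)
        dplyr::mutate(tidy(fit), compartment = comp, .before = 1)
      })
    })

    list(cohort = cohort, sites = sim$sites, primitives = prims,
         structural = struct, curves_n = length(unique(paste(
           curves$specimen, curves$compartment, curves$trabecula, curves$site))),
         properties = props, aggregated = agg, indices = indices,
         structural_indices = struct_idx, summaries = summaries,
         histo_summary = histo_summary, ttests = tt, odds_ratios = or_tab)
  }, error = function(e) {
    abort(sprintf("run_pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "ossindent_error_pipeline", parent = e)
  })

  # --- write outputs
  out <- config$out_dir
  wr <- function(d, f) readr::write_csv(d, file.path(out, f), na = "")
  wr(res$cohort, "cohort.csv")
  wr(res$sites, "site_truth.csv")
  wr(res$properties, "site_properties.csv")
  wr(res$aggregated, "specimen_summary.csv")
  for (e in names(res$primitives)) {
    write_primitives(res$primitives[[e]],
                     file.path(out, sprintf("primitives_%s.csv", e)))
  }
  write_primitives(res$structural, file.path(out, "primitives_structural.csv"))
  wr(res$indices, "histo_indices.csv")
  wr(res$structural_indices, "structural_indices.csv")
  wr(res$summaries, "group_summary.csv")
  wr(res$histo_summary, "histo_group_summary.csv")
  wr(res$ttests, "ttests.csv")
  wr(res$odds_ratios, "odds_ratios.csv")

  manifest <- list(
    package = "ossindent",
    version = as.character(packageVersion("ossindent")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stats_level = config$stats_level,
    config = serialize_config(config),
    tables = list.files(out, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  report <- c(
    "ossindent pipeline run",
    sprintf("seed: %d  subjects: %d  sites/subject: %d",
            config$seed, nrow(res$cohort),
            spec$n_cortical_sites + spec$n_trabeculae * spec$n_sites_per_trabecula),
    "",
    "group summaries (nanomechanics, subject level):",
    utils::capture.output(print(as.data.frame(res$summaries), digits = 3)),
    "",
    "odds ratios (AFF ~ duration + property, clustered):",
    utils::capture.output(print(as.data.frame(res$odds_ratios), digits = 3))
  )
  writeLines(report, file.path(out, "report.txt"))
  say("run complete: %s", out)
  attr(out, "results") <- res
  invisible(out)
}

# config -> plain named list for the JSON manifest (drops functions/classes)
serialize_config <- function(config) {
  spec <- unclass(config$spec)
  spec$mech <- NULL; spec$histo <- NULL  # bulky target tables hashed instead
  list(
    out_dir = config$out_dir, seed = config$seed,
    spec = spec,
    mech_targets_rows = nrow(config$spec$mech),
    histo_targets_rows = nrow(config$spec$histo),
    protocol = unclass(config$protocol),
    indenter = unclass(config$indenter),
    nu_s = config$nu_s, fit_fraction = config$fit_fraction,
    mar_floor = config$mar_floor, stats_level = config$stats_level,
    curves_dir = config$curves_dir,
    write_curve_files = config$write_curve_files
  )
}
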