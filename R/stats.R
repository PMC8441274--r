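#' Per-group mean and SD summary table
#'
#' Summarises variables as mean, sample SD (n - 1 denominator), and n per
#' group, with a formatted `"mean +/- sd"` label, the conventional shape of
#' a case-control characteristics table.
#'
#' @param data A data frame.
#' @param variables Character vector of numeric column names to summarise.
#' @param group Name of the grouping column (default `"group"`).
#' @param digits Significant digits used in the formatted label.
#'
#' @return A tibble with columns `variable`, `group`, `n`, `mean`, `sd`,
#'   `label`. Variables with no non-missing values in a group are emitted
#'   with `n = 0` and `NA` summaries.
#' @export
#' @examples
#' d <- data.frame(group = c("a", "a", "b", "b"), x = c(10, 14, 3, 5))
#' group_summary(d, "x")
group_summary <- function(data, variables, group = "group", digits = 3) {
  check_columns(data, c(variables, group), "group_summary")
  data |>
    tidyr::pivot_longer(dplyr::all_of(variables),
                        names_to = "variable", values_to = "value") |>
    dplyr::group_by(.data$variable, dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = ifelse(sum(!is.na(.data$value)) > 0,
                    mean(.data$value, na.rm = TRUE), NA_real_),
      sd = ifelse(sum(!is.na(.data$value)) > 1, sd(.data$value, na.rm = TRUE),
                  ifelse(sum(!is.na(.data$value)) == 1, 0, NA_real_)),
      .groups = "drop") |>
    dplyr::mutate(label = ifelse(
      .data$n > 0,
      paste0(signif(.data$mean, digits), " ± ", signif(.data$sd, digits)),
      NA_character_)) |>
    dplyr::rename(group = dplyr::all_of(group))
}

#' Two-sample t test from summary statistics
#'
#' Student's pooled-variance two-sided t test (default) or Welch's test,
#' computed directly from per-group means, SDs, and sample sizes, so the
#' same code path serves raw data (via [two_group_ttest()]) and published
#' summary tables.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (SDs with n - 1
#'   denominator).
#' @param welch Use Welch's unequal-variance test instead of the pooled
#'   test.
#'
#' @return A one-row tibble: `estimate` (mean1 - mean2), `t`, `df`, `p`.
#'   With zero variance in both groups and equal means, `t = 0`, `p = 1`.
#' @export
#' @examples
#' ttest_from_summary(42.6, 4.66, 16, 36.1, 4.22, 16)
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  est <- mean1 - mean2
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
          else n1 + n2 - 2
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  tibble::tibble(estimate = est, t = t, df = df, p = p)
}

#' Two-sample t test on a data frame
#'
#' Splits `variable` by the two levels of `group` and runs
#' [ttest_from_summary()] on the per-group summaries; by construction the
#' result is identical to computing the test from the raw vectors.
#'
#' @param data A data frame.
#' @param variable Name of the numeric column to test.
#' @param group Name of the two-level grouping column.
#' @param welch Use Welch's test.
#'
#' @return A one-row tibble: `variable`, `group1`, `group2`, `estimate`,
#'   `t`, `df`, `p`.
#' @export
two_group_ttest <- function(data, variable, group = "group", welch = FALSE) {
  check_columns(data, c(variable, group), "two_group_ttest")
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) {
    abort("two_group_ttest: grouping column must have exactly two levels.",
          class = "ossindent_error_invalid")
  }
  x <- data[[variable]][g == levels(g)[1L]]
  y <- data[[variable]][g == levels(g)[2L]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("two_group_ttest: need at least 2 observations per group.",
          class = "ossindent_error_degenerate")
  }
  res <- ttest_from_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y), welch = welch)
  dplyr::bind_cols(tibble::tibble(variable = variable,
                                  group1 = levels(g)[1L],
                                  group2 = levels(g)[2L]), res)
}

#' Odds ratio for AFF from clustered logistic regression
#'
#' Fits the case-control model of the binary AFF outcome on treatment
#' duration plus one nanomechanical property. With site-level data the fit
#' is a GEE with exchangeable working correlation and robust variance
#' clustered by subject; with one row per subject it reduces to ordinary
#' logistic regression with a cluster-robust (sandwich) variance. Cortical
#' and cancellous compartments are intended to be fitted separately (filter
#' the table first). Odds ratios are per unit of the property, with Wald
#' 95% confidence limits on the log-odds scale.
#'
#' @param data A data frame with one row per site (or per subject)
#'   containing the outcome, duration, property, and cluster columns.
#' @param property Name of the property column (e.g. `"E_GPa"`).
#' @param duration Name of the treatment-duration covariate.
#' @param outcome Name of the outcome column; a factor whose second level
#'   (or the value `"AFF"`) is the event, or a 0/1 numeric.
#' @param cluster Name of the subject/cluster id column.
#' @param corstr Working correlation for the site-level GEE. (When the
#'   outcome is constant within clusters — one case status per subject —
#'   the fit uses the independence working structure, see [gee_logit()].)
#' @param level `"site"` fits the supplied rows directly; `"subject"`
#'   collapses the property and duration to subject means first (one row
#'   per cluster), which removes the attenuation that within-subject
#'   site-to-site scatter of the property induces on the odds ratio;
#'   `"auto"` (default) keeps the rows as supplied.
#' @param conf.level Confidence level for the Wald interval.
#'
#' @return An object of class `aff_or` wrapping the [gee_logit()] fit.
#'   `tidy()` returns `variable`, `OR`, `ci_low`, `ci_high`, `p`,
#'   `adjusted_for`; under apparent complete separation the interval is
#'   reported as (0, Inf) rather than a fabricated finite one.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_per_group = 8, or_per_gpa = 1.3), seed = 5)
#' d <- merge(sim$sites[sim$sites$compartment == "cortical", ], sim$cohort)
#' tidy(fit_aff_or(d, "E_GPa"))
fit_aff_or <- function(data, property,
                       duration = "duration_yr",
                       outcome = "group",
                       cluster = "subject_id",
                       corstr = "exchangeable",
                       level = c("auto", "site", "subject"),
                       estimator = c("gee", "firth"),
                       conf.level = 0.95) {
  level <- match.arg(level)
  estimator <- match.arg(estimator)
  check_columns(data, c(property, duration, outcome, cluster), "fit_aff_or")
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y)) {
    y <- as.integer(as.character(y) == "AFF")
  }
  if (!all(y %in% c(0, 1))) {
    abort("fit_aff_or: outcome must be AFF/nonAFF or 0/1.",
          class = "ossindent_error_invalid")
  }
  d <- data.frame(.y = y,
                  .dur = data[[duration]],
                  .prop = data[[property]],
                  .id = data[[cluster]])
  if (level == "subject" && anyDuplicated(d$.id)) {
    d <- d |>
      dplyr::group_by(.data$.id) |>
      dplyr::summarise(.y = .data$.y[1L],
                       .dur = mean(.data$.dur, na.rm = TRUE),
                       .prop = mean(.data$.prop, na.rm = TRUE),
                       .groups = "drop")
  }
  fit <- if (estimator == "firth") {
    if (anyDuplicated(d$.id)) {
      abort("fit_aff_or: the Firth estimator requires one row per cluster (use level = \"subject\").",
            class = "ossindent_error_invalid")
    }
    firth_logit(.y ~ .dur + .prop, d)
  } else {
    gee_logit(.y ~ .dur + .prop, d, id = ".id", corstr = corstr)
  }
  structure(
    list(fit = fit, property = property, duration = duration,
         conf.level = conf.level, estimator = estimator,
         level = if (anyDuplicated(d$.id)) "site" else "subject"),
    class = "aff_or"
  )
}

#' @export
tidy.aff_or <- function(x, ...) {
  td <- tidy(x$fit, conf.int = TRUE, conf.level = x$conf.level,
             exponentiate = TRUE)
  td <- td[td$term != "(Intercept)", ]
  out <- tibble::tibble(
    variable = c(x$duration, x$property),
    OR = td$estimate,
    ci_low = td$conf.low,
    ci_high = td$conf.high,
    p = td$p.value,
    adjusted_for = c(x$property, x$duration)
  )
  if (isTRUE(x$fit$separation)) {
    warn("fit_aff_or: apparent complete separation; interval unbounded.",
         class = "ossindent_warning_separation")
    out$ci_low <- 0
    out$ci_high <- Inf
    out$p <- NA_real_
  }
  out
}

#' @export
glance.aff_or <- function(x, ...) {
  g <- glance(x$fit)
  g$level <- x$level
  g
}

#' @export
print.aff_or <- function(x, ...) {
  cat(sprintf("<aff_or> %s-level logistic fit (%s)\n",
              x$level,
              if (x$estimator == "firth") "bias-reduced"
              else paste("GEE,", x$fit$corstr)))
  print(tidy(x))
  invisible(x)
}
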