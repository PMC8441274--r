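#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an indentation force-depth curve
#'
#' @param object An [indent_curve][segment_curve()] (or any curve tibble
#'   with `depth_nm`, `load_mN` and optionally `phase`).
#' @param ... Unused.
#' @return A ggplot: load versus depth, coloured by protocol phase when
#'   available.
#' @export
autoplot.indent_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_nm, y = .data$load_mN))
  p <- if (!is.null(object$phase)) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$phase), linewidth = 0.5)
  } else {
    p + ggplot2::geom_path(linewidth = 0.5)
  }
  p + ggplot2::labs(x = "Depth (nm)", y = "Load (mN)", colour = "Phase") +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios
#'
#' @param data A tidy odds-ratio table with columns `variable`, `OR`,
#'   `ci_low`, `ci_high` (e.g. from `tidy(fit_aff_or(...))`, optionally
#'   with a `compartment` column for faceting).
#' @return A ggplot on a log odds-ratio axis with a reference line at 1.
#' @export
plot_or_forest <- function(data) {
  check_columns(data, c("variable", "OR", "ci_low", "ci_high"), "plot_or_forest")
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$OR, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if ("compartment" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~compartment)
  }
  p
}

#' Group summary dot plot
#'
#' @param data A [group_summary()] tibble.
#' @return A ggplot of per-group means with +/- 1 SD bars, faceted by
#'   variable.
#' @export
plot_group_summary <- function(data) {
  check_columns(data, c("variable", "group", "mean", "sd"), "plot_group_summary")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Mean ± SD") +
    ggplot2::theme_minimal()
}
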