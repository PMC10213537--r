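#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a subgroup report
#'
#' Percent change with 95% CI per bin, in the conventional forest-plot
#' layout: one dot per subgroup with its interval, sample size in the
#' label, and a dashed reference line at zero.
#'
#' @param object A `subgroup_report` (or any tibble with `bin`,
#'   `pct_change`, `pct_ci_low`, `pct_ci_high`, `k`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.subgroup_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$pct_change), ]
  d$label <- paste0(d$bin, " (", d$k, ")")
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct_change, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$pct_ci_low,
                                         xmax = .data$pct_ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "Change (%) with 95% CI", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.subgroup_report
#' @export
plot_forest <- function(object, ...) autoplot.subgroup_report(object, ...)

#' Bar chart of random-forest moderator importance
#'
#' @param object An `rf_importance` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rf_importance <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$moderator <- factor(d$moderator, levels = rev(d$moderator))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct_inc_mse,
                                  y = .data$moderator)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "MSE increase (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of effect sizes with the fitted response curve
#'
#' @param object A `response_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.response_curve <- function(object, ...) {
  d <- object$model$model
  names(d)[1:2] <- c("y", "x")
  grid <- tibble::tibble(x = seq(object$x_range[1], object$x_range[2],
                                 length.out = 200))
  grid$y <- predict_curve(object, grid$x)
  lab <- sprintf("%s fit: R2 = %.2f, p = %.2g", object$model_form,
                 object$r_squared, object$p_value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = object$x_name, y = "Effect size (ln response ratio)",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}
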