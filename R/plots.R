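#' Plot a prediction report
#'
#' Compounds ordered by increasing DNT probability with their credible
#' intervals, colour-coded by the two-threshold hazard class; one panel
#' per pathway node.
#'
#' @param object A `dnt_predictions` tibble from [predict_report()].
#' @param nodes Which nodes to show (default all four).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnt_predictions <- function(object, nodes = qaop_nodes, ...) {
  thr <- attr(object, "thresholds")
  df <- dplyr::filter(object, .data$node %in% nodes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_prob, y = .data$compound,
                                   colour = .data$hazard_class)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0, alpha = 0.5) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_vline(xintercept = unname(thr), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~node, nrow = 1) +
    ggplot2::scale_colour_manual(values = c(low = "#2c7fb8",
                                            medium = "#fe9929",
                                            high = "#d7301f")) +
    ggplot2::labs(x = "posterior probability of inducing the event",
                  y = NULL, colour = "hazard class") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot posterior coefficient intervals of a fit
#'
#' Forest plot of the pooled coefficients (posterior means and credible
#' intervals) with the hyperparameter mean for reference.
#'
#' @param object A `dnt_fit`.
#' @param level Interval level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnt_fit <- function(object, level = 0.95, ...) {
  td <- tidy(object, level = level)
  td <- dplyr::filter(td, grepl("^(beta_|mu$|sigma$)", .data$term))
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "posterior estimate", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot an exploratory-analysis report
#'
#' Heatmap of the pairwise-complete Pearson correlation matrix.
#'
#' @param object A `dnt_eda` from [explore_dnt_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnt_eda <- function(object, ...) {
  cm <- object$correlations
  df <- tibble::as_tibble(as.table(cm), .name_repair = "minimal")
  names(df) <- c("var1", "var2", "correlation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
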