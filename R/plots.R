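#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_errorbar
#'   geom_abline geom_boxplot labs theme_minimal autoplot position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot per-split ensemble accuracy of an evaluation report
#'
#' Bars show the mean coefficient of determination across ensembles per
#' split; error bars show +/- one standard deviation (absent when a single
#' ensemble was used).
#'
#' @param object A `yield_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yield_eval_report <- function(object, ...) {
  s <- object$summary
  ggplot(s, aes(x = .data$split, y = .data$mean_r2)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean_r2 - .data$sd_r2,
                      ymax = .data$mean_r2 + .data$sd_r2), width = 0.2) +
    labs(x = NULL, y = expression(R^2),
         title = "Ensemble prediction accuracy by split") +
    theme_minimal()
}

#' Observed-versus-predicted yield scatter plot
#'
#' @param obs,pred Numeric vectors of observed and predicted yields
#'   (percent).
#' @param highlight Optional logical vector marking outlier reactions.
#' @return A ggplot object.
#' @export
plot_pred_obs <- function(obs, pred, highlight = NULL) {
  d <- tibble(obs = obs, pred = pred,
              highlight = highlight %||% rep(FALSE, length(obs)))
  ggplot(d, aes(x = .data$obs, y = .data$pred, colour = .data$highlight)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6, show.legend = any(d$highlight)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    labs(x = "observed yield (%)", y = "predicted yield (%)",
         colour = "outlier") +
    theme_minimal()
}

#' Group-wise yield box plot split by a marker set
#'
#' Visualises [groupwise_yield_summary()]-style contrasts directly from
#' the dataset: one box per group structure, filled by whether the
#' reaction contains a marker structure.
#'
#' @param ds A [reaction_dataset()].
#' @param group_role,marker_role,marker_set As in
#'   [groupwise_yield_summary()].
#' @return A ggplot object.
#' @export
plot_groupwise_yields <- function(ds, group_role, marker_role, marker_set) {
  marker_canon <- canonicalize_structures(marker_set)
  d <- tibble(
    group = ds$table[[group_role]],
    with_marker = ds$table[[marker_role]] %in% marker_canon,
    yield = ds$table$yield
  )
  ggplot(d, aes(x = .data$group, y = .data$yield, fill = .data$with_marker)) +
    geom_boxplot(position = position_dodge()) +
    labs(x = group_role, y = "observed yield (%)", fill = "with marker") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
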