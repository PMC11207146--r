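# ggplot2 presentation helpers for the main result types.

#' Plot average treatment effects by buffer radius
#'
#' Mean treated-control difference with +-1 bootstrap s.d. ribbons, one
#' panel per metric.
#'
#' @param object a [bootstrap_ate()] table.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.remiforest_ate <- function(object, ...) plot_ate(object)

#' @rdname autoplot.remiforest_ate
#' @param ate a [bootstrap_ate()] table.
#' @export
plot_ate <- function(ate) {
  ggplot2::ggplot(ate, ggplot2::aes(x = .data$radius, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_diff - .data$boot_sd,
                                      ymax = .data$mean_diff + .data$boot_sd),
                         alpha = 0.2, fill = "forestgreen") +
    ggplot2::geom_line(colour = "forestgreen") +
    ggplot2::geom_point(ggplot2::aes(size = .data$occ_h1), colour = "forestgreen") +
    ggplot2::scale_size_continuous(name = "occ. p<0.05 (%)", range = c(1, 4)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "buffer radius (m)",
                  y = "treated - control change",
                  title = "Remittance treatment effect by buffer radius") +
    ggplot2::theme_minimal()
}

#' Plot predictive margins over the payment grid
#'
#' @param margins the `margins` tibble from [marginal_effects()].
#' @param response y-axis label.
#' @return a ggplot.
#' @export
plot_margins <- function(margins, response = "P(send remittance)") {
  ggplot2::ggplot(margins, ggplot2::aes(x = .data$payment, y = .data$margin)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "cumulative program payment (1,000 Yuan)",
                  y = response, title = "Predictive margins") +
    ggplot2::theme_minimal()
}

#' Scatter of group remittance against ring forest change
#'
#' Mirrors the group-level robustness display: all-points and
#' outlier-excluded trend lines per ring zone.
#'
#' @param groups group table. @param ring_changes ring change rows.
#' @param metric outcome column.
#' @return a ggplot.
#' @export
plot_group_association <- function(groups, ring_changes,
                                   metric = "delta_forest") {
  d <- dplyr::inner_join(groups, ring_changes,
                         by = c(group_id = "unit_id")) |>
    dplyr::filter(.data$group_remittance_total > 0, !is.na(.data[[metric]]))
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$group_remittance_total),
                                  y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50") +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "log10 group remittance (Yuan)", y = metric,
                  title = "Group-level remittance-forest association") +
    ggplot2::theme_minimal()
}

#' Distance-bin flow summaries
#'
#' @param flow_table a [build_flow_table()] result.
#' @param attribute column of the city flow table to summarise by bin.
#' @return a ggplot.
#' @export
plot_flow_bins <- function(flow_table, attribute = "n_migrants") {
  fl <- flow_table$flows
  fl <- fl[!is.na(fl$bin), ]
  ggplot2::ggplot(fl, ggplot2::aes(x = .data$bin, y = .data[[attribute]])) +
    ggplot2::geom_boxplot(fill = "tan") +
    ggplot2::labs(x = "migration distance bin", y = attribute,
                  title = "Flow attributes by distance bin") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
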