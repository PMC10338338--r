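#' Plot single-cell reporter traces
#'
#' CDK2 and APC/C activity over time for a handful of cells, with the
#' treatment time and the 0.6 CDK2 commitment threshold marked.
#'
#' @param traces A trace tibble (see [generate_population()]).
#' @param cells Cell ids to show (default: first 4).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, cells = NULL) {
  if (is.null(cells)) cells <- unique(traces$cell_id)[1:min(4, dplyr::n_distinct(traces$cell_id))]
  d <- traces |>
    dplyr::filter(.data$cell_id %in% cells) |>
    tidyr::pivot_longer(c("cdk2", "apc"), names_to = "channel",
                        values_to = "activity")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$activity,
                                  colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$treatment_time_h),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0.6, linetype = "dotted") +
    ggplot2::facet_wrap(~cell_id) +
    ggplot2::labs(x = "Time (h)", y = "Reporter activity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' CDK2 activity heat map ordered by fate timing
#'
#' Cells are ordered with [order_for_heatmap()]: dividers by mitosis time,
#' then exiting cells by exit time.
#'
#' @param traces A trace tibble.
#' @param features The matching [classify_fates()] table.
#' @return A ggplot object.
#' @export
plot_trace_heatmap <- function(traces, features) {
  ord <- order_for_heatmap(features)
  d <- dplyr::mutate(traces, cell_id = factor(.data$cell_id, levels = rev(ord)))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$cell_id,
                                  fill = pmin(.data$cdk2, 1.5))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "CDK2") +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot CDK2 dose-response curves for both branches
#'
#' @param model A [build_network()] result.
#' @param eval_time Evaluation time in hours, or `Inf` for steady state.
#' @param doses MEKi dose grid.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(model, eval_time = Inf,
                               doses = seq(0, 1, by = 0.05)) {
  d <- dplyr::bind_rows(
    dose_response(model, doses, eval_time, "HIGH"),
    dose_response(model, doses, eval_time, "LOW")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$dose, .data$cdk2,
                                  colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "MEKi dose (relative)", y = "CDK2 activity",
                  colour = "Branch",
                  title = paste0(model$architecture, ", eval at ",
                                 ifelse(is.infinite(eval_time), "steady state",
                                        paste0(eval_time, " h")))) +
    ggplot2::theme_minimal()
}
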