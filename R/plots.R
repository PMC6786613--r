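#' Plot per-combination sweep means against carrying capacity
#'
#' One line per disaster frequency; points are means over replicates.
#'
#' @param sweep A `herd_sweep` tibble from [run_sweep()].
#' @param response One of the per-run outcome columns
#'   (`"largest_network_size"`, `"largest_network_duration"`,
#'   `"final_gini"`, `"end_population"`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, response = "largest_network_size") {
  responses <- c("largest_network_size", "largest_network_duration",
                 "final_gini", "end_population")
  response <- match.arg(response, responses)
  labels <- c(largest_network_size = "Mean largest network size (clients)",
              largest_network_duration = "Mean largest network duration (steps)",
              final_gini = "Mean final Gini index",
              end_population = "Mean end population (households)")
  agg <- sweep |>
    dplyr::group_by(.data$carrying_capacity, .data$disaster_prob) |>
    dplyr::summarise(value = mean(.data[[response]]), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$carrying_capacity,
                                    y = .data$value,
                                    colour = factor(.data$disaster_prob),
                                    group = factor(.data$disaster_prob))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Carrying capacity (animals)",
                  y = labels[[response]],
                  colour = "Disaster\nfrequency") +
    ggplot2::theme_minimal()
}

#' Heatmap of mean final Gini over the sweep grid
#'
#' @param sweep A `herd_sweep` tibble, typically from [run_gini_sweep()].
#' @return A ggplot object.
#' @export
plot_gini_sweep <- function(sweep) {
  agg <- sweep |>
    dplyr::group_by(.data$carrying_capacity, .data$disaster_prob) |>
    dplyr::summarise(mean_gini = mean(.data$final_gini), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$carrying_capacity),
                                    y = factor(.data$disaster_prob),
                                    fill = .data$mean_gini)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Carrying capacity (animals)",
                  y = "Disaster frequency",
                  fill = "Mean final\nGini index") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.herd_sweep <- function(object, response = "largest_network_size", ...) {
  plot_sweep(object, response = response)
}

#' Plot standardized regression coefficients
#'
#' @param object A `herd_ols` object from [standardized_ols()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.herd_ols <- function(object, ...) {
  ggplot2::ggplot(object$coefficients,
                  ggplot2::aes(x = .data$term, y = .data$beta)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Standardized beta",
                  title = paste("Response:", object$response)) +
    ggplot2::theme_minimal()
}
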