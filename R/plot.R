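# Quick-look plotting.

#' Plot simulated trajectories
#'
#' One facet per read-out, coloured by scenario — the standard way the
#' simulated mRNA levels and protein activities are displayed.
#'
#' @param object A `uprt_timecourse` or `uprt_panel` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uprt_timecourse <- function(object, ...) {
  d <- as_tibble(object) |>
    dplyr::mutate(readout = factor(unname(SPECIES_LABEL[.data$species]),
                                   levels = unname(SPECIES_LABEL)))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$value,
                                  colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~readout, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "relative level",
                  colour = "scenario") +
    ggplot2::theme_minimal()
}

#' Plot a phenotype call table
#'
#' @param object A `uprt_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uprt_calls <- function(object, ...) {
  d <- as_tibble(object) |>
    dplyr::mutate(key = paste(.data$species, .data$feature),
                  vs = paste(.data$scenario, "vs", .data$reference))
  ggplot2::ggplot(d, ggplot2::aes(.data$key, .data$vs,
                                  fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "read-out", y = NULL, fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot synthetic measurements over the true trajectories
#'
#' @param object A `uprt_synthetic` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uprt_synthetic <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$normalized_value,
                                  colour = .data$scenario)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$true_value)) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "normalized signal") +
    ggplot2::theme_minimal()
}
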