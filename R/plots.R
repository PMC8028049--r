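# ggplot2 visualisations for the main result types.

#' Plot a prediction-correlation report
#'
#' Scatter of predicted vs reference energy differences per partition with
#' the identity line.
#'
#' @param object A `reax_correlation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reax_correlation_report <- function(object, ...) {
  ggplot2::ggplot(
    object$pairs,
    ggplot2::aes(x = .data$reference, y = .data$predicted,
      colour = .data$partition
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "reference energy difference (kcal/mol)",
      y = "predicted energy difference (kcal/mol)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a partial-charge report
#'
#' Predicted EEM charge against the reference for every atom, coloured by
#' element.
#'
#' @param object A `reax_charge_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reax_charge_report <- function(object, ...) {
  ggplot2::ggplot(
    object$atoms,
    ggplot2::aes(x = .data$reference, y = .data$eem, colour = .data$element)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "reference charge (e)", y = "EEM charge (e)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot trajectory temperature and total energy
#'
#' @param object A [reax_trajectory].
#' @param ... Unused.
#' @return A ggplot object (temperature and total energy vs time, free
#'   y scales).
#' @export
autoplot.reax_trajectory <- function(object, ...) {
  df <- tibble::tibble(
    time = trajectory_times(object),
    temperature = vapply(object$frames, function(f) f$temperature, 0),
    energy = vapply(object$frames, function(f) {
      if (is.null(f$energy)) NA_real_ else f$energy$total
    }, 0)
  )
  long <- tidyr::pivot_longer(df, c("temperature", "energy"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (fs)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a swarm-training cost history
#'
#' @param object A `reax_swarm_fit`.
#' @param ... Unused.
#' @return A ggplot object (global-best cost vs iteration, log scale).
#' @export
autoplot.reax_swarm_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$history,
    ggplot2::aes(x = .data$iteration, y = .data$best_cost)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "global best cost") +
    ggplot2::theme_minimal()
}
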