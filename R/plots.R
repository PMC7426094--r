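# ggplot2 views of the main result types.

#' Plot a mutant-frequency trajectory
#'
#' @param object A `drive_trajectory`.
#' @param ... Unused.
#' @return A ggplot: mutant frequency against generation (log-scaled x beyond
#'   generation 1), annotated with the outcome.
#' @method autoplot drive_trajectory
#' @export
autoplot.drive_trajectory <- function(object, ...) {
  df <- object$states
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation + 1, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "generation (log scale, offset by 1)",
      y = "mutant allele frequency",
      title = sprintf("n = %d, t = %g: %s", object$params$n, object$params$t,
                      object$outcome)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an invasion phase diagram
#'
#' @param object A `drive_phase` grid from [phase_grid()].
#' @param ... Unused.
#' @return A ggplot tiling the (n, t) plane by invasion outcome, with the
#'   cost-free critical drive strength overlaid.
#' @method autoplot drive_phase
#' @export
autoplot.drive_phase <- function(object, ...) {
  boundary <- tibble(n = sort(unique(object$n)))
  boundary$t_critical <- critical_drive_strength(boundary$n)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$t,
                                       fill = .data$invades)) +
    ggplot2::geom_tile() +
    ggplot2::geom_line(data = boundary,
                       ggplot2::aes(x = .data$n, y = .data$t_critical),
                       inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85", `TRUE` = "#2c7fb8")) +
    ggplot2::labs(x = "number of drivers (n)", y = "drive strength (t)",
                  fill = "mutant invades") +
    ggplot2::theme_minimal()
}

#' Plot a spore census
#'
#' @param object A `spore_census`.
#' @param ... Unused.
#' @return A ggplot of probability (or frequency) by spore class, split by
#'   viability.
#' @method autoplot spore_census
#' @export
autoplot.spore_census <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(viability = ifelse(.data$viable, "viable", "dead")) |>
    group_by(.data$klass, .data$viability) |>
    summarise(prob = sum(.data$prob), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$klass, y = .data$prob,
                                   fill = .data$viability)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(viable = "#31a354", dead = "grey70")) +
    ggplot2::labs(x = NULL, y = "fraction of spores", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot drive-strength estimates
#'
#' @param object A `drive_fit` from [fit_drive_strength()].
#' @param ... Unused.
#' @return A ggplot of per-diploid estimates with confidence intervals.
#' @method autoplot drive_fit
#' @export
autoplot.drive_fit <- function(object, ...) {
  df <- as_tibble(object)
  id <- names(df)[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[id]], y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "drive strength estimate") +
    ggplot2::theme_minimal()
}
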