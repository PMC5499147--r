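#' Plot population curves
#'
#' Healthy, collateral and altered-population trajectories over time for one
#' dose, in the style of a health-versus-time panel.
#'
#' @param curves An `imm_curves` tibble from [population_curves()].
#' @return A ggplot object.
#' @export
plot_populations <- function(curves) {
  stopifnot(inherits(curves, "imm_curves"))
  long <- tidyr::pivot_longer(as_tibble(curves), -"t",
                              names_to = "population", values_to = "cells")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$cells,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time", y = "cells",
      title = sprintf("Population curves at dose V0 = %g", attr(curves, "V0"))
    )
}

#' @export
autoplot.imm_curves <- function(object, ...) plot_populations(object)

#' Plot a dose sweep
#'
#' Two panels of the dose-response summary: minimal health percentage versus
#' dose, and the collateral-damage max/min band versus dose.
#'
#' @param sweep An `imm_sweep` tibble from [dose_sweep()].
#' @param which `"health"`, `"collateral"` or `"both"` (patchwork-free: both
#'   uses faceting on a rescaled long table).
#' @return A ggplot object.
#' @export
plot_dose_sweep <- function(sweep, which = c("health", "collateral")) {
  stopifnot(inherits(sweep, "imm_sweep"))
  which <- match.arg(which)
  if (which == "health") {
    ggplot2::ggplot(sweep, ggplot2::aes(x = .data$V0, y = .data$min_health_pct)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(ggplot2::aes(shape = .data$rebound)) +
      ggplot2::labs(x = "trigger dose V0", y = "minimal health (%)",
                    shape = "rebound")
  } else {
    ggplot2::ggplot(sweep, ggplot2::aes(x = .data$V0)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_collateral,
                                        ymax = .data$max_collateral),
                           alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$max_collateral)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$min_collateral),
                         linetype = "dashed") +
      ggplot2::labs(x = "trigger dose V0", y = "collateral damage")
  }
}

#' @export
autoplot.imm_sweep <- function(object, ...) plot_dose_sweep(object, ...)

#' Plot simulated trigger fields
#'
#' Spatial profiles of the free trigger (and bound fractions, when present)
#' at each output time.
#'
#' @param field An `imm_field` tibble.
#' @param value Column to plot (default `"u"`).
#' @return A ggplot object.
#' @export
plot_trigger_field <- function(field, value = "u") {
  stopifnot(inherits(field, "imm_field"))
  ggplot2::ggplot(field, ggplot2::aes(x = .data$x, y = .data[[value]],
                                      colour = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position", y = value, colour = "time")
}

#' @export
autoplot.imm_field <- function(object, ...) plot_trigger_field(object, ...)

#' Plot a pathway cascade
#'
#' Stage outputs of the sigmoid cascade against the extracellular trigger
#' concentration.
#'
#' @param tbl A tibble from [compose_pathway()].
#' @return A ggplot object.
#' @export
plot_pathway <- function(tbl) {
  long <- tidyr::pivot_longer(tbl, c("h_p", "h_e", "dQ_max"),
                              names_to = "stage", values_to = "output")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$T0, y = .data$output,
                                     colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(x = "trigger concentration T0", y = "stage output")
}
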