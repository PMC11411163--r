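#' Plot a simulated trajectory
#'
#' Faceted view of a trajectory: subpopulation and total densities,
#' per-cell toxin, mutant fraction, cumulative released load, and the
#' induction program actually applied.
#'
#' @param object A `lysim_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lysim_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "t_h", "x", "y", "total", "p",
                  "fraction_mutant", "released_load", "ahl_nM"),
    -"t_h", names_to = "series", values_to = "value")
  panel <- c(x = "density (a.u.)", y = "density (a.u.)",
             total = "density (a.u.)", p = "toxin (a.u.)",
             fraction_mutant = "mutant fraction",
             released_load = "released load (a.u.)",
             ahl_nM = "AHL (nM)")
  long$panel <- factor(panel[long$series], levels = unique(unname(panel)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_h, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (h)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of a strategy sweep
#'
#' Released load before mutant takeover over the period x on-duration grid;
#' invalid cells (on-duration exceeding the period) are blank.
#'
#' @param object A `lysim_strategy_grid` from [sweep_strategies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lysim_strategy_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(round(.data$on_h, 3)),
                                   y = factor(round(.data$period_h, 3)),
                                   fill = .data$load)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "ON duration (h)", y = "period (h)",
                  fill = "load before\ntakeover") +
    ggplot2::theme_minimal()
}

#' Plot plate-reader growth curves
#'
#' One line per replicate, coloured by AHL concentration; the canonical
#' quick look at a [generate_plate_reader()] data set.
#'
#' @param data Growth-curve data frame (columns `time_h`, `od600`,
#'   `ahl_nM`, `replicate`).
#' @param log_y Use a log10 density axis.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(data, log_y = FALSE) {
  check_gc_columns(data)
  g <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$time_h, y = .data$od600,
                                    colour = factor(.data$ahl_nM),
                                    group = interaction(.data$ahl_nM,
                                                        .data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (h)", y = "OD600 (a.u.)", colour = "AHL (nM)") +
    ggplot2::theme_minimal()
  if (log_y) g <- g + ggplot2::scale_y_log10()
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
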