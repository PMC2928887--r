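#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation: species through time
#'
#' Total (extant plus extinct) and extant species counts per generation.
#'
#' @param object A `radsim_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radsim_sim <- function(object, ...) {
  stt <- species_through_time(object)
  long <- tidyr::pivot_longer(stt, c("total", "extant"),
                              names_to = "curve", values_to = "species")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$species,
                                     color = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "number of species",
                  color = NULL,
                  title = sprintf("%s regime (N = %d, mu = %g, q_min = %g)",
                                  object$params$regime, object$params$N,
                                  object$params$mu, object$params$q_min)) +
    ggplot2::theme_minimal()
}

#' Plot a fit surface
#'
#' Mean misfit over the parameter grid, shown as `log(E)` for clarity of
#' the isoclines, faceted by population size if several are present.
#'
#' @param object A `radsim_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radsim_fit <- function(object, ...) {
  surf <- object$surface
  pl <- ggplot2::ggplot(surf, ggplot2::aes(.data$mu, .data$q_min,
                                           fill = log(.data$mean_E))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log E") +
    ggplot2::labs(x = expression(mu), y = expression(q[min])) +
    ggplot2::theme_minimal()
  if (length(unique(surf$N)) > 1)
    pl <- pl + ggplot2::facet_wrap(~N, labeller = ggplot2::label_both)
  pl
}

#' Plot a confidence band with an observed series
#'
#' @param band A [confidence_band()] tibble.
#' @param obs Optional observed [event_series()] to overlay (normalized).
#' @return A ggplot.
#' @export
plot_confidence_band <- function(band, obs = NULL) {
  pl <- ggplot2::ggplot(band, ggplot2::aes(.data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "normalized time", y = "cumulative species") +
    ggplot2::theme_minimal()
  if (!is.null(obs)) {
    obs <- normalize_times(obs)
    pl <- pl + ggplot2::geom_point(
      data = tibble::tibble(time = obs$time, cumulative = obs$cumulative),
      ggplot2::aes(.data$time, .data$cumulative))
  }
  pl
}

#' @importFrom rlang .data
NULL
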