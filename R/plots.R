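#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for package result types
#'
#' `autoplot()` methods: trajectories (one line per component), stability
#' region maps (tile raster of the three classes), bifurcation curves
#' (critical `k1*` versus `zbar`) and datasets (points with error bars,
#' faceted by condition, optionally overlaid with a fit).
#'
#' @param object A trajectory, region grid, bifurcation curve or dataset.
#' @param ... Unused.
#' @return A ggplot object.
#' @name triloop-plots
NULL

#' @rdname triloop-plots
#' @method autoplot triloop_trajectory
#' @export
autoplot.triloop_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object)[c("time", "x", "y", "z")],
                            c("x", "y", "z"), names_to = "component")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname triloop-plots
#' @method autoplot triloop_region
#' @export
autoplot.triloop_region <- function(object, ...) {
  axes <- attr(object, "axes")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                               fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(stable = "grey90",
                                          oscillatory = "grey40",
                                          no_steady_state = "tomato")) +
    ggplot2::theme_minimal()
}

#' @rdname triloop-plots
#' @method autoplot triloop_bifurcation
#' @export
autoplot.triloop_bifurcation <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$z_bar, .data$k1_star)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(bar(z)), y = expression(k[1]^"*")) +
    ggplot2::theme_minimal()
}

#' @rdname triloop-plots
#' @param fit Optional `triloop_fit` whose simulated curves are overlaid.
#' @method autoplot triloop_dataset
#' @export
autoplot.triloop_dataset <- function(object, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                         colour = .data$observable)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0, alpha = 0.5) +
    ggplot2::facet_wrap(~condition, scales = "free_y") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    map <- attr(object, "observable_map")
    sims <- simulate_conditions(fit$spec, fit$params, object)
    lines <- dplyr::bind_rows(lapply(names(sims), function(cond) {
      tr <- sims[[cond]]
      dplyr::bind_rows(lapply(names(map), function(o) {
        tibble::tibble(time = tr$time,
                       value = fit$scales[[o]] * tr[[map[[o]]$component]],
                       observable = o, condition = cond)
      }))
    }))
    lines <- dplyr::semi_join(lines, df, by = c("observable", "condition"))
    pl <- pl + ggplot2::geom_line(data = lines)
  }
  pl
}
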