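#' Plot a decade-binned discovery series
#'
#' Cumulative described species per decade, optionally with fitted growth
#' curves and their asymptotes overlaid.
#'
#' @param series A `decade_series` tibble (or several stacked, with a
#'   `stratum` column).
#' @param fits Optional tibble from [fit_growth_models()] (single
#'   stratum).
#' @return A ggplot object.
#' @export
plot_discovery_curve <- function(series, fits = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(series),
                       ggplot2::aes(x = .data$decade_start,
                                    y = .data$cumulative)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Decade", y = "Cumulative species described")
  if (!is.na(series$stratum[1]) &&
      dplyr::n_distinct(series$stratum) > 1) {
    p <- p + ggplot2::facet_wrap(~stratum, scales = "free_y")
  }
  if (!is.null(fits) && "fit" %in% names(fits)) {
    curves <- purrr::map_dfr(fits$fit, function(f) {
      if (!f$converged) return(NULL)
      tt <- seq(min(f$data$t), max(f$data$t), length.out = 200)
      tibble::tibble(
        model = f$model,
        decade_start = stats::approx(f$data$t, f$data$decade_start,
                                     xout = tt)$y,
        cumulative = growth_curve(f$model, tt, f$params)
      )
    })
    if (nrow(curves) > 0) {
      p <- p + ggplot2::geom_line(
        data = curves, ggplot2::aes(colour = .data$model), linewidth = 0.6
      ) + ggplot2::labs(colour = "Model")
    }
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  dat <- tibble::as_tibble(object$data)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t,
                                         y = .data$cumulative)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Decade index", y = "Cumulative species",
                  title = object$model)
  if (object$converged) {
    tt <- seq(min(dat$t), max(dat$t), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(t = tt,
                            cumulative = growth_curve(object$model, tt,
                                                      object$params)),
      colour = "steelblue"
    ) +
      ggplot2::geom_hline(yintercept = object$asymptote,
                          linetype = "dashed")
  }
  p
}

#' Plot per-decade taxonomist counts and description rates
#'
#' @param effort An `effort_series` tibble from [count_taxonomists()].
#' @return A ggplot object.
#' @export
plot_effort_series <- function(effort) {
  long <- tibble::as_tibble(effort) |>
    dplyr::select("decade_start", "taxonomists",
                  "species_per_taxonomist") |>
    tidyr::pivot_longer(-"decade_start")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$decade_start,
                                     y = .data$value)) +
    ggplot2::geom_col(width = 8) +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Decade", y = NULL)
}

#' Map discovery priority over the analysis grid
#'
#' Tile map of the 0-10 priority score (10 = highest discovery
#' potential), optionally with polygon layers outlined.
#'
#' @param grid A `discovery_grid` with a `priority` column.
#' @param polygons Optional polygon tibble to outline.
#' @return A ggplot object.
#' @export
plot_priority_map <- function(grid, polygons = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(grid)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$priority
    )) +
    ggplot2::scale_fill_gradient(low = "darkgreen", high = "white",
                                 limits = c(0, 10)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Priority")
  if (!is.null(polygons) && nrow(polygons) > 0) {
    p <- p + ggplot2::geom_polygon(
      data = tibble::as_tibble(polygons),
      ggplot2::aes(x = .data$lon, y = .data$lat,
                   group = .data$polygon_id, colour = .data$layer),
      fill = NA, linewidth = 0.4
    )
  }
  p
}
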