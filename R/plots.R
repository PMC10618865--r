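#' Plot range overlap (or symmetry) against node age
#'
#' The classic age-range correlation panel: one point per sister pair,
#' colored by sympatry class, with the least-squares line.
#'
#' @param table pair table from [build_pair_table()].
#' @param y `"overlap"` or `"symmetry"`.
#' @return a ggplot object.
#' @export
plot_age_range <- function(table, y = c("overlap", "symmetry")) {
  y <- match.arg(y)
  dat <- dplyr::filter(table, !is.na(.data[[y]]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$node_age, y = .data[[y]])) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "grey40", linewidth = 0.6) +
    ggplot2::geom_point(ggplot2::aes(color = .data$classification), size = 2) +
    ggplot2::labs(x = "Node age (Ma)",
                  y = if (y == "overlap") "Range overlap O" else "Range symmetry S",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of trait contrasts by sympatry class
#'
#' @param table pair table from [build_pair_table()].
#' @param trait `"depth"` or `"length"`.
#' @return a ggplot object.
#' @export
plot_contrasts <- function(table, trait = c("depth", "length")) {
  trait <- match.arg(trait)
  col <- if (trait == "depth") "contrast_depth" else "contrast_length"
  lab <- if (trait == "depth") "Max depth contrast (m)" else "Max length contrast (cm)"
  dat <- dplyr::filter(table, !is.na(.data[[col]]), !is.na(.data$classification))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$classification, y = .data[[col]],
                                    fill = .data$classification)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Heatmap of stacked species richness
#'
#' @param richness integer matrix from [range_richness()] (with its `grid`
#'   attribute).
#' @return a ggplot object.
#' @export
plot_richness <- function(richness) {
  grid <- attr(richness, "grid")
  stopifnot(!is.null(grid))
  dat <- tidyr::expand_grid(lat = grid_lat_centers(grid),
                            lon = grid_lon_centers(grid))
  dat <- dat[order(dat$lon, dat$lat), ]
  dat$richness <- as.vector(richness)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lon, y = .data$lat,
                                    fill = .data$richness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Species") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.arc_regression <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "grey40") +
    ggplot2::labs(x = object$x, y = object$y,
                  subtitle = sprintf("slope = %.3g, r = %.3g, p = %.3g",
                                     object$slope, object$r, object$p_value)) +
    ggplot2::theme_minimal()
}
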