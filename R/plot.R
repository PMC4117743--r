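#' Plot a scaling profile on log-log axes
#'
#' @param object A `csac_profile` from [msd_profile()] or
#'   [contact_probability()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csac_profile <- function(object, ...) {
  type <- attr(object, "profile_type")
  ycol <- if (identical(type, "msd")) "R2" else "Pc"
  ylab <- if (identical(type, "msd")) {
    expression(R^2 * (s) ~ "[" * nm^2 * "]")
  } else {
    expression(P[c](s))
  }
  df <- dplyr::filter(tibble::as_tibble(object),
                      !is.na(.data[[ycol]]), .data[[ycol]] > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data[[ycol]])) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(s ~ "[persistence units]"), y = ylab) +
    ggplot2::theme_bw()
}

#' Plot a power-law fit over its data
#'
#' @param object A `csac_fit`.
#' @param data The profile or data frame the fit was computed from.
#' @param x,y Column names when `data` is a plain data frame.
#' @param ... Unused.
#' @return A ggplot with the fitted line over the fit range.
#' @export
autoplot.csac_fit <- function(object, data, x = NULL, y = NULL, ...) {
  type <- attr(data, "profile_type")
  if (is.null(x)) {
    x <- "s"
    y <- if (identical(type, "msd")) "R2" else "Pc"
  }
  df <- dplyr::filter(tibble::as_tibble(data),
                      !is.na(.data[[y]]), .data[[y]] > 0)
  seg <- tibble::tibble(x = 10^seq(log10(object$fit_range[1]),
                                   log10(object$fit_range[2]),
                                   length.out = 50))
  seg$y <- object$amplitude * seg$x^object$slope
  lbl <- sprintf("exponent = %.3f", object$exponent)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = seg,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(subtitle = lbl, x = x, y = y) +
    ggplot2::theme_bw()
}

#' Distance-matrix heat map of one conformation
#'
#' Spatial distances between loci, darker meaning closer -- the model
#' analogue of a single-chain contact map; domain-like substructures
#' appear as dark blocks on the diagonal.
#'
#' @param conf A `csac_conformation`.
#' @param resolution Units or beads.
#' @return A ggplot.
#' @export
plot_distance_map <- function(conf, resolution = c("units", "beads")) {
  m <- distance_matrix(conf, resolution)
  df <- tibble::tibble(
    i = rep(seq_len(nrow(m)), times = ncol(m)),
    j = rep(seq_len(ncol(m)), each = nrow(m)),
    d = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$d)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "distance [nm]") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "persistence unit", y = "persistence unit") +
    ggplot2::theme_bw()
}
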