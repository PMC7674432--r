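#' @importFrom rlang .data %||%
NULL

#' Plot polarization maps
#'
#' Raster display of the modulation-depth, orientation or mean-intensity
#' image; invalid pixels are blank.
#'
#' @param object A `polarization_maps` object.
#' @param what `"m"`, `"phi"` or `"a0"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polarization_maps <- function(object, what = c("m", "phi", "a0"), ...) {
  what <- match.arg(what)
  df <- tidy(object)
  df$value <- df[[what]]
  df$value[!df$mask] <- NA
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (what == "m") {
    p + ggplot2::scale_fill_viridis_c(name = "modulation\ndepth",
                                      limits = c(0, 1), na.value = "grey20",
                                      option = "mako")
  } else if (what == "phi") {
    p + ggplot2::scale_fill_gradientn(
      name = "orientation\n(rad)",
      colours = grDevices::hsv(seq(0, 1, length.out = 64)),
      limits = c(0, pi), na.value = "grey20"
    )
  } else {
    p + ggplot2::scale_fill_viridis_c(name = "a0", na.value = "grey20")
  }
}

#' Plot an emission-ratio (polarity) map
#'
#' Warm-colormap raster of the channel ratio; masked pixels are blank.
#'
#' @param object A `polarity_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polarity_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradientn(
      name = sprintf("%s / %s", object$channels[1], object$channels[2]),
      colours = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
      na.value = "grey20"
    ) +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a two-fluorophore accuracy report
#'
#' Mapping error per quantity and resolution mode, faceted by channel-split
#' convention and fluorophore.
#'
#' @param object A `spot_accuracy_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spot_accuracy_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$quantity, .data$error_pct,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(convention ~ fluorophore) +
    ggplot2::labs(x = NULL, y = "mapping error (%)", fill = "resolution")
}

#' Polarity-phase scatter with group ellipses
#'
#' The classification view: per-structure (emission ratio, modulation depth)
#' measurements with each group's sigma (solid) and 2-sigma (dashed)
#' contours.
#'
#' @param points Data frame with `ratio`, `depth` and optionally `label`.
#' @param ellipses List of [fit_group_ellipse()] results.
#' @return A ggplot.
#' @export
plot_polarity_phase <- function(points, ellipses) {
  cont <- purrr::map(ellipses, function(e) {
    dplyr::bind_rows(
      dplyr::mutate(ellipse_contour(e, 1), contour = "sigma", label = e$label),
      dplyr::mutate(ellipse_contour(e, 2), contour = "2 sigma", label = e$label)
    )
  }) |> purrr::list_rbind()
  aes_pt <- if ("label" %in% names(points)) {
    ggplot2::aes(.data$ratio, .data$depth, colour = .data$label)
  } else {
    ggplot2::aes(.data$ratio, .data$depth)
  }
  ggplot2::ggplot(points, aes_pt) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_path(
      data = cont,
      ggplot2::aes(.data$ratio, .data$depth, colour = .data$label,
                   linetype = .data$contour),
      inherit.aes = FALSE
    ) +
    ggplot2::scale_linetype_manual(values = c("sigma" = "solid",
                                              "2 sigma" = "dashed")) +
    ggplot2::labs(x = "emission ratio (polarity)",
                  y = "modulation depth (phase)")
}

#' Export an orientation map as an HSV-coded PNG
#'
#' Hue encodes the dipole orientation (0 to pi over the hue circle), value
#' the mean intensity `a0`; invalid pixels are black. Display parity with
#' the usual orientation-map figures.
#'
#' @param maps A `polarization_maps` object.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
export_orientation_png <- function(maps, path) {
  stopifnot(inherits(maps, "polarization_maps"))
  h <- maps$phi / pi
  v <- maps$a0 / max(maps$a0, 1e-12)
  h[!maps$mask | is.na(h)] <- 0
  v[!maps$mask] <- 0
  col <- grDevices::hsv(pmin(pmax(h, 0), 1), 1, pmin(pmax(v, 0), 1))
  rgb <- grDevices::col2rgb(col) / 255
  arr <- array(0, c(nrow(h), ncol(h), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(h))
  arr[, , 2] <- matrix(rgb[2, ], nrow(h))
  arr[, , 3] <- matrix(rgb[3, ], nrow(h))
  png::writePNG(arr, path)
  invisible(path)
}
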