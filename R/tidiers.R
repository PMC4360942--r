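## broom-style tidiers and ggplot2 autoplot methods for the fitted objects
## and reconstruction results.

#' Tidy a photon-transfer gain fit
#'
#' @param x A `gain_fit`.
#' @param ... Unused.
#' @return A tibble of the per-level fit points: `mean_dn`, `variance_dn2`,
#'   `used` (FALSE for saturation-excluded levels), and the fitted
#'   variance `.fitted`.
#' @export
tidy.gain_fit <- function(x, ...) {
  dplyr::mutate(x$fit_points,
                .fitted = x$gain_dn_per_photon * .data$mean_dn +
                  x$read_noise_var_dn2)
}

#' Glance at a photon-transfer gain fit
#'
#' @param x A `gain_fit`.
#' @param ... Unused.
#' @return A one-row tibble: gain, offset, read-noise variance, levels
#'   used/excluded.
#' @export
glance.gain_fit <- function(x, ...) {
  tibble::tibble(gain_dn_per_photon = x$gain_dn_per_photon,
                 offset_dn = x$offset_dn,
                 read_noise_var_dn2 = x$read_noise_var_dn2,
                 read_noise_sigma_dn = sqrt(x$read_noise_var_dn2),
                 levels_used = x$levels_used,
                 levels_excluded = x$levels_excluded)
}

#' Glance at a modulation-contrast fit
#'
#' @param x A `contrast_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the contrast and selection diagnostics.
#' @export
glance.contrast_fit <- function(x, ...) {
  tibble::tibble(modulation_contrast = x$modulation_contrast,
                 pixels_used = x$pixels_used,
                 selection_threshold = x$selection_threshold,
                 ratio_median = x$ratio_median,
                 ratio_iqr = x$ratio_iqr)
}

#' Tidy a quantitative reconstruction result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return A long tibble with one row per pixel and image: `row`, `col`,
#'   `image`, `photons`, plus the depth metadata.
#' @export
tidy.quant_result <- function(x, ...) {
  imgs <- quant_image_list(x)
  purrr::map_dfr(names(imgs), function(nm) {
    img <- imgs[[nm]]
    tibble::tibble(row = as.vector(base::row(img)),
                   col = as.vector(base::col(img)),
                   image = nm, photons = as.vector(img))
  }) |>
    dplyr::mutate(depth_index = x$depth_index, depth_um = x$depth_um)
}

#' Glance at a quantitative reconstruction result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return A one-row tibble of per-image means and the depth metadata.
#' @export
glance.quant_result <- function(x, ...) {
  tibble::tibble(depth_index = x$depth_index, depth_um = x$depth_um,
                 rows = nrow(x$widefield_photons),
                 cols = ncol(x$widefield_photons),
                 widefield_mean = mean(x$widefield_photons),
                 sectioned_mean = mean(x$sectioned_photons),
                 widefield_noise_mean = mean(x$widefield_noise),
                 sectioned_noise_mean = mean(x$sectioned_noise))
}

#' Plot a photon-transfer gain fit
#'
#' Variance-versus-mean points with the fitted photon-transfer line;
#' saturation-excluded levels are hollow.
#'
#' @param object A `gain_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gain_fit <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean_dn, y = .data$variance_dn2)) +
    ggplot2::geom_abline(intercept = object$read_noise_var_dn2,
                         slope = object$gain_dn_per_photon,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = "mean signal above dark (DN)", y = "temporal variance (DN²)",
      title = sprintf("Photon transfer: g = %.3g DN/photon, read noise %.3g DN",
                      object$gain_dn_per_photon,
                      sqrt(object$read_noise_var_dn2))) +
    ggplot2::theme_minimal()
}

#' Plot the four images of a quantitative result
#'
#' Raster panels of the wide-field and sectioned photon images and their
#' noise maps, on a common photon colour scale per row type.
#'
#' @param object A `quant_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quant_result <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(image = factor(.data$image, levels = quant_images()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$photons)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~image, nrow = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "photons") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Quantitative SIM output, depth %d",
                                  object$depth_index)) +
    ggplot2::theme_minimal()
}

#' Plot photon/noise histograms
#'
#' Step histograms comparing the sectioned and wide-field images (and
#' their noise maps) from [photon_noise_histograms()].
#'
#' @param histograms Tibble from [photon_noise_histograms()].
#' @return A ggplot.
#' @export
plot_photon_histograms <- function(histograms) {
  df <- dplyr::mutate(histograms,
                      panel = ifelse(grepl("noise", .data$image),
                                     "noise (photons)", "light energy (photons)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$count,
                                   colour = .data$image)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "photons", y = "pixel count") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
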