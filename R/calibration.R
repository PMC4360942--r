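## Calibration experiment 1: camera gain and read noise by the
## photon-transfer method (variance-vs-mean of flat-field pairs).
## Calibration experiment 2: illumination modulation contrast from a thin
## fluorescent bead field.

#' Flat-field calibration series
#'
#' A photon-transfer gain calibration data set: at each of more than five
#' illumination levels, from dark to near saturation, two uniformly
#' illuminated ("empty field") frames taken with the same integration time.
#' The first level must be the dark (zero illumination) pair; it defines the
#' camera offset.
#'
#' @param levels List of levels, each a list with numeric matrices
#'   `frame_a` and `frame_b` (identical dimensions, grey-level DN) and
#'   optionally `nominal_order` (integer rank; defaults to list position).
#' @param bit_depth Camera digitization depth in bits (8--16).
#' @param integration_time_tag Free-text metadata describing the exposure.
#'
#' @return An object of class `flatfield_series`.
#' @seealso [mean_variance_points()], [fit_gain()], [calibrate_gain()],
#'   [render_flatfield_series()] to simulate one.
#' @export
flatfield_series <- function(levels, bit_depth = 12L, integration_time_tag = "") {
  if (!is.list(levels) || length(levels) < 6L) {
    ps_insufficient_levels_error(sprintf(
      "a flat-field series needs more than five illumination levels; got %d.",
      length(levels)))
  }
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 8L || bit_depth > 16L) {
    ps_parameter_error("`bit_depth` must be an integer between 8 and 16.")
  }
  dims <- NULL
  levels <- lapply(seq_along(levels), function(i) {
    lv <- levels[[i]]
    if (!is.list(lv) || is.null(lv$frame_a) || is.null(lv$frame_b)) {
      ps_format_error(sprintf("level %d must contain `frame_a` and `frame_b`.", i))
    }
    a <- lv$frame_a; b <- lv$frame_b
    if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b))) {
      ps_format_error(sprintf(
        "level %d: the two frames must be matrices of identical dimensions.", i))
    }
    if (!is.null(dims) && !identical(dim(a), dims)) {
      ps_format_error(sprintf(
        "level %d: frame dimensions differ from earlier levels.", i))
    }
    dims <<- dim(a)
    list(frame_a = a * 1.0, frame_b = b * 1.0,
         nominal_order = lv$nominal_order %||% i)
  })
  structure(list(levels = levels, bit_depth = bit_depth,
                 integration_time_tag = integration_time_tag),
            class = "flatfield_series")
}

#' @export
print.flatfield_series <- function(x, ...) {
  d <- dim(x$levels[[1]]$frame_a)
  cat(sprintf("<flatfield_series> %d levels, %d x %d frames, %d-bit\n",
              length(x$levels), d[1], d[2], x$bit_depth))
  invisible(x)
}

#' Mean-variance points from a flat-field series
#'
#' For each illumination level computes the photon-transfer point
#' (mean DN above dark, variance in DN^2).  The mean is the spatial mean of
#' `(frame_a + frame_b)/2` minus the dark level (the mean of the first,
#' zero-illumination pair); the variance is the spatial variance of
#' `frame_a - frame_b` divided by 2.  Differencing the paired frames cancels
#' any static per-pixel structure (photo-response and offset fixed-pattern
#' noise), leaving only the temporal shot + read noise that the
#' photon-transfer relation describes.
#'
#' @param series A [flatfield_series()].
#' @return A tibble with one row per level: `level`, `mean_dn`,
#'   `variance_dn2`, plus the dark offset as attribute `offset_dn`.
#' @export
mean_variance_points <- function(series) {
  stopifnot(inherits(series, "flatfield_series"))
  offset <- mean((series$levels[[1]]$frame_a + series$levels[[1]]$frame_b) / 2)
  rows <- purrr::map_dfr(seq_along(series$levels), function(i) {
    lv <- series$levels[[i]]
    tibble::tibble(
      level = i,
      mean_dn = mean((lv$frame_a + lv$frame_b) / 2) - offset,
      variance_dn2 = stats::var(as.vector(lv$frame_a - lv$frame_b)) / 2)
  })
  attr(rows, "offset_dn") <- offset
  rows
}

new_gain_fit <- function(gain_dn_per_photon, offset_dn, read_noise_var_dn2,
                         fit_points = tibble::tibble(mean_dn = numeric(),
                                                     variance_dn2 = numeric(),
                                                     used = logical()),
                         levels_used = NA_integer_, levels_excluded = NA_integer_,
                         bit_depth = NA_integer_) {
  structure(
    list(gain_dn_per_photon = gain_dn_per_photon,
         offset_dn = offset_dn,
         read_noise_var_dn2 = read_noise_var_dn2,
         fit_points = fit_points,
         levels_used = levels_used,
         levels_excluded = levels_excluded,
         bit_depth = bit_depth),
    class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat("<gain_fit>\n")
  cat(sprintf("  gain:            %.6g DN/photon\n", x$gain_dn_per_photon))
  cat(sprintf("  dark offset:     %.6g DN\n", x$offset_dn))
  cat(sprintf("  read noise var:  %.6g DN^2 (sigma %.4g DN)\n",
              x$read_noise_var_dn2, sqrt(x$read_noise_var_dn2)))
  cat(sprintf("  levels used/excluded: %s/%s\n", x$levels_used, x$levels_excluded))
  invisible(x)
}

#' Fit camera gain and read noise to photon-transfer points
#'
#' Fits the photon-transfer line `variance = g * mean + read_noise_var` to
#' the per-level (mean, variance) points.  The slope is the camera gain in
#' DN/photon; the intercept is the read-noise variance in DN^2.  Levels
#' whose absolute mean exceeds `saturation_cut` of full scale are excluded
#' before fitting (clipping at saturation destroys the linear relation).
#'
#' By default the fit is weighted least squares with the standard
#' photon-transfer weights `1/variance^2`, applied in two passes (ordinary
#' least squares to get fitted variances, then the weighted refit): the
#' sampling error of a sample variance is proportional to the variance
#' itself, so unweighted fitting lets the brightest, noisiest points swamp
#' the intercept and makes the read-noise estimate practically worthless.
#' `weights = "none"` restores the plain OLS fit.
#'
#' @param points Data frame with columns `mean_dn` (dark-subtracted) and
#'   `variance_dn2`, e.g. from [mean_variance_points()].
#' @param bit_depth Camera digitization bits, for the saturation cut.
#' @param saturation_cut Levels with `mean_dn + offset_dn` above this
#'   fraction of `2^bit_depth - 1` are excluded (default 0.9).
#' @param offset_dn Dark level in DN, copied into the result (and used in
#'   the saturation comparison).  Taken from the `offset_dn` attribute of
#'   `points` when present.
#' @param weights `"ptc"` (photon-transfer weights, default) or `"none"`.
#'
#' @return A `gain_fit` object; see also [tidy()] and [glance()] methods.
#' @export
#' @examples
#' pts <- tibble::tibble(mean_dn = c(0, 100, 200, 400, 800, 1600),
#'                       variance_dn2 = 0.5 * c(0, 100, 200, 400, 800, 1600) + 3)
#' fit_gain(pts, bit_depth = 12)   # recovers g = 0.5, read noise 3 exactly
fit_gain <- function(points, bit_depth = 12L, saturation_cut = 0.9,
                     offset_dn = NULL, weights = c("ptc", "none")) {
  weights <- match.arg(weights)
  offset_dn <- offset_dn %||% attr(points, "offset_dn") %||% 0
  points <- tibble::as_tibble(points[, c("mean_dn", "variance_dn2")])
  if (nrow(points) < 6L) {
    ps_insufficient_levels_error(sprintf(
      "gain fitting needs more than five mean-variance points; got %d.",
      nrow(points)))
  }
  full_scale <- 2^as.integer(bit_depth) - 1
  usable <- (points$mean_dn + offset_dn) <= saturation_cut * full_scale
  if (sum(usable) < 5L) {
    ps_insufficient_levels_error(sprintf(
      "only %d levels remain below the %.0f%% saturation cut; at least 5 are required.",
      sum(usable), 100 * saturation_cut))
  }
  pts <- points[usable, ]
  fit <- stats::lm(variance_dn2 ~ mean_dn, data = pts)
  if (weights == "ptc") {
    w <- 1 / pmax(stats::fitted(fit), .Machine$double.eps)^2
    fit <- stats::lm(variance_dn2 ~ mean_dn, data = pts, weights = w)
  }
  g <- unname(coef(fit)[["mean_dn"]])
  icpt <- unname(coef(fit)[["(Intercept)"]])
  if (!is.finite(g) || g <= 0) {
    ps_calibration_error(sprintf(
      "photon-transfer fit failed: non-positive slope (%.4g DN/photon).", g))
  }
  if (icpt < 0) {
    rlang::warn(sprintf(
      "negative read-noise intercept (%.4g DN^2) clamped to 0.", icpt),
      class = "photonsim_warning")
    icpt <- 0
  }
  new_gain_fit(
    gain_dn_per_photon = g, offset_dn = offset_dn, read_noise_var_dn2 = icpt,
    fit_points = tibble::tibble(mean_dn = points$mean_dn,
                                variance_dn2 = points$variance_dn2,
                                used = usable),
    levels_used = sum(usable), levels_excluded = sum(!usable),
    bit_depth = as.integer(bit_depth))
}

#' One-call gain calibration from a flat-field series
#'
#' Convenience wrapper: [mean_variance_points()] then [fit_gain()], with the
#' series' bit depth and dark offset carried through.
#'
#' @inheritParams mean_variance_points
#' @inheritParams fit_gain
#' @return A `gain_fit`.
#' @export
calibrate_gain <- function(series, saturation_cut = 0.9,
                           weights = c("ptc", "none")) {
  pts <- mean_variance_points(series)
  fit_gain(pts, bit_depth = series$bit_depth, saturation_cut = saturation_cut,
           offset_dn = attr(pts, "offset_dn"), weights = match.arg(weights))
}

#' Photon count of a uniform field from its grey-level statistics
#'
#' For a shot-noise-limited detector with linear gain the detected photon
#' number of a uniformly illuminated field is `(mean / sigma)^2`: shot-noise
#' variance equals the photon count, so the gain cancels from the ratio.
#' Used as the consistency cross-check on the photon-transfer calibration.
#'
#' @param mean_dn_offset_subtracted Mean grey level above dark, in DN.
#' @param sigma_dn Standard deviation of the grey-level distribution, DN.
#' @return Estimated photon count.
#' @export
#' @examples
#' photon_count_uniform(400, 20)   # 400 photons
photon_count_uniform <- function(mean_dn_offset_subtracted, sigma_dn) {
  if (!is.numeric(sigma_dn) || any(sigma_dn <= 0)) {
    ps_degenerate_input_error(
      "`sigma_dn` must be > 0: a noiseless signal has no shot-noise photon count.")
  }
  (mean_dn_offset_subtracted / sigma_dn)^2
}

#' @export
print.contrast_fit <- function(x, ...) {
  cat("<contrast_fit>\n")
  cat(sprintf("  modulation contrast m: %.6g\n", x$modulation_contrast))
  cat(sprintf("  pixels used: %d (threshold %.4g DN)\n",
              x$pixels_used, x$selection_threshold))
  cat(sprintf("  sectioned/widefield ratio: median %.4g, IQR %.4g\n",
              x$ratio_median, x$ratio_iqr))
  invisible(x)
}

new_contrast_fit <- function(modulation_contrast, pixels_used = NA_integer_,
                             selection_threshold = NA_real_,
                             ratio_median = modulation_contrast,
                             ratio_iqr = NA_real_) {
  structure(
    list(modulation_contrast = modulation_contrast, pixels_used = pixels_used,
         selection_threshold = selection_threshold, ratio_median = ratio_median,
         ratio_iqr = ratio_iqr),
    class = "contrast_fit")
}

#' Estimate the illumination modulation contrast from a bead field
#'
#' The modulation contrast `m` -- the AC/DC ratio of the illumination grid
#' at the sample plane -- converts demodulated amplitude into in-focus
#' photons.  It is specific to each objective / grid-frequency combination
#' and is measured once from a raw SIM triplet of a thin fluorescent
#' microsphere layer (beads smaller than the sectioning thickness, so
#' essentially no out-of-focus light).  For such a sample the
#' sectioned-to-wide-field ratio equals `m` exactly at every lit pixel, so
#' the estimator offset-subtracts the triplet, selects bright wide-field
#' pixels, and takes the median of the per-pixel ratio
#' `sectioned_raw / widefield_raw` (camera gain cancels in the ratio).
#'
#' Any uniform out-of-focus background biases the ratio downward (the
#' wide-field denominator grows while the modulated numerator does not) --
#' the quantitative reason the bead layer must be thin.
#'
#' @param bead_triplet A [phase_triplet()] in DN (raw, ungridded processing).
#' @param gain A `gain_fit`; supplies the dark offset and the noise floor.
#' @param selection_quantile Bright-pixel selection: keep wide-field pixels
#'   at or above this quantile (default 0.95, i.e. the top 5%).
#' @param noise_floor_dn Absolute wide-field brightness floor (DN above
#'   dark) that selected pixels must also exceed; defaults to 10 read-noise
#'   standard deviations (at least 10 DN), which rejects everything in an
#'   all-dark image.
#' @param prefactor Demodulation prefactor, see [sectioned_raw()]; must
#'   match the one used at reconstruction time.
#'
#' @return A `contrast_fit` with the global scalar `modulation_contrast`.
#' @export
estimate_modulation_contrast <- function(bead_triplet, gain,
                                         selection_quantile = 0.95,
                                         noise_floor_dn = NULL,
                                         prefactor = sqrt(2) / 3) {
  stopifnot(inherits(bead_triplet, "phase_triplet"), inherits(gain, "gain_fit"))
  if (bead_triplet$pixel_unit != "DN") {
    ps_usage_error("contrast calibration expects the raw bead triplet in DN.")
  }
  if (selection_quantile <= 0 || selection_quantile >= 1) {
    ps_parameter_error("`selection_quantile` must lie strictly between 0 and 1.")
  }
  noise_floor_dn <- noise_floor_dn %||%
    max(10 * sqrt(max(gain$read_noise_var_dn2, 0)), 10)
  off <- gain$offset_dn
  t0 <- phase_triplet(bead_triplet$i1 - off, bead_triplet$i2 - off,
                      bead_triplet$i3 - off, pixel_unit = "DN")
  s <- sectioned_raw(t0, prefactor = prefactor)
  w <- widefield_raw(t0)
  thr <- stats::quantile(w, selection_quantile, names = FALSE)
  sel <- w >= thr & w > noise_floor_dn
  if (!any(sel)) {
    ps_empty_selection_error(sprintf(
      "no pixels pass the bead selection (quantile %.2f, floor %.3g DN above dark): the field looks dark.",
      selection_quantile, noise_floor_dn))
  }
  ratios <- s[sel] / w[sel]
  m <- stats::median(ratios)
  if (!is.finite(m) || m <= 0 || m > 1) {
    ps_implausible_contrast_error(sprintf(
      "median sectioned/widefield ratio %.4g lies outside (0, 1]; check the grid focus and the concatenation layout.",
      m))
  }
  new_contrast_fit(modulation_contrast = m, pixels_used = sum(sel),
                   selection_threshold = thr, ratio_median = m,
                   ratio_iqr = stats::IQR(ratios))
}
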