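## Photon-calibrated reconstruction: DN -> photons, demodulation with
## shot-noise debiasing, delta-method noise maps, 3D stacks, histograms.

#' Calibration profile
#'
#' Bundles the two calibration results -- camera gain ([fit_gain()]) and
#' illumination modulation contrast ([estimate_modulation_contrast()]) --
#' with provenance metadata.  One profile is valid for one combination of
#' camera settings, objective and illumination grid.
#'
#' @param gain A `gain_fit`.
#' @param contrast A `contrast_fit`, or a single number in (0, 1] taken as
#'   the modulation contrast.
#' @param created_with Named list of free-text metadata (objective, grid
#'   descriptor, camera tag, ...), stored and written to the calibration
#'   file.
#' @return An object of class `calibration_profile`.
#' @seealso [write_calibration()], [read_calibration()]
#' @export
calibration_profile <- function(gain, contrast, created_with = list()) {
  stopifnot(inherits(gain, "gain_fit"))
  if (is.numeric(contrast) && length(contrast) == 1L) {
    contrast <- new_contrast_fit(contrast)
  }
  stopifnot(inherits(contrast, "contrast_fit"))
  m <- contrast$modulation_contrast
  if (!is.finite(m) || m <= 0 || m > 1) {
    ps_calibration_error(sprintf(
      "modulation contrast must lie in (0, 1]; got %.4g.", m))
  }
  structure(list(gain = gain, contrast = contrast,
                 created_with = created_with),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile>\n")
  cat(sprintf("  gain %.6g DN/photon, offset %.6g DN, read noise var %.6g DN^2\n",
              x$gain$gain_dn_per_photon, x$gain$offset_dn,
              x$gain$read_noise_var_dn2))
  cat(sprintf("  modulation contrast m = %.6g\n",
              x$contrast$modulation_contrast))
  invisible(x)
}

#' Convert a grey-level image to photons
#'
#' `(DN - offset) / gain` per pixel.  Noise fluctuations below the dark
#' level yield slightly negative photon values; they are retained (not
#' clamped) so that downstream averages stay unbiased.
#'
#' @param image_dn Numeric matrix in DN.
#' @param gain A `gain_fit`.
#' @return A matrix in photon units.
#' @export
#' @examples
#' g <- photonsim:::new_gain_fit(2, 100, 4)
#' to_photons(matrix(300, 1, 1), g)   # 100 photons
to_photons <- function(image_dn, gain) {
  stopifnot(inherits(gain, "gain_fit"))
  (image_dn - gain$offset_dn) / gain$gain_dn_per_photon
}

triplet_to_photons <- function(t, gain) {
  if (t$pixel_unit == "photons") return(t)
  phase_triplet(to_photons(t$i1, gain), to_photons(t$i2, gain),
                to_photons(t$i3, gain), pixel_unit = "photons")
}

## per-frame total noise variance in photons^2: shot (plug-in, clamped at 0)
## plus read noise referred to the input
frame_variances <- function(t_photons, gain) {
  rv <- gain$read_noise_var_dn2 / gain$gain_dn_per_photon^2
  list(v1 = pmax(t_photons$i1, 0) + rv,
       v2 = pmax(t_photons$i2, 0) + rv,
       v3 = pmax(t_photons$i3, 0) + rv)
}

new_quant_result <- function(widefield_photons, sectioned_photons,
                             widefield_noise, sectioned_noise,
                             depth_index = 0L, depth_um = NA_real_) {
  structure(
    list(widefield_photons = widefield_photons,
         sectioned_photons = sectioned_photons,
         widefield_noise = widefield_noise,
         sectioned_noise = sectioned_noise,
         depth_index = as.integer(depth_index), depth_um = depth_um),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> depth %d%s, %d x %d pixels (photons)\n",
    x$depth_index,
    if (is.na(x$depth_um)) "" else sprintf(" (%g um)", x$depth_um),
    nrow(x$widefield_photons), ncol(x$widefield_photons)))
  cat(sprintf("  widefield: mean %.4g    sectioned: mean %.4g\n",
              mean(x$widefield_photons), mean(x$sectioned_photons)))
  invisible(x)
}

#' @export
dim.quant_result <- function(x) dim(x$widefield_photons)

quant_images <- function() {
  c("widefield", "sectioned", "widefield_noise", "sectioned_noise")
}

quant_image_list <- function(r) {
  list(widefield = r$widefield_photons, sectioned = r$sectioned_photons,
       widefield_noise = r$widefield_noise, sectioned_noise = r$sectioned_noise)
}

#' Predicted noise map of the wide-field image
#'
#' The wide-field image is the mean of three frames, so its variance is the
#' sum of the per-frame variances over 9: per-pixel
#' `sigma_W = sqrt((N1 + N2 + N3)/9 + 3 * sigma_r^2 / (9 g^2))`, with shot
#' variance taken as the observed photon count of each frame (plug-in,
#' clamped at zero) and the read-noise variance referred to photons.
#'
#' @param t_photons A [phase_triplet()] in photon units.
#' @param gain A `gain_fit` (supplies the read-noise variance and gain).
#' @return An M x N matrix of predicted standard deviations, in photons.
#' @export
noise_widefield <- function(t_photons, gain) {
  stopifnot(inherits(t_photons, "phase_triplet"))
  if (t_photons$pixel_unit != "photons") {
    ps_usage_error("`t_photons` must be in photon units; see to_photons().")
  }
  v <- frame_variances(t_photons, gain)
  sqrt((v$v1 + v$v2 + v$v3) / 9)
}

#' Predicted noise map of the sectioned image
#'
#' First-order (delta-method) propagation of per-frame shot + read noise
#' through the square-law demodulation, then division by the modulation
#' contrast.  With `D` the sum of squared pairwise differences, the
#' demodulation partials are
#' `dIs/dIi = (sqrt(2)/3) (2 Ii - Ij - Ik) / sqrt(D)`, so
#' `Var(Is) = sum_i (dIs/dIi)^2 (Ni + sigma_r^2/g^2)` and the returned map
#' is `sqrt(Var(Is)) / m`.  Where `D` is numerically zero (locally
#' unmodulated pixel) the singular partials are replaced by their
#' phase-averaged limit `Var(Is) = (2/3) * mean per-frame variance`.
#'
#' Out-of-focus light is removed from the sectioned image but its shot
#' noise is not: the map increases monotonically with the background level
#' and decreases monotonically with `m`, so sectioned noise always exceeds
#' wide-field noise for the same scene whenever `m <= 1`.
#'
#' @inheritParams noise_widefield
#' @param m Modulation contrast in (0, 1].
#' @param prefactor Demodulation prefactor, see [sectioned_raw()].
#' @return An M x N matrix of predicted standard deviations, in photons.
#' @export
noise_sectioned <- function(t_photons, m, gain, prefactor = sqrt(2) / 3) {
  stopifnot(inherits(t_photons, "phase_triplet"))
  if (t_photons$pixel_unit != "photons") {
    ps_usage_error("`t_photons` must be in photon units; see to_photons().")
  }
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0) {
    ps_calibration_error("modulation contrast `m` must be a positive number.")
  }
  v <- frame_variances(t_photons, gain)
  var_s <- sectioned_var_delta(t_photons, v, prefactor)
  sqrt(var_s) / m
}

## delta-method Var(Is); `v` = list of per-frame variances (photons^2)
sectioned_var_delta <- function(t, v, prefactor = sqrt(2) / 3) {
  i1 <- t$i1; i2 <- t$i2; i3 <- t$i3
  d <- pairwise_sq_diff(t)
  g1 <- 2 * i1 - i2 - i3
  g2 <- 2 * i2 - i1 - i3
  g3 <- 2 * i3 - i1 - i2
  num <- g1^2 * v$v1 + g2^2 * v$v2 + g3^2 * v$v3
  scale2 <- pmax(i1^2 + i2^2 + i3^2, 1)
  degen <- d <= 1e-12 * scale2
  var_s <- matrix(0, nrow(d), ncol(d))
  var_s[!degen] <- prefactor^2 * num[!degen] / d[!degen]
  ## phase-averaged closed form at unmodulated pixels: (2/3) mean variance
  vbar <- (v$v1 + v$v2 + v$v3) / 3
  var_s[degen] <- (2 / 3) * vbar[degen]
  var_s
}

#' Process one raw SIM triplet into photon-calibrated images
#'
#' The full per-depth pipeline: convert each phase to photons, form the
#' wide-field image (three-phase mean), demodulate the sectioned image and
#' divide by the modulation contrast `m` so its pixels are in-focus photon
#' counts, and attach the per-pixel noise maps ([noise_widefield()],
#' [noise_sectioned()]).
#'
#' The square root in the demodulation is nonlinear, so the naive estimator
#' `sectioned_raw / m` is biased upward under noise: the per-frame noise
#' variances inflate the sum of squared differences `D` by `2 (V1+V2+V3)`
#' in expectation.  With `debias = TRUE` (default) that expected inflation
#' is subtracted from `D` before the square root (clamping at zero), and a
#' clamped second-order Taylor factor `1 + Var(D) / (8 D^2)` corrects the
#' square root's concavity bias; the ensemble mean of the result tracks the
#' true in-focus photon count to well under 1% even under heavy out-of-focus
#' background (verified against the package's Monte-Carlo oracle).
#' `debias = FALSE` gives the plain estimator, which is exact on noiseless
#' data but biased on real (noisy) data.
#'
#' The final sectioned image is clamped at zero; intermediate negative
#' photon values are retained.
#'
#' @param t A [phase_triplet()] in DN (or already in photons).
#' @param calib A [calibration_profile()].
#' @param debias Apply shot-noise debiasing to the sectioned image
#'   (default `TRUE`; see Details).
#' @param prefactor Demodulation prefactor, see [sectioned_raw()].  Photon
#'   outputs are invariant to it provided contrast calibration used the
#'   same value.
#' @param depth_index,depth_um Depth bookkeeping attached to the result.
#' @return A `quant_result`: four M x N photon-unit images
#'   (`widefield_photons`, `sectioned_photons`, `widefield_noise`,
#'   `sectioned_noise`) plus depth metadata.
#' @export
process_triplet <- function(t, calib, debias = TRUE, prefactor = sqrt(2) / 3,
                            depth_index = 0L, depth_um = NA_real_) {
  stopifnot(inherits(t, "phase_triplet"), inherits(calib, "calibration_profile"))
  m <- calib$contrast$modulation_contrast
  if (!is.finite(m) || m <= 0 || m > 1) {
    ps_calibration_error(sprintf(
      "calibration profile carries an invalid modulation contrast (%.4g).", m))
  }
  tp <- triplet_to_photons(t, calib$gain)
  w <- widefield_raw(tp)
  d <- pairwise_sq_diff(tp)
  if (debias) {
    v <- frame_variances(tp, calib$gain)
    vsum <- v$v1 + v$v2 + v$v3
    dc <- pmax(d - 2 * vsum, 0)
    g1 <- 2 * tp$i1 - tp$i2 - tp$i3
    g2 <- 2 * tp$i2 - tp$i1 - tp$i3
    g3 <- 2 * tp$i3 - tp$i1 - tp$i2
    var_d <- 4 * (g1^2 * v$v1 + g2^2 * v$v2 + g3^2 * v$v3)
    ## second-order concavity correction for sqrt(); the Taylor series is
    ## only trustworthy while the correction is small, hence the 1.25 cap
    fac <- pmin(1 + var_d / (8 * pmax(dc, sqrt(var_d))^2), 1.25)
    s <- prefactor * sqrt(dc) * fac / m
  } else {
    s <- prefactor * sqrt(d) / m
  }
  s <- pmax(s, 0)
  new_quant_result(
    widefield_photons = w,
    sectioned_photons = s,
    widefield_noise = noise_widefield(tp, calib$gain),
    sectioned_noise = noise_sectioned(tp, m, calib$gain, prefactor = prefactor),
    depth_index = depth_index, depth_um = depth_um)
}

#' Process a 3D stack of concatenated SIM images
#'
#' Applies [process_triplet()] independently to each page of a depth stack
#' (no axial coupling); page order is depth order.
#'
#' @param stack A list of 3M x N matrices (one concatenated triplet per
#'   depth), e.g. the `pages` of [read_concatenated_tiff()].
#' @param calib A [calibration_profile()].
#' @param z_step_um Optional axial step in micrometres; when given, depth
#'   `i` (0-based) is annotated with `depth_um = i * z_step_um`.
#' @param order Phase-block ordering, see [split_concatenated()].
#' @inheritParams process_triplet
#' @return A list of `quant_result` objects with `depth_index` 0, 1, ...
#' @export
process_stack <- function(stack, calib, z_step_um = NULL, order = c(1, 2, 3),
                          debias = TRUE, prefactor = sqrt(2) / 3) {
  if (is.matrix(stack)) stack <- list(stack)
  if (!is.list(stack) || length(stack) == 0L) {
    ps_stack_error("`stack` must be a non-empty list of 3M x N matrices.")
  }
  dims <- dim(stack[[1]])
  for (i in seq_along(stack)) {
    if (!is.matrix(stack[[i]]) || !identical(dim(stack[[i]]), dims)) {
      ps_stack_error(sprintf(
        "stack page %d has inconsistent dimensions (expected %d x %d).",
        i, dims[1], dims[2]))
    }
  }
  purrr::map(seq_along(stack), function(i) {
    t <- split_concatenated(stack[[i]], order = order)
    process_triplet(t, calib, debias = debias, prefactor = prefactor,
                    depth_index = i - 1L,
                    depth_um = if (is.null(z_step_um)) NA_real_
                               else (i - 1) * z_step_um)
  })
}

#' Photon and noise histograms of a quantitative result
#'
#' Histograms of the four output images, the summary used to compare the
#' sectioned and wide-field images: background removal shows up as extra
#' counts in the lowest bins of the sectioned photon histogram, and the
#' demodulation noise amplification as a right-shifted sectioned noise
#' histogram.  The two photon images share one set of bin edges and the two
#' noise maps share another, so counts are directly comparable within each
#' pair; counts sum to M x N for every image.
#'
#' @param result A `quant_result`.
#' @param bin_width Bin width in photons (> 0).
#' @return A tibble with columns `image` (one of `widefield`, `sectioned`,
#'   `widefield_noise`, `sectioned_noise`), `bin_lo`, `bin_hi`, `bin_mid`
#'   and `count`.
#' @export
photon_noise_histograms <- function(result, bin_width) {
  stopifnot(inherits(result, "quant_result"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0) {
    ps_parameter_error("`bin_width` must be a single positive number of photons.")
  }
  imgs <- quant_image_list(result)
  groups <- list(photon = c("widefield", "sectioned"),
                 noise = c("widefield_noise", "sectioned_noise"))
  purrr::map_dfr(groups, function(members) {
    vals <- unlist(imgs[members], use.names = FALSE)
    lo <- floor(min(vals) / bin_width) * bin_width
    nbins <- max(1L, ceiling((max(vals) - lo) / bin_width + 1e-9))
    edges <- lo + bin_width * seq(0L, nbins)
    purrr::map_dfr(members, function(nm) {
      idx <- pmin(pmax(floor((imgs[[nm]] - lo) / bin_width), 0), nbins - 1L)
      counts <- tabulate(idx + 1L, nbins)
      tibble::tibble(image = nm,
                     bin_lo = edges[seq_len(nbins)],
                     bin_hi = edges[seq_len(nbins) + 1L],
                     bin_mid = (edges[seq_len(nbins)] + edges[seq_len(nbins) + 1L]) / 2,
                     count = counts)
    })
  })
}
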