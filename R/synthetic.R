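## Ground-truth simulator: camera model, scenes, rendered triplets,
## flat-field series, bead fields, 3D stacks, and the Monte-Carlo oracle.

#' Camera model for the simulator
#'
#' Linear camera: `DN = round(clip(g * Poisson(lambda) + N(0, sigma_r) +
#' offset, 0, 2^bits - 1))`.  Defaults describe a typical 12-bit
#' monochrome microscope CCD at moderate gain.
#'
#' @param gain_dn_per_photon Gain g in DN per photon (> 0).
#' @param offset_dn Dark level in DN.
#' @param read_noise_sigma_dn Gaussian read noise sigma in DN (>= 0).
#' @param bit_depth Digitization depth in bits (8--16).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(gain_dn_per_photon = 2, offset_dn = 100,
                         read_noise_sigma_dn = 2, bit_depth = 12L) {
  if (!is.numeric(gain_dn_per_photon) || gain_dn_per_photon <= 0) {
    ps_parameter_error("camera gain must be > 0 DN/photon.")
  }
  if (read_noise_sigma_dn < 0) {
    ps_parameter_error("read noise sigma must be >= 0 DN.")
  }
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 8L || bit_depth > 16L) {
    ps_parameter_error("`bit_depth` must be an integer between 8 and 16.")
  }
  structure(list(gain_dn_per_photon = gain_dn_per_photon,
                 offset_dn = offset_dn,
                 read_noise_sigma_dn = read_noise_sigma_dn,
                 bit_depth = bit_depth),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> g = %g DN/photon, offset %g DN, read sigma %g DN, %d-bit\n",
    x$gain_dn_per_photon, x$offset_dn, x$read_noise_sigma_dn, x$bit_depth))
  invisible(x)
}

full_scale <- function(camera) 2^camera$bit_depth - 1

#' Synthetic SIM scene with known ground truth
#'
#' A scene is described by the expected in-focus photon image `F` (per
#' frame), an unmodulated background photon image `B` standing in for all
#' out-of-focus light, the illumination modulation contrast `m`, and the
#' grid geometry.  The reconstruction algorithms only distinguish modulated
#' from unmodulated light, so injecting defocus directly as the
#' unmodulated `B` term is the minimal faithful model (no 3D PSF is
#' simulated).  The grid is a one-dimensional sinusoid along the column
#' (x) axis; orientation is irrelevant to the per-pixel algorithms.
#'
#' @param in_focus_photons Matrix (or single number with `dim`) of expected
#'   in-focus photons per frame, `F >= 0`.
#' @param background_photons Matrix or scalar of expected unmodulated
#'   photons per frame, `B >= 0`.
#' @param modulation_contrast Grid modulation contrast m in (0, 1].
#' @param grid_period_px Grid period in pixels (> 0).
#' @param grid_phase_rad Global grid phase offset in radians.
#' @param dim Image dimensions, used when `in_focus_photons` is scalar.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(in_focus_photons, background_photons = 0,
                            modulation_contrast = 0.5, grid_period_px = 12.8,
                            grid_phase_rad = 0, dim = NULL) {
  if (!is.matrix(in_focus_photons)) {
    if (is.null(dim)) {
      ps_parameter_error("scalar `in_focus_photons` needs explicit `dim`.")
    }
    in_focus_photons <- matrix(in_focus_photons, dim[1], dim[2])
  }
  if (!is.matrix(background_photons)) {
    background_photons <- matrix(background_photons,
                                 nrow(in_focus_photons), ncol(in_focus_photons))
  }
  if (!identical(dim(in_focus_photons), dim(background_photons))) {
    ps_parameter_error("`in_focus_photons` and `background_photons` must match in size.")
  }
  if (any(in_focus_photons < 0) || any(background_photons < 0)) {
    ps_parameter_error("photon densities must be non-negative.")
  }
  m <- modulation_contrast
  ## the simulator admits m = 0 (unmodulated illumination) even though a
  ## usable calibration requires m in (0, 1]
  if (!is.finite(m) || m < 0 || m > 1) {
    ps_parameter_error("`modulation_contrast` must lie in [0, 1].")
  }
  if (grid_period_px <= 0) {
    ps_parameter_error("`grid_period_px` must be > 0.")
  }
  structure(list(in_focus_photons = in_focus_photons,
                 background_photons = background_photons,
                 modulation_contrast = m,
                 grid_period_px = grid_period_px,
                 grid_phase_rad = grid_phase_rad),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px, m = %g, grid period %g px, mean F %.4g, mean B %.4g\n",
    nrow(x$in_focus_photons), ncol(x$in_focus_photons), x$modulation_contrast,
    x$grid_period_px, mean(x$in_focus_photons), mean(x$background_photons)))
  invisible(x)
}

## expected photon rate per phase i (1..3): F (1 + m cos(2 pi x / T + phi0 +
## 2 pi (i-1)/3)) + B, with x the column index
scene_lambda <- function(scene, phase_index) {
  f <- scene$in_focus_photons
  xph <- 2 * pi * (col(f) / scene$grid_period_px) + scene$grid_phase_rad +
    PHASE_STEP * (phase_index - 1)
  f * (1 + scene$modulation_contrast * cos(xph)) + scene$background_photons
}

#' Noiseless photon-unit phase triplet of a scene
#'
#' The expected photon rates of the three phases, as a photon-unit
#' [phase_triplet()]; handy for evaluating closed forms and for noise-map
#' predictions at the scene's expectation.
#'
#' @param scene A [synthetic_scene()].
#' @return A [phase_triplet()] in photon units.
#' @export
scene_expected_triplet <- function(scene) {
  phase_triplet(scene_lambda(scene, 1), scene_lambda(scene, 2),
                scene_lambda(scene, 3), pixel_unit = "photons")
}

expose_frame <- function(lambda, camera, noiseless = FALSE) {
  g <- camera$gain_dn_per_photon
  if (noiseless) {
    return(g * lambda + camera$offset_dn)
  }
  n <- length(lambda)
  dn <- g * rpois(n, lambda) +
    rnorm(n, 0, camera$read_noise_sigma_dn) + camera$offset_dn
  dn <- round(pmin(pmax(dn, 0), full_scale(camera)))
  matrix(dn, nrow(lambda), ncol(lambda))
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

## deterministic sub-seeds below 2^31 from one master seed; a single
## consumer keeps the master seed so e.g. a one-page stack renders
## identically to render_triplet() under the same seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  if (n == 1L) return(list(as.integer(seed)))
  as.list(withr::with_seed(as.integer(seed),
                           sample.int(2147483646L, n, replace = FALSE)))
}

#' Render a raw concatenated SIM triplet of a synthetic scene
#'
#' Applies the sinusoidal illumination forward model to the scene, passes
#' each phase through the camera model (Poisson shot noise, Gaussian read
#' noise, rounding and clipping), and concatenates the three phase images
#' row-wise in the raw acquisition layout.
#'
#' @param scene A [synthetic_scene()].
#' @param camera A [camera_model()].
#' @param noiseless If `TRUE`, bypass Poisson/Gaussian noise and
#'   rounding/clipping and return the exact expected DN.
#' @param seed Integer seed for reproducible noise; `NULL` uses the current
#'   RNG state.
#' @param order Phase-block ordering, see [split_concatenated()].
#' @return A 3M x N matrix in DN.  If any pixel's expected DN exceeds full
#'   scale a `photonsim_saturation_warning` is issued (the render still
#'   completes, with clipping).
#' @export
render_triplet <- function(scene, camera, noiseless = FALSE, seed = NULL,
                           order = c(1, 2, 3)) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(camera, "camera_model"))
  lams <- lapply(1:3, function(i) scene_lambda(scene, i))
  peak_dn <- camera$gain_dn_per_photon * max(vapply(lams, max, 0)) +
    camera$offset_dn
  if (!noiseless && peak_dn > full_scale(camera)) {
    ps_saturation_warning(sprintf(
      "expected peak signal %.0f DN exceeds full scale %d DN; highlights will clip.",
      peak_dn, full_scale(camera)))
  }
  frames <- with_optional_seed(seed, lapply(lams, expose_frame, camera = camera,
                                            noiseless = noiseless))
  t <- phase_triplet(frames[[1]], frames[[2]], frames[[3]], pixel_unit = "DN")
  concatenate_triplet(t, order = order)
}

#' Simulate a flat-field gain-calibration series
#'
#' Renders two independent uniform frames per illumination level under the
#' camera model.  Mirrors the acquisition protocol: the level ramp starts
#' at zero (the dark pair) and must have more than five steps.
#'
#' @param camera A [camera_model()].
#' @param photon_levels Ordered vector of expected photons per frame; the
#'   first entry must be 0 and at least 6 levels are required.
#' @param frame_dim Frame dimensions `c(rows, cols)`.
#' @param seed Integer seed (`NULL` for current RNG state).
#' @return A [flatfield_series()].
#' @export
render_flatfield_series <- function(camera, photon_levels,
                                    frame_dim = c(512L, 512L), seed = NULL) {
  stopifnot(inherits(camera, "camera_model"))
  if (length(photon_levels) < 6L) {
    ps_protocol_error(sprintf(
      "the calibration protocol requires more than five illumination levels; got %d.",
      length(photon_levels)))
  }
  if (photon_levels[1] != 0) {
    ps_protocol_error("the first illumination level must be dark (0 photons).")
  }
  if (is.unsorted(photon_levels)) {
    ps_protocol_error("`photon_levels` must be ordered from dark upward.")
  }
  lam0 <- matrix(0, frame_dim[1], frame_dim[2])
  levels <- with_optional_seed(seed, lapply(photon_levels, function(np) {
    lam <- lam0 + np
    list(frame_a = expose_frame(lam, camera),
         frame_b = expose_frame(lam, camera))
  }))
  flatfield_series(levels, bit_depth = camera$bit_depth,
                   integration_time_tag = "simulated")
}

#' Simulate a thin fluorescent bead field and render its SIM triplet
#'
#' Places `n_beads` Gaussian-profile beads at uniformly random positions,
#' sums their in-focus photon profiles, and renders the scene with
#' [render_triplet()].  The bead layer is thin by construction
#' (`background = 0`), matching the contrast-calibration protocol's
#' requirement of beads smaller than the sectioning thickness.
#'
#' @param n_beads Number of beads.
#' @param peak_photons Expected photons per frame at a bead's centre.
#' @param bead_sigma_px Gaussian radius of a bead in pixels; should be
#'   small relative to the grid period.
#' @param dim Frame dimensions `c(rows, cols)`.
#' @param modulation_contrast,grid_period_px,grid_phase_rad Scene
#'   parameters, see [synthetic_scene()].
#' @param background_photons Uniform unmodulated background (default 0;
#'   nonzero values emulate a thick sample and bias the contrast estimate
#'   downward).
#' @param camera A [camera_model()].
#' @param seed Integer seed (`NULL` for current RNG state).
#' @param noiseless Bypass camera noise, see [render_triplet()].
#' @return A 3M x N matrix in DN, with the generating [synthetic_scene()]
#'   attached as attribute `"scene"`.
#' @export
render_bead_field <- function(n_beads = 200L, peak_photons = 2000,
                              bead_sigma_px = 1.5, dim = c(256L, 256L),
                              modulation_contrast = 0.6, grid_period_px = 12.8,
                              grid_phase_rad = 0, background_photons = 0,
                              camera = camera_model(bit_depth = 16L),
                              seed = NULL, noiseless = FALSE) {
  seeds <- derive_seeds(seed, 2L)
  f <- with_optional_seed(seeds[[1]], {
    f <- matrix(0, dim[1], dim[2])
    if (n_beads > 0) {
      margin <- ceiling(4 * bead_sigma_px)
      ys <- stats::runif(n_beads, 1 + margin, dim[1] - margin)
      xs <- stats::runif(n_beads, 1 + margin, dim[2] - margin)
      half <- ceiling(4 * bead_sigma_px)
      for (b in seq_len(n_beads)) {
        r0 <- max(1L, floor(ys[b]) - half); r1 <- min(dim[1], floor(ys[b]) + half)
        c0 <- max(1L, floor(xs[b]) - half); c1 <- min(dim[2], floor(xs[b]) + half)
        rr <- r0:r1; cc <- c0:c1
        prof <- exp(-((rr - ys[b])^2 %o% rep(1, length(cc)) +
                        rep(1, length(rr)) %o% (cc - xs[b])^2) /
                      (2 * bead_sigma_px^2))
        f[rr, cc] <- f[rr, cc] + peak_photons * prof
      }
    }
    f
  })
  scene <- synthetic_scene(f, background_photons = background_photons,
                           modulation_contrast = modulation_contrast,
                           grid_period_px = grid_period_px,
                           grid_phase_rad = grid_phase_rad)
  out <- render_triplet(scene, camera, noiseless = noiseless, seed = seeds[[2]])
  attr(out, "scene") <- scene
  out
}

#' Simulate a 3D SIM acquisition
#'
#' One independent [render_triplet()] per depth, each with a sub-seed
#' derived deterministically from the master seed.
#'
#' @param scene_per_depth List of [synthetic_scene()]s, shallowest first.
#' @param camera A [camera_model()].
#' @param seed Master seed (`NULL` for current RNG state).
#' @param noiseless Bypass camera noise.
#' @return A list of 3M x N DN matrices, one page per depth.
#' @export
render_stack <- function(scene_per_depth, camera, seed = NULL,
                         noiseless = FALSE) {
  if (!is.list(scene_per_depth) || length(scene_per_depth) == 0L) {
    ps_stack_error("`scene_per_depth` must be a non-empty list of scenes.")
  }
  dims <- dim(scene_per_depth[[1]]$in_focus_photons)
  for (s in scene_per_depth) {
    if (!identical(dim(s$in_focus_photons), dims)) {
      ps_stack_error("all depth scenes must share the same dimensions.")
    }
  }
  seeds <- derive_seeds(seed, length(scene_per_depth))
  purrr::map(seq_along(scene_per_depth), function(i) {
    render_triplet(scene_per_depth[[i]], camera, noiseless = noiseless,
                   seed = seeds[[i]])
  })
}

#' Monte-Carlo ensemble oracle for the reconstruction pipeline
#'
#' Renders `n_reps` independent noisy realizations of a scene, reconstructs
#' each with [process_triplet()], and returns the per-pixel ensemble mean
#' and standard deviation of all four output images.  This empirical
#' distribution -- not any closed form -- is the package's ground truth for
#' validating the predicted noise maps and the unbiasedness of the photon
#' estimates.
#'
#' @param scene A [synthetic_scene()].
#' @param camera A [camera_model()].
#' @param calib A [calibration_profile()] used for reconstruction.
#' @param n_reps Ensemble size; at least 100 is recommended for stable
#'   standard deviations (a warning is issued below that).
#' @param seed Master seed (`NULL` for current RNG state).
#' @param debias Passed to [process_triplet()].
#' @param noiseless Render without camera noise (sanity check: the
#'   ensemble standard deviation is then exactly zero).
#' @return A list with elements `mean` and `sd`, each a named list of four
#'   M x N matrices (`widefield`, `sectioned`, `widefield_noise`,
#'   `sectioned_noise`), plus `n_reps`.
#' @export
monte_carlo_oracle <- function(scene, camera, calib, n_reps = 500L,
                               seed = NULL, debias = TRUE, noiseless = FALSE) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) ps_parameter_error("`n_reps` must be at least 2.")
  if (n_reps < 100L) {
    rlang::warn("fewer than 100 Monte-Carlo repetitions give unstable ensemble statistics.",
                class = "photonsim_warning")
  }
  seeds <- derive_seeds(seed, n_reps)
  nms <- quant_images()
  d <- dim(scene$in_focus_photons)
  s1 <- s2 <- setNames(replicate(4, matrix(0, d[1], d[2]), simplify = FALSE), nms)
  ref <- NULL   # shifted accumulation avoids catastrophic cancellation
  for (r in seq_len(n_reps)) {
    raw <- render_triplet(scene, camera, noiseless = noiseless,
                          seed = seeds[[r]])
    res <- process_triplet(split_concatenated(raw), calib, debias = debias)
    imgs <- quant_image_list(res)
    if (is.null(ref)) ref <- imgs
    for (nm in nms) {
      dx <- imgs[[nm]] - ref[[nm]]
      s1[[nm]] <- s1[[nm]] + dx
      s2[[nm]] <- s2[[nm]] + dx^2
    }
  }
  mean_ <- setNames(lapply(nms, function(nm) ref[[nm]] + s1[[nm]] / n_reps), nms)
  sd_ <- setNames(lapply(nms, function(nm) {
    v <- (s2[[nm]] - s1[[nm]]^2 / n_reps) / (n_reps - 1)
    sqrt(pmax(v, 0))
  }), nms)
  list(mean = mean_, sd = sd_, n_reps = n_reps)
}
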