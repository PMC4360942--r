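make_series <- function(level_values, dim = c(8L, 8L), bit_depth = 12L,
                        pattern = 0) {
  levels <- lapply(level_values, function(v) {
    list(frame_a = matrix(v, dim[1], dim[2]) + pattern,
         frame_b = matrix(v, dim[1], dim[2]) + pattern)
  })
  flatfield_series(levels, bit_depth = bit_depth)
}

test_that("mean_variance_points subtracts dark and uses pair differencing", {
  ## identical constant frames: zero difference variance, mean above dark
  ser <- make_series(c(100, 150, 200, 300, 500, 900))
  pts <- mean_variance_points(ser)
  expect_equal(attr(pts, "offset_dn"), 100)
  expect_equal(pts$mean_dn[2], 50)
  expect_equal(pts$variance_dn2, rep(0, 6))
})

test_that("mean-variance points are immune to static fixed-pattern structure", {
  cam <- camera_model(2, 100, 2, 12)
  lv <- seq(0, 1500, length.out = 7)
  ser <- render_flatfield_series(cam, lv, frame_dim = c(64L, 64L), seed = 3)
  ## same photon realizations, plus a static +/-5 DN per-pixel pattern added
  ## to both frames of every level
  pat <- matrix(rep_len(c(-5, 5), 64 * 64), 64, 64)
  ser_pat <- flatfield_series(lapply(ser$levels, function(l) {
    list(frame_a = l$frame_a + pat, frame_b = l$frame_b + pat)
  }), bit_depth = 12L)
  p0 <- mean_variance_points(ser)
  p1 <- mean_variance_points(ser_pat)
  expect_equal(p1$variance_dn2, p0$variance_dn2, tolerance = 1e-12)
  expect_equal(p1$mean_dn, p0$mean_dn, tolerance = 1e-12)
})

test_that("fit_gain recovers an exact photon-transfer line exactly", {
  means <- c(0, 100, 200, 400, 800, 1600)
  pts <- tibble::tibble(mean_dn = means, variance_dn2 = 0.5 * means + 3)
  for (w in c("ptc", "none")) {
    fit <- fit_gain(pts, bit_depth = 12, weights = w)
    expect_equal(fit$gain_dn_per_photon, 0.5, tolerance = 1e-10)
    expect_equal(fit$read_noise_var_dn2, 3, tolerance = 1e-8)
  }
})

test_that("fit_gain enforces the level-count protocol and saturation guard", {
  means <- c(0, 100, 200, 400, 800)
  pts5 <- tibble::tibble(mean_dn = means, variance_dn2 = 2 * means + 4)
  expect_ps_error(fit_gain(pts5, bit_depth = 12),
                  "photonsim_insufficient_levels_error")
  expect_ps_error(make_series(c(100, 200, 300, 400, 500)),
                  "photonsim_insufficient_levels_error")

  ## two saturated levels excluded from the fit but reported
  means <- c(0, 200, 400, 800, 1600, 3200, 3900, 4050)
  pts <- tibble::tibble(mean_dn = means, variance_dn2 = 2 * means + 4)
  pts$variance_dn2[7:8] <- c(10, 5)    # clipping collapses the variance
  fit <- fit_gain(pts, bit_depth = 12, saturation_cut = 0.9)
  expect_equal(fit$levels_excluded, 2L)
  expect_equal(fit$gain_dn_per_photon, 2, tolerance = 1e-8)

  ## too few points once the saturated ones are gone
  expect_ps_error(fit_gain(pts[c(1:3, 7:8), ][c(1, 2, 3, 4, 5, 5), ],
                           bit_depth = 12),
                  "photonsim_insufficient_levels_error")

  ## decreasing variance-vs-mean has no physical gain
  bad <- tibble::tibble(mean_dn = c(0, 100, 200, 400, 800, 1600),
                        variance_dn2 = c(600, 500, 400, 300, 200, 100))
  expect_ps_error(fit_gain(bad, bit_depth = 12), "photonsim_calibration_error")
})

test_that("simulated flat-field series recover gain and read noise", {
  for (g in c(0.5, 5)) {
    cam <- camera_model(g, 100, 2, 12)
    lv <- seq(0, 0.8 * (2^12 - 1 - 100) / g, length.out = 8)
    ser <- render_flatfield_series(cam, lv, frame_dim = c(256L, 256L),
                                   seed = 20 + g)
    fit <- calibrate_gain(ser)
    expect_lt(abs(fit$gain_dn_per_photon - g) / g, 0.02)
    expect_lt(abs(fit$read_noise_var_dn2 - 4) / 4, 0.15)
    expect_lt(abs(fit$offset_dn - 100), 0.1)
  }
})

test_that("photon counting from mean and sigma follows the shot-noise relation", {
  expect_equal(photon_count_uniform(400, 20), 400)
  expect_ps_error(photon_count_uniform(400, 0), "photonsim_degenerate_input_error")

  ## Monte-Carlo: mean^2/variance is gain-free and unbiased
  cam <- camera_model(2, 100, 2, 16)
  frame <- withr::with_seed(31, photonsim:::expose_frame(matrix(1000, 320, 320), cam))
  est <- photon_count_uniform(mean(frame) - 100, sd(frame))
  expect_lt(abs(est - 1000) / 1000, 0.02)
})

test_that("modulation contrast is exact on a noiseless thin fluorescent plane", {
  scene <- synthetic_scene(500, 0, modulation_contrast = 0.6, dim = c(24L, 48L))
  raw <- render_triplet(scene, photon_camera(), noiseless = TRUE)
  t <- split_concatenated(raw)
  fit <- estimate_modulation_contrast(t, truth_gain(photon_camera()))
  expect_equal(fit$modulation_contrast, 0.6, tolerance = 1e-9)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("modulation contrast recovers the simulator truth from a noisy bead field", {
  cam <- camera_model(2, 100, 2, 16)
  raw <- render_bead_field(n_beads = 80L, peak_photons = 2000,
                           dim = c(128L, 128L), modulation_contrast = 0.6,
                           camera = cam, seed = 91)
  fit <- estimate_modulation_contrast(split_concatenated(raw), truth_gain(cam))
  expect_lt(abs(fit$modulation_contrast - 0.6) / 0.6, 0.03)
})

test_that("degenerate contrast inputs raise the documented errors", {
  cam <- camera_model(2, 100, 2, 16)
  dark <- withr::with_seed(5, {
    mk <- function() matrix(round(100 + rnorm(32 * 32, 0, 2)), 32, 32)
    phase_triplet(mk(), mk(), mk())
  })
  expect_ps_error(estimate_modulation_contrast(dark, truth_gain(cam)),
                  "photonsim_empty_selection_error")

  ## modulation amplitude above the mean: ratio > 1 is unphysical for
  ## fluorescence under a grid of contrast <= 1
  over <- sinusoid_triplet(A = 1100, B = 1500, phi = 0.4, dim = c(16L, 16L))
  expect_ps_error(
    estimate_modulation_contrast(over, truth_gain(photon_camera())),
    "photonsim_implausible_contrast_error")
})

test_that("out-of-focus background biases the contrast down, monotonically", {
  cam <- photon_camera()
  m_hat <- vapply(c(0, 500, 2000), function(bg) {
    raw <- render_bead_field(n_beads = 60L, peak_photons = 3000,
                             dim = c(96L, 96L), modulation_contrast = 0.6,
                             background_photons = bg, camera = cam,
                             seed = 17, noiseless = TRUE)
    estimate_modulation_contrast(split_concatenated(raw),
                                 truth_gain(cam))$modulation_contrast
  }, numeric(1))
  expect_equal(m_hat[1], 0.6, tolerance = 1e-6)
  expect_true(all(diff(m_hat) < 0))
})
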