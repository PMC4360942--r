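test_that("to_photons applies (DN - offset)/g and keeps sub-dark values", {
  g <- photonsim:::new_gain_fit(2, 100, 4)
  expect_equal(to_photons(matrix(300, 1, 1), g)[1, 1], 100)
  expect_equal(to_photons(matrix(100, 1, 1), g)[1, 1], 0)
  expect_equal(to_photons(matrix(99, 1, 1), g)[1, 1], -0.5)
})

test_that("noiseless reconstruction hits the closed form exactly", {
  cam <- photon_camera()
  calib <- truth_profile(cam, 0.5)
  scene <- synthetic_scene(200, 400, modulation_contrast = 0.5,
                           dim = c(12L, 36L))
  raw <- render_triplet(scene, cam, noiseless = TRUE)
  res <- process_triplet(split_concatenated(raw), calib, debias = FALSE)
  expect_equal(res$widefield_photons, matrix(600, 12, 36), tolerance = 1e-12)
  expect_equal(res$sectioned_photons, matrix(200, 12, 36), tolerance = 1e-9)

  ## pure out-of-focus light has no modulated component
  flat <- synthetic_scene(0, 400, modulation_contrast = 0.5, dim = c(8L, 8L))
  res0 <- process_triplet(
    split_concatenated(render_triplet(flat, cam, noiseless = TRUE)),
    calib, debias = FALSE)
  expect_equal(res0$sectioned_photons, matrix(0, 8, 8), tolerance = 1e-9)
  expect_equal(res0$widefield_photons, matrix(400, 8, 8), tolerance = 1e-12)
})

test_that("photon outputs are invariant to the demodulation prefactor convention", {
  ## scaling the square-law prefactor by c scales both the demodulated
  ## amplitude and the calibrated contrast by c, so photon outputs cancel
  cam <- photon_camera()
  plane <- synthetic_scene(500, 0, modulation_contrast = 0.3, dim = c(16L, 32L))
  bead_raw <- render_triplet(plane, cam, noiseless = TRUE)
  scene <- synthetic_scene(200, 300, modulation_contrast = 0.3, dim = c(16L, 32L))
  raw <- render_triplet(scene, cam, seed = 77)
  t <- split_concatenated(raw)

  run <- function(pref) {
    m <- estimate_modulation_contrast(split_concatenated(bead_raw),
                                      truth_gain(cam),
                                      prefactor = pref)$modulation_contrast
    profile <- calibration_profile(truth_gain(cam), m)
    process_triplet(t, profile, prefactor = pref)$sectioned_photons
  }
  ref <- run(sqrt(2) / 3)
  alt <- run(2 * sqrt(2) / 3)
  expect_equal(alt, ref, tolerance = 1e-9)
})

test_that("invalid modulation contrast is rejected before processing", {
  cam <- photon_camera()
  calib <- truth_profile(cam, 0.5)
  calib$contrast$modulation_contrast <- -0.2
  t <- sinusoid_triplet(100, 10, 0, dim = c(4L, 4L))
  expect_ps_error(process_triplet(t, calib), "photonsim_calibration_error")
  expect_ps_error(noise_sectioned(sinusoid_triplet(100, 10, 0, unit = "photons"),
                                  -1, truth_gain(cam)),
                  "photonsim_calibration_error")
})

test_that("wide-field noise map follows the mean-of-three propagation", {
  g0 <- photonsim:::new_gain_fit(1, 0, 0)
  t <- phase_triplet(matrix(300, 2, 2), matrix(300, 2, 2), matrix(300, 2, 2),
                     pixel_unit = "photons")
  expect_equal(noise_widefield(t, g0), matrix(10, 2, 2))
  dark <- phase_triplet(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                        pixel_unit = "photons")
  expect_equal(noise_widefield(dark, g0), matrix(0, 2, 2))
  ## read noise adds 3 sigma_r^2 / (9 g^2) in photon units
  g1 <- photonsim:::new_gain_fit(2, 100, 36)
  expect_equal(noise_widefield(dark, g1), matrix(sqrt(3 * 9 / 9), 2, 2))
})

test_that("sectioned noise map matches the phase-averaged closed form", {
  gf <- photonsim:::new_gain_fit(1, 0, 0)
  ## F = 200, B = 400, m = 0.5: sigma averaged over grid phase is
  ## sqrt((2/3)(F + B))/m = 40 photons
  scene <- synthetic_scene(200, 400, modulation_contrast = 0.5,
                           grid_period_px = 32, dim = c(2L, 32L))
  sig <- noise_sectioned(scene_expected_triplet(scene), 0.5, gf)
  expect_equal(mean(sig), 40, tolerance = 0.005)

  ## unmodulated pixel: the singular delta-method limit is replaced by the
  ## phase-averaged form sqrt((2/3) * mean variance)/m
  cst <- phase_triplet(matrix(600, 2, 2), matrix(600, 2, 2), matrix(600, 2, 2),
                       pixel_unit = "photons")
  expect_equal(noise_sectioned(cst, 0.5, gf), matrix(40, 2, 2))
  expect_true(all(is.finite(noise_sectioned(cst, 0.5, gf))))
})

test_that("sectioned noise grows with background and shrinks with contrast", {
  gf <- photonsim:::new_gain_fit(1, 0, 0)
  sig_at <- function(B, m) {
    scene <- synthetic_scene(200, B, modulation_contrast = m, dim = c(4L, 24L))
    noise_sectioned(scene_expected_triplet(scene), m, gf)
  }
  s0 <- sig_at(0, 0.5); s200 <- sig_at(200, 0.5); s800 <- sig_at(800, 0.5)
  expect_true(all(s200 > s0) && all(s800 > s200))

  m_low <- sig_at(400, 0.3); m_mid <- sig_at(400, 0.5); m_high <- sig_at(400, 0.8)
  expect_true(all(m_mid < m_low) && all(m_high < m_mid))

  ## demodulation amplifies noise: sectioned >= widefield for any m <= 1
  scene <- synthetic_scene(200, 400, modulation_contrast = 1, dim = c(4L, 24L))
  tp <- scene_expected_triplet(scene)
  expect_true(all(noise_sectioned(tp, 1, gf) >= noise_widefield(tp, gf) - 1e-9))
})

test_that("process_stack handles depths independently with depth bookkeeping", {
  cam <- photon_camera()
  calib <- truth_profile(cam, 0.5)
  scene <- synthetic_scene(200, 100, modulation_contrast = 0.5, dim = c(6L, 9L))
  page <- render_triplet(scene, cam, noiseless = TRUE)
  res <- process_stack(rep(list(page), 5), calib, z_step_um = 2)
  expect_length(res, 5)
  expect_equal(vapply(res, `[[`, 0L, "depth_index"), 0:4)
  expect_equal(vapply(res, `[[`, 0, "depth_um"), c(0, 2, 4, 6, 8))
  for (r in res[-1]) {
    expect_equal(r$sectioned_photons, res[[1]]$sectioned_photons)
  }
  expect_ps_error(process_stack(list(), calib), "photonsim_stack_error")
  expect_ps_error(process_stack(list(page, page[1:6, ]), calib),
                  "photonsim_stack_error")
})

test_that("every quantitative result carries four same-size non-negative-noise images", {
  cam <- camera_model(2, 100, 2, 16)
  calib <- truth_profile(cam, 0.5)
  scene <- synthetic_scene(200, 400, modulation_contrast = 0.5, dim = c(10L, 14L))
  res <- process_triplet(
    split_concatenated(render_triplet(scene, cam, seed = 4)), calib)
  imgs <- photonsim:::quant_image_list(res)
  expect_named(imgs, c("widefield", "sectioned", "widefield_noise",
                       "sectioned_noise"))
  for (img in imgs) expect_equal(dim(img), c(10L, 14L))
  expect_true(all(res$widefield_noise >= 0))
  expect_true(all(res$sectioned_noise >= 0))
  expect_true(all(res$sectioned_photons >= 0))
})

test_that("photon histograms bin all pixels and flag degenerate bin widths", {
  mk <- function(v) matrix(v, 4, 4)
  res <- photonsim:::new_quant_result(mk(10), mk(10), mk(2), mk(3))
  h <- photon_noise_histograms(res, bin_width = 5)
  expect_s3_class(h, "tbl_df")
  sums <- tapply(h$count, h$image, sum)
  expect_true(all(sums == 16))
  expect_equal(sum(h$count[h$image == "widefield"] > 0), 1L)

  expect_ps_error(photon_noise_histograms(res, 0), "photonsim_parameter_error")
  expect_ps_error(photon_noise_histograms(res, -1), "photonsim_parameter_error")
})

test_that("tidiers return well-formed tibbles", {
  cam <- photon_camera()
  calib <- truth_profile(cam, 0.5)
  scene <- synthetic_scene(100, 50, modulation_contrast = 0.5, dim = c(5L, 6L))
  res <- process_triplet(
    split_concatenated(render_triplet(scene, cam, noiseless = TRUE)), calib)
  td <- tidy(res)
  expect_equal(nrow(td), 5 * 6 * 4)
  expect_setequal(unique(td$image), photonsim:::quant_images())
  gl <- glance(res)
  expect_equal(gl$widefield_mean, mean(res$widefield_photons))
})
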