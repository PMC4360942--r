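test_that("rendering is deterministic under a fixed seed", {
  cam <- camera_model(2, 100, 2, 12)
  scene <- synthetic_scene(300, 100, modulation_contrast = 0.5, dim = c(16L, 16L))
  a <- render_triplet(scene, cam, seed = 123)
  b <- render_triplet(scene, cam, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, render_triplet(scene, cam, seed = 124)))

  beads1 <- render_bead_field(n_beads = 20L, dim = c(64L, 64L), seed = 9,
                              camera = cam, peak_photons = 500)
  beads2 <- render_bead_field(n_beads = 20L, dim = c(64L, 64L), seed = 9,
                              camera = cam, peak_photons = 500)
  expect_identical(beads1, beads2)

  st1 <- render_stack(rep(list(scene), 3), cam, seed = 55)
  st2 <- render_stack(rep(list(scene), 3), cam, seed = 55)
  expect_identical(st1, st2)
  ## depths are independent realizations, not copies
  expect_false(identical(st1[[1]], st1[[2]]))
})

test_that("unmodulated illumination renders three identical phase blocks", {
  scene <- synthetic_scene(300, 100, modulation_contrast = 0, dim = c(8L, 8L))
  raw <- render_triplet(scene, photon_camera(), noiseless = TRUE)
  t <- split_concatenated(raw)
  expect_equal(t$i1, t$i2)
  expect_equal(t$i2, t$i3)
})

test_that("camera model reproduces its stated first two moments", {
  cam <- camera_model(2, 100, 2, 16)
  n <- 400L
  frame <- withr::with_seed(71,
    photonsim:::expose_frame(matrix(n, 350L, 300L), cam))
  expect_lt(abs(mean(frame) - (2 * n + 100)) / (2 * n + 100), 0.005)
  expect_lt(abs(var(as.vector(frame)) - (4 * n + 4)) / (4 * n + 4), 0.02)
})

test_that("energy bookkeeping: noiseless reconstruction returns F + B and F", {
  cam <- camera_model(2.5, 50, 0, 16)
  calib <- truth_profile(cam, 0.4)
  withr::with_seed(8, {
    f <- matrix(runif(64, 0, 300), 8, 8)
    b <- matrix(runif(64, 0, 500), 8, 8)
  })
  scene <- synthetic_scene(f, b, modulation_contrast = 0.4, dim = c(8L, 8L))
  raw <- render_triplet(scene, cam, noiseless = TRUE)
  res <- process_triplet(split_concatenated(raw), calib, debias = FALSE)
  expect_equal(res$widefield_photons, f + b, tolerance = 1e-9)
  expect_equal(res$sectioned_photons, f, tolerance = 1e-7)
})

test_that("flat-field simulation enforces the acquisition protocol", {
  cam <- camera_model(2, 100, 2, 12)
  expect_ps_error(render_flatfield_series(cam, c(0, 100, 200, 400, 800)),
                  "photonsim_protocol_error")
  expect_ps_error(
    render_flatfield_series(cam, c(10, 100, 200, 400, 800, 1600)),
    "photonsim_protocol_error")
  ser <- render_flatfield_series(cam, c(0, 100, 200, 400, 800, 1500),
                                 frame_dim = c(128L, 128L), seed = 2)
  ## dark level pins the offset to within a few standard errors
  expect_lt(abs(mean(ser$levels[[1]]$frame_a) - 100), 3 * 2 / 128)
})

test_that("expected saturation triggers a warning, not an error", {
  cam <- camera_model(2, 100, 2, 8)    # full scale 255
  scene <- synthetic_scene(200, 0, modulation_contrast = 0.5, dim = c(4L, 4L))
  expect_warning(render_triplet(scene, cam, seed = 1),
                 class = "photonsim_saturation_warning")
})

test_that("a one-page stack renders identically to a single triplet", {
  cam <- camera_model(2, 100, 2, 12)
  scene <- synthetic_scene(300, 100, modulation_contrast = 0.5, dim = c(8L, 8L))
  expect_identical(render_stack(list(scene), cam, seed = 99)[[1]],
                   render_triplet(scene, cam, seed = 99))
  big <- synthetic_scene(300, 100, modulation_contrast = 0.5, dim = c(10L, 8L))
  expect_ps_error(render_stack(list(scene, big), cam, seed = 1),
                  "photonsim_stack_error")
})

test_that("the Monte-Carlo oracle is exact in the noiseless limit and converges", {
  cam <- camera_model(2, 100, 2, 16)
  calib <- truth_profile(cam, 0.5)
  scene <- synthetic_scene(200, 400, modulation_contrast = 0.5, dim = c(6L, 12L))
  quiet <- monte_carlo_oracle(scene, cam, calib, n_reps = 120, seed = 3,
                              noiseless = TRUE)
  for (sd_img in quiet$sd) expect_equal(sd_img, matrix(0, 6, 12))

  orc <- monte_carlo_oracle(scene, cam, calib, n_reps = 400, seed = 3)
  ## ensemble mean of the wide-field image within 4 standard errors of F+B
  se <- orc$sd$widefield / sqrt(orc$n_reps)
  expect_true(mean(abs(orc$mean$widefield - 600) <= 4 * se) > 0.95)
  expect_warning(monte_carlo_oracle(scene, cam, calib, n_reps = 50, seed = 1),
                 class = "photonsim_warning")
})
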