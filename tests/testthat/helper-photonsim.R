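## shared fixtures, built in code

## triplet whose phases sample A + B cos(phi + 2 pi (i-1)/3) at one value of
## phi, replicated over a small image
sinusoid_triplet <- function(A, B, phi, dim = c(4L, 4L), unit = "DN") {
  mk <- function(k) matrix(A + B * cos(phi + 2 * pi * k / 3), dim[1], dim[2])
  phase_triplet(mk(0), mk(1), mk(2), pixel_unit = unit)
}

## gain_fit carrying known true camera parameters (bypasses fitting)
truth_gain <- function(camera) {
  photonsim:::new_gain_fit(
    gain_dn_per_photon = camera$gain_dn_per_photon,
    offset_dn = camera$offset_dn,
    read_noise_var_dn2 = camera$read_noise_sigma_dn^2,
    bit_depth = camera$bit_depth)
}

## calibration profile built from simulator ground truth
truth_profile <- function(camera, m) {
  calibration_profile(truth_gain(camera), m)
}

## photon-domain camera: g = 1, no offset, no read noise
photon_camera <- function(bit_depth = 16L) {
  camera_model(gain_dn_per_photon = 1, offset_dn = 0,
               read_noise_sigma_dn = 0, bit_depth = bit_depth)
}

expect_ps_error <- function(expr, class) {
  expect_error(expr, class = class)
}
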