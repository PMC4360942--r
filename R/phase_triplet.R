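## Core data model: three co-registered images at illumination phases
## 0, 2pi/3, 4pi/3, and the pure (unit-free) square-law demodulation.

PHASE_STEP <- 2 * pi / 3

#' Three-phase SIM image triplet
#'
#' Bundles the three co-registered images acquired under sinusoidal
#' illumination shifted by 0, 2pi/3 and 4pi/3 -- the minimal set for
#' square-law optical-sectioning demodulation.  The 2pi/3 phase step is the
#' only supported geometry.
#'
#' @param i1,i2,i3 Numeric matrices of identical dimensions (M rows, N
#'   columns).  Values are grey levels (DN) straight off the camera, or
#'   photons after calibration; sub-dark fluctuations may make
#'   photon-unit values slightly negative, so negativity is not rejected.
#' @param pixel_unit `"DN"` (digital number, uncalibrated) or `"photons"`.
#'
#' @return An object of class `phase_triplet`: a list with elements `i1`,
#'   `i2`, `i3`, `phase_step` (always 2pi/3) and `pixel_unit`.
#' @seealso [split_concatenated()] to build one from a row-concatenated
#'   3M x N image; [sectioned_raw()] and [widefield_raw()] for demodulation.
#' @export
#' @examples
#' t <- phase_triplet(matrix(3, 2, 2), matrix(2, 2, 2), matrix(1, 2, 2))
#' widefield_raw(t)   # 2 everywhere
phase_triplet <- function(i1, i2, i3, pixel_unit = c("DN", "photons")) {
  pixel_unit <- match.arg(pixel_unit)
  imgs <- list(i1 = i1, i2 = i2, i3 = i3)
  for (nm in names(imgs)) {
    x <- imgs[[nm]]
    if (!is.matrix(x) || !is.numeric(x)) {
      ps_layout_error(sprintf("`%s` must be a numeric matrix.", nm))
    }
    if (nrow(x) < 1L || ncol(x) < 1L) {
      ps_layout_error(sprintf("`%s` must have at least one row and column.", nm))
    }
    if (anyNA(x)) {
      ps_layout_error(sprintf("`%s` contains missing values.", nm))
    }
  }
  d1 <- dim(i1)
  if (!identical(d1, dim(i2)) || !identical(d1, dim(i3))) {
    ps_layout_error(sprintf(
      "all three phase images must share dimensions; got %dx%d, %dx%d, %dx%d.",
      nrow(i1), ncol(i1), nrow(i2), ncol(i2), nrow(i3), ncol(i3)))
  }
  structure(
    list(i1 = i1 * 1.0, i2 = i2 * 1.0, i3 = i3 * 1.0,
         phase_step = PHASE_STEP, pixel_unit = pixel_unit),
    class = "phase_triplet")
}

#' @export
print.phase_triplet <- function(x, ...) {
  cat(sprintf("<phase_triplet> %d x %d pixels, phase step 2pi/3, unit: %s\n",
              nrow(x$i1), ncol(x$i1), x$pixel_unit))
  invisible(x)
}

#' @export
dim.phase_triplet <- function(x) dim(x$i1)

normalize_phase_order <- function(order) {
  if (is.character(order) && length(order) == 1L) {
    order <- as.integer(strsplit(order, "")[[1]])
  }
  order <- as.integer(order)
  if (length(order) != 3L || anyNA(order) || !setequal(order, 1:3)) {
    ps_usage_error(
      "`order` must be a permutation of 1, 2, 3 (e.g. c(1, 2, 3) or \"321\").")
  }
  order
}

#' Split a row-concatenated 3M x N image into a phase triplet
#'
#' Raw optical-sectioning SIM data arrive as a single image in which the
#' three phase images are stacked on top of each other: 3M rows by N
#' columns.  This splits the row-thirds back into a [phase_triplet()].
#'
#' @param stacked Numeric matrix with row count divisible by 3.
#' @param order Which phase each row block (top to bottom) holds.  The
#'   default `c(1, 2, 3)` means the top third is phase 1 (grid phase 0),
#'   the middle third phase 2 (2pi/3), the bottom third phase 3 (4pi/3).
#'   `"321"` or `c(3, 2, 1)` reverses the assignment.  Acquisition software
#'   rarely documents the order; all demodulation results are invariant to
#'   it, so it matters only for metadata fidelity.
#' @param pixel_unit Unit of the pixel values, as in [phase_triplet()].
#'
#' @return A [phase_triplet()].  Pixel values are never altered.
#' @export
#' @examples
#' x <- rbind(matrix(1, 2, 4), matrix(2, 2, 4), matrix(3, 2, 4))
#' split_concatenated(x)$i2[1, 1]           # 2
#' split_concatenated(x, "321")$i1[1, 1]    # 3
split_concatenated <- function(stacked, order = c(1, 2, 3),
                               pixel_unit = c("DN", "photons")) {
  pixel_unit <- match.arg(pixel_unit)
  if (!is.matrix(stacked) || !is.numeric(stacked)) {
    ps_layout_error("`stacked` must be a numeric matrix.")
  }
  order <- normalize_phase_order(order)
  nr <- nrow(stacked)
  if (nr %% 3L != 0L) {
    ps_layout_error(sprintf(
      "concatenated layout requires a row count divisible by 3; got %d x %d.",
      nr, ncol(stacked)))
  }
  m <- nr %/% 3L
  blocks <- lapply(0:2, function(k) stacked[(k * m + 1L):((k + 1L) * m), , drop = FALSE])
  phases <- vector("list", 3L)
  for (k in 1:3) phases[[order[k]]] <- blocks[[k]]
  phase_triplet(phases[[1L]], phases[[2L]], phases[[3L]], pixel_unit = pixel_unit)
}

#' Re-concatenate a phase triplet into a 3M x N image
#'
#' Inverse of [split_concatenated()]; used when writing simulated data in
#' the raw acquisition layout.
#'
#' @param t A [phase_triplet()].
#' @param order Row-block ordering, as in [split_concatenated()].
#' @return A 3M x N numeric matrix.
#' @export
concatenate_triplet <- function(t, order = c(1, 2, 3)) {
  stopifnot(inherits(t, "phase_triplet"))
  order <- normalize_phase_order(order)
  phases <- list(t$i1, t$i2, t$i3)
  do.call(rbind, lapply(order, function(p) phases[[p]]))
}

#' Square-law demodulation: raw sectioned image
#'
#' Demodulates a phase triplet into the optically sectioned amplitude
#' \deqn{I_s = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_1-I_3)^2 + (I_2-I_3)^2}.}
#' Only in-focus light is modulated by the illumination grid, so the
#' pairwise differences cancel the unmodulated (out-of-focus plus offset)
#' component and the root-sum-of-squares extracts the modulation amplitude
#' regardless of the local grid phase.  With the sqrt(2)/3 prefactor a pure
#' sinusoid \eqn{I_i = A + B\cos(\phi + 2\pi(i-1)/3)} demodulates to exactly
#' `B` (and [widefield_raw()] returns exactly `A`).
#'
#' The result is in the same unit as the input and is everywhere
#' non-negative; it is invariant to adding any constant to all three phases
#' and to permuting the phases, and scales linearly with the input.
#'
#' @param t A [phase_triplet()].
#' @param prefactor Demodulation prefactor; the default `sqrt(2)/3` is the
#'   convention used throughout the package.  Photon-calibrated outputs are
#'   prefactor-invariant as long as demodulation and contrast calibration
#'   share the convention, which is why it is exposed at all.
#' @return An M x N matrix, same unit as the input, `>= 0`.
#' @export
#' @examples
#' t <- phase_triplet(matrix(3, 1, 1), matrix(2, 1, 1), matrix(1, 1, 1))
#' sectioned_raw(t)   # sqrt(12)/3 = 1.1547
sectioned_raw <- function(t, prefactor = sqrt(2) / 3) {
  stopifnot(inherits(t, "phase_triplet"))
  prefactor * sqrt(pairwise_sq_diff(t))
}

## sum of squared pairwise differences D = (I1-I2)^2 + (I1-I3)^2 + (I2-I3)^2
pairwise_sq_diff <- function(t) {
  (t$i1 - t$i2)^2 + (t$i1 - t$i3)^2 + (t$i2 - t$i3)^2
}

#' Wide-field image from a phase triplet
#'
#' Arithmetic mean of the three phases.  The three illumination patterns are
#' 2pi/3 apart, so their sinusoidal terms cancel exactly and the mean equals
#' the image that uniform illumination at the same average intensity would
#' have produced -- in single-exposure units, matching the photon-counting
#' semantics of the calibrated pipeline.
#'
#' @inheritParams sectioned_raw
#' @return An M x N matrix, same unit as the input.
#' @export
widefield_raw <- function(t) {
  stopifnot(inherits(t, "phase_triplet"))
  (t$i1 + t$i2 + t$i3) / 3
}
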