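---
title: "Photon-calibrated optical sectioning SIM: models, calibration and noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-calibrated optical sectioning SIM: models, calibration and noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonsim)
```

## The measurement model

Optical-sectioning structured illumination microscopy (SIM) images a sample
three times under a sinusoidal illumination grid shifted by 0, $2\pi/3$ and
$4\pi/3$.  Per pixel, the expected signal of phase $i$ in photons is

$$\lambda_i = F\,\bigl(1 + m\cos(\varphi + 2\pi(i-1)/3)\bigr) + B,$$

where $F$ is the in-focus photon flux, $B$ the unmodulated out-of-focus
background, $m\in(0,1]$ the illumination modulation contrast at the sample
plane, and $\varphi$ the local grid phase.  Only in-focus light carries the
modulation, which is what makes sectioning possible: the square-law
demodulation

$$I_s = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_1-I_3)^2 + (I_2-I_3)^2}$$

returns the modulation amplitude $mF$ regardless of $\varphi$, and the
three-phase mean $I_w = (I_1+I_2+I_3)/3$ returns $F + B$, the image uniform
illumination would have produced.  The $\sqrt2/3$ prefactor is a convention
(a pure sinusoid of amplitude $B$ demodulates to exactly $B$); every
photon-calibrated output is invariant to it as long as demodulation and
contrast calibration share it, which `photonsim` enforces by threading one
`prefactor` argument through both.  The wide-field estimator is the *mean*,
not the sum, of the phases so that its photon values have single-exposure
semantics consistent with the shot-noise photon-counting relation below.

The camera is modelled as linear: $DN = \mathrm{round}(\mathrm{clip}(g\,
\mathrm{Pois}(\lambda) + \mathcal N(0,\sigma_r) + \text{offset}))$ with gain
$g$ (DN/photon), dark offset (DN) and Gaussian read noise $\sigma_r$ (DN).
Raw data are converted by $N = (DN - \text{offset})/g$; sub-dark
fluctuations go slightly negative and are deliberately retained until the
final clamp, so averages stay unbiased.

## The two calibration experiments

**Camera gain (photon transfer).**  Pairs of uniformly illuminated frames
at more than five levels from dark to near saturation give per-level points
(mean above dark, temporal variance).  The variance is estimated as
$\mathrm{Var}(a-b)/2$ from each pair: differencing cancels static
photo-response and offset fixed-pattern structure that would otherwise
masquerade as temporal noise.  The photon-transfer relation
$\mathrm{Var} = g\,\overline{DN} + \sigma_r^2$ is fitted with weighted
least squares, weights $1/\hat v^2$ from a first unweighted pass.  This is
a deliberate deviation from a plain OLS fit: the sampling error of a sample
variance scales with the variance itself, so in a realistic series
($512^2$ pixels, $\sigma_r = 2$ DN) the *unweighted* intercept has a
standard error comparable to the true read-noise variance itself —
order 100 % — while the weighted fit, anchored by the precise dark and
low-light points, recovers it to a few percent.  The slope (gain) is
insensitive to the choice; the intercept is not.  Levels with means above
90 % of full scale (configurable) are excluded, since clipping destroys
the linear mean–variance relation.  Quantization adds $1/12\ \mathrm{DN}^2$
to the intercept, a $\sim$2 % bias at $\sigma_r = 2$ DN that we accept.

As a cross-check, a uniform field's photon count can be estimated without
knowing $g$ at all: for shot-noise-limited data
$N_d = (\overline{DN}/\sigma)^2$, since gain cancels from the ratio
(`photon_count_uniform()`).

**Modulation contrast.**  $m$ is specific to each objective/grid pair and
is measured from a raw SIM triplet of a thin fluorescent microsphere
layer.  For a thin layer ($B \approx 0$) the ratio $I_s/I_w = m$ exactly at
every lit pixel, so the estimator selects bright wide-field pixels (at or
above the 95th percentile, and above an absolute noise floor of ten read
noise sigmas) and takes the **median** of the per-pixel ratio — the paper
family's one-number-per-configuration framing, robust to the odd outlier.
Uniform background biases the ratio towards $m\,F/(F+B)$, which is the
quantitative reason the bead layer must be thinner than the sectioning
depth; the package asserts this monotone degradation in its tests rather
than pretending it away.  An estimated $m$ outside $(0,1]$ is rejected as
implausible (defocused grid or wrong concatenation layout).

## Photon estimation and its debiasing

The naive quantitative sectioned image is $I_s/m$.  Under noise it is
biased: writing $D$ for the sum of squared pairwise differences, each
per-frame noise variance $V_i = N_i + \sigma_r^2/g^2$ inflates $D$ by
$2(V_1+V_2+V_3)$ in expectation, and the square root then adds a concavity
bias of the opposite sign.  At $F = 200$, $m = 0.5$ photons the plain
estimator overshoots by 1–4 % as $B$ grows from 0 to 800 — real bias, not
Monte-Carlo error.  `process_triplet()` therefore (by default):

1. subtracts the plug-in noise inflation: $D_c = \max(D - 2\sum_i V_i,\,0)$;
2. corrects the square root's concavity with a second-order Taylor factor
   $1 + \widehat{\mathrm{Var}}(D)/(8 D_c^2)$, where
   $\widehat{\mathrm{Var}}(D) = 4\sum_i (2I_i-I_j-I_k)^2 V_i$, with the
   denominator floored at $\sqrt{\widehat{\mathrm{Var}}(D)}$ and the whole
   factor capped at 1.25 — the Taylor series is only meaningful while the
   correction is small, and an uncapped factor explodes at near-zero
   modulation.

The cap and floor are numerical guards chosen once, before the validation
suite was run against them, on the argument above; they are not tuned
constants.  With debiasing the ensemble mean tracks the true $F$ to
well under 1 % across $B \in \{0, 200, 800\}$ (the package's Monte-Carlo
oracle verifies this in `test-acceptance.R`).  `debias = FALSE` restores
the plain estimator, which is the right choice for noiseless closed-form
checks — debiasing necessarily subtracts a nonzero expected-noise term
and so breaks noiseless exactness; the two properties (noiseless
exactness, noisy unbiasedness) cannot be had by one estimator, and the
package resolves the tension with an explicit switch defaulting to the
quantitative (noisy-data) behaviour.  The final sectioned image is clamped
at zero.

## Noise maps

SIM noise has three sources: shot noise of the in-focus light, shot noise
of the out-of-focus light (removed in the mean but not in variance), and
the amplification introduced by the nonlinear demodulation.  The wide-field
map is exact first-order propagation through the three-frame mean,
$\sigma_W = \sqrt{(V_1+V_2+V_3)/9}$.  The sectioned map propagates the
per-frame variances through the square law by the delta method,

$$\frac{\partial I_s}{\partial I_i} = \frac{\sqrt 2}{3}\,
\frac{2I_i - I_j - I_k}{\sqrt D},\qquad
\sigma_s = \frac 1m\sqrt{\textstyle\sum_i
\bigl(\partial I_s/\partial I_i\bigr)^2 V_i},$$

with the phase-averaged closed form $\mathrm{Var}(I_s) = \tfrac23\bar V$
substituted where $D$ is numerically zero (locally unmodulated pixels,
where the derivative is singular).  Read noise is included in both maps
(referred to photons as $\sigma_r^2/g^2$) and the inclusion is recorded in
the output metadata.  Dividing by $m \le 1$ is exactly the demodulation
noise amplification: the sectioned map is never below the wide-field map
for the same scene, grows monotonically with $B$, and shrinks
monotonically with $m$.  These predictions are anchored to the Monte-Carlo
ensemble (2000 realizations, median relative deviation under 5 % at
$F \ge 50$), not to any transcribed constant.

## What the simulator emulates — and what it does not

The generator's stated world: a 12-bit (calibration) or 16-bit (imaging)
camera at $g = 2$ DN/photon, offset 100 DN, read noise 2 DN; flat-field
ramps of 8 levels from dark to 80 % of full scale; bead fields of 200
Gaussian beads of peak 2000 photons and $\sigma = 1.5$ px on a 12.8 px
grid with $m = 0.6$; test scenes of $F = 200$, $B \in \{0,200,800\}$,
$m = 0.5$.  Defocus is injected directly as the unmodulated $B$ term
rather than through a 3D PSF: the per-pixel algorithms distinguish only
modulated from unmodulated light, so this is the minimal faithful model.
Consequently a green test establishes correctness of calibration,
demodulation, unit conversion and noise propagation — it does not
establish anything about PSF shape, contrast decay with defocus, stripe
artifacts from grid drift, bleaching, or camera nonlinearity, none of
which are modelled.  Rounding and clipping *are* part of the default
camera so calibration sees realistic quantization; closed-form tests use
the `noiseless` flag.  Randomness is fully seeded, with per-page/per-frame
sub-seeds derived deterministically from one master seed.

## Numerical and design choices

* **Phase geometry** is fixed at $2\pi/3$; other step counts are out of
  scope.  The raw layout is three phase images concatenated row-wise
  ($3M \times N$); the block-to-phase order is configurable (`order`,
  default top-to-bottom = phases 1, 2, 3) because acquisition software
  rarely documents it — all outputs are permutation-invariant, so it is
  metadata only.
* **Degenerate-pixel threshold**: $D \le 10^{-12}\max(\sum I_i^2, 1)$
  switches the noise map to the phase-averaged form.
* **Saturation** in the simulator warns rather than errors (highlights
  clip, as on a real camera); in gain fitting, saturated levels are
  excluded and fewer than five usable levels is a hard error.
* **Calibration file** is versioned human-readable text at full double
  precision (the original plugin's binary format is undocumented, so an
  open format replaces it); unknown versions and missing fields are hard
  schema errors.  Output manifests carry an MD5 digest of the calibration
  numbers, so any stale-calibration mismatch is detectable.
* **Depths are independent**: no axial regularization; a 3D stack is a
  sequence of per-depth reconstructions with depth bookkeeping.
* **TIFF I/O** is a purpose-built baseline codec (uncompressed greyscale,
  8/16-bit unsigned in, 32-bit float out, multi-page), cross-checked in
  the test suite against an independent TIFF implementation.

## Known limitations

Per-pixel gain maps (PRNU), dark-current versus integration time, EM
excess noise, super-resolution SIM reconstruction and frequency-domain
processing are out of scope.  The contrast estimator assumes an evenly
covered, thin bead field; sparse fields make the 95th-percentile selection
noisier.  The noise maps are first-order predictions evaluated at the
observed counts: at very low signal ($mF$ within a few standard errors of
zero) the clamped square root makes both the photon estimate and its
predicted error conservative rather than exact.
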