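---
title: "Polarization holographic imaging of flowing microplastics: models and methods"
author: "holopol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarization holographic imaging of flowing microplastics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holopol)
```

## The measurement problem

Millimetre-scale plastic particles suspended in water are transparent,
which makes them nearly invisible to ordinary bright-field imaging and
indistinguishable from mineral or biological debris. Two optical
properties rescue the measurement. First, any particle in a coherent
beam scatters a wavefront that interferes with the unscattered
illumination, so a single camera frame — an in-line (Gabor) hologram —
encodes the particle's position, outline and focus depth. Second, many
common polymers (PC, PET, PVC, PP, PS, PMMA) are birefringent: they act
as weak linear retarders, rotating some of a circularly polarized beam
into linear polarization in a material-dependent amount, while glass and
other isotropic contaminants do not. A polarization camera whose 2x2
pixel groups carry wire-grid analyzers at 0, 45, 90 and 135 degrees
captures both signals in one shot, for particles flowing continuously
through a quartz channel.

`holopol` implements this instrument end to end in simulation and
analysis: a physically based synthetic-scene renderer with complete
ground truth, Stokes/DoLP/AoP/SSD feature recovery, angular-spectrum
reconstruction, particle morphometry, multi-frame tracking and counting,
nearest-centroid material classification, and Bland-Altman agreement
statistics.

## Forward model

### Vector Gabor rendering

Each rendered frame follows the Jones calculus of the optical train.
The illumination is left-circular, `E = (1, i)/sqrt(2)` times the square
root of the illumination intensity. At the object plane a particle
multiplies the field by a scalar amplitude transmittance `t` and a
linear-retarder Jones matrix `J(delta, theta)` with retardance `delta`
(drawn once per particle from `Normal(delta_mean, delta_sd)` clipped to
`[0, pi]` — birefringence is treated as a material property, uniform
within a particle) and fast-axis angle `theta`. Both field components
are then propagated independently over the sample-to-sensor distance
`z` by the angular-spectrum operator; water and the quartz walls are
treated as isotropic. At the sensor, the analyzer at angle `a` records
`|cos(a) Ex + sin(a) Ey|^2`. There is no separate reference beam: the
undiffracted background is the reference, and the twin image that this
geometry produces is accepted, as it is in the real instrument.

All sign conventions (circular handedness, the propagation kernel sign,
which axis acquires the retarder phase) are centralized in
`holopol_conventions()`. One consequence worth stating: with this
handedness a uniform retarder frame renders channel intensities
`I(a) = (1/2) (1 - sin(delta) sin(2a - 2 theta))` per unit illumination,
which the test suite pins against an independent Mueller-calculus
oracle.

### Propagation

`angular_spectrum_propagate()` multiplies the field spectrum by
`exp(-i 2 pi z / lambda * sqrt(1 - lambda^2 (fx^2 + fy^2)))`, with the
zero-frequency sample at the array origin. Evanescent components are
hard-zeroed rather than decayed: for the distances used here they carry
no usable signal and zeroing avoids overflow at large `z`. The kernel
is unitary below the cutoff, so band-limited fields conserve energy to
numerical precision and `z` followed by `-z` is an identity — both are
tested. Sampling imposes `|z| <= N * pitch^2 / lambda` (about 19 mm for
a 256-pixel grid at the 6.9 um channel pitch); the renderer refuses
larger distances with a sampling error rather than aliasing silently.
No zero-padding is applied by default; wrap-around from the FFT
periodicity is negligible at the validated distances.

### Study conditions

The synthetic defaults are the instrument's: 632.8 nm illumination,
3.45 um physical pixels in 2x2 analyzer groups (6.9 um channel pitch)
on a 2464x2056 mosaic, a 5x10 mm flow channel driven at 8 ml/min
(2.667 mm/s bulk speed), and circular input polarization. The
sample-to-sensor distance is not published; 5 mm — the channel
half-thickness scale — is adopted once and sits comfortably inside the
sampling bound. Magnification defaults to 1 (lensless in-line), so one
channel pixel maps to 6.9 um at the object plane.

The per-material retardance means (glass 0, PMMA 0.15, PS 0.35, PVC
0.45, PC 0.6, PP 0.9, PET 1.3 rad; SD 0.05) are *configuration, not
physics*: published birefringence values for these polymers as
suspended millimetre fragments do not exist, so the table is chosen
only to create orderable birefringence classes and is documented as
synthetic throughout.

## Feature recovery

The four channels give the linear Stokes maps `I = I0 + I90`,
`Q = I0 - I90`, `U = I45 - I135`, from which

* `DoLP = sqrt(Q^2 + U^2) / I`, with pixels below `1e-3` of the frame
  maximum flagged invalid rather than divided (the floor is
  configurable);
* `AoP = (1/2) atan(U / Q)` with the single-argument arctangent, which
  fixes the range to `[-pi/4, +pi/4]`; `Q = 0` maps to
  `sign(U) pi / 4`, and fully depolarized pixels are 0 and invalid;
* `SSD`, the per-pixel population standard deviation (divisor N = 4,
  stated so the closed forms are exact) across the four channels.

For a uniform retarder under circular light, `DoLP = |sin(delta)|`
independent of `theta`, and `SSD = |sin(delta)| / (2 sqrt(2))` times
the total intensity — the closed forms that make the glass control
(`delta = 0` gives identically zero DoLP and SSD, even through
propagation) and the material contrast claims falsifiable. SSD and DoLP
are computed on the raw four-angle holograms by default — inside a
particle's geometric shadow they approximate their object-plane values —
with the reconstructed-amplitude route available where in-focus feature
maps are preferred.

## Segmentation and the twin image

Detecting particles on in-line holograms must confront the twin image:
every particle is surrounded by a halo of diffraction rings whose
amplitude, for strongly retarding materials, exceeds the whole signal
of weakly retarding ones. Two observations make segmentation reliable:

1. The rings are *phase-oscillatory* while the in-focus object term is
   phase-coherent. Smoothing the complex reconstruction (Gaussian,
   sigma 3 px, applied to real and imaginary parts before the modulus)
   cancels most of the halo and leaves particle supports intact. This
   smoothed amplitude is used only to *find* candidates, above an
   absolute floor of 3% of the median intensity (below which blank
   frames would otherwise hallucinate structure — automatic thresholds
   always find a "bimodal" split).
2. Contrast is per-particle, not per-frame: a global automatic
   threshold set by the brightest particle drops the faintest. Each
   candidate is therefore re-thresholded by an Otsu split computed in
   its own bounding-box neighbourhood on the raw amplitude, followed by
   closing, hole filling and 8-connected labelling with a minimum-area
   filter.

With this two-stage detector the full render-process-segment chain
recovers ground-truth maximum Feret diameter and area exactly for all
six materials at the battery's particle sizes, which is well inside the
3%/5% envelope the tests enforce.

## Morphometry

All caliper measures use the pixel-corner (outer boundary) convention:
each boundary pixel contributes its four corners, so a single pixel has
extent 1 px and diagonal `sqrt(2)` px; a 30x40 px rectangle has maximum
Feret diameter 50 px. A brute-force maximum over convex-hull vertex
pairs is the declared truth; the rotating-calipers implementation is
required by the tests to agree with it *exactly* on 1000 random masks.
Minimum Feret width is the smallest over hull edges of the farthest
vertex distance.

The perimeter comes from the traced crack (pixel-corner) outline after
two midpoint-smoothing passes: the raw crack polygon is exact for
axis-aligned edges but overestimates oblique ones by up to `sqrt(2)`;
two passes make 45-degree staircases exact and bring smooth outlines
within a few percent. Circularity uses the perimeter-equivalence form
`C = 2 sqrt(pi A) / P` (the convention of commercial particle-imaging
instruments; the squared form is exposed as an option), giving a large
rasterized disc about 0.97 and a square 0.89 against the continuous
`sqrt(pi)/2 = 0.886`. Sphere-equivalent volume is `(pi/6) CED^3` with
`CED = 2 sqrt(A/pi)`. Area is pixel count times the squared
object-plane pixel size — the calibration the instrument's own software
leaves unstated.

Shape classes are a fixed-order rule cascade (fiber by aspect >= 5;
bead by circularity >= 0.92 and aspect <= 1.2; pellet by circularity >=
0.85 and aspect <= 1.5; foam by solidity < 0.85; film by transmittance
>= 0.9 and area; else fragment), with every threshold configurable. A
mask-only classifier cannot recognize films — that class requires the
transmittance feature estimated from the intensity ratio inside versus
outside the mask (which measures `t^2` for a transmittance-`t`
particle).

## Autofocus

The reconstruction depth is found by maximizing a focus metric over a
uniform `z` grid, ties toward the smallest depth (so a featureless
hologram returns the lower bound, documented). An intensity-variance
metric turns out to be useless here: the mean-subtracted deviation
field's energy is conserved under propagation, so for the weak objects
of this instrument normalized variance is nearly flat in `z` and its
maximum lands on a scan edge. The implemented metric is the normalized
gradient energy (Brenner-style squared first differences of the
amplitude, background retained), which concentrates sharply at the true
depth — the simulator round trip recovers the render depth to within
one scan step.

## Tracking and counting

The detector-tracker is deliberately classical and fully specified: a
constant-velocity greedy linker. Each live track predicts its next
position as last position plus velocity (the difference of its last two
matched positions); detections within a gate are assigned nearest-first
with ties to the lower track id; unmatched detections spawn tentative
tracks; tracks confirm after 3 consecutive hits and terminate after 5
consecutive misses, and a confirmation, once earned, keeps the particle
in the count after its track ends at the channel exit. The default gate
is twice the expected per-frame flow displacement plus 10 px. Greedy
association rather than global assignment is adequate at flow-cell
densities and keeps the linker deterministic; there is no appearance
model or re-identification.

Against ground truth, a particle counts as correctly counted when a
confirmed track covers at least half of its visible trajectory (centroid
within 15 px per frame). Counting accuracy is `1 - |count - true|/true`.

## Material classification

The discriminative signal — SSD and DoLP statistics within the mask —
is low-dimensional, so the classifier is a transparent nearest-centroid
model: features (mean SSD, 90th-percentile SSD, mean DoLP, mean
transmittance) are standardized by the training-set mean and the
*pooled within-class* SD (zero-variance features dropped), each class
is its mean standardized vector, prediction is the nearest centroid
with ties to the first class in model order. Within-class rather than
total SD matters: it expresses separations in units of measurement
noise, so a feature with no class signal — transmittance, when all
plastics share the same nominal value — stays at unit noise instead of
being inflated into a spurious discriminant, while the birefringence
features' class gaps grow to many noise units. Standardization makes
predictions invariant to affine rescaling of any raw feature. The split is stratified 8:1:1 by class
under a seed; the validation share is reserved for threshold tuning of
segmentation and is not consumed by the centroid model. Feature
statistics are taken over a mask eroded by 2 px (boundary pixels mix
particle and background fringes) and, along a track, as medians over
the fully visible detections only, since border-clipped frames dilute
the polarimetric features.

## The synthetic battery and what it shows

The end-to-end figure of merit is computed by
`counting_classification_battery()`: 20 videos (seeds `base + 0..19`),
60 frames each, 256x256 channel resolution, alternating noiseless and
mildly noisy (1% background scatter, 1% shot-noise scale, 0.002 read
noise), with 3-4 particles per video in distinct flow lanes spaced so
that particles can never merge, sizes 170-310 um, drawn from the six
plastics with retardance SD tightened to 0.02 rad so that adjacent
class means are at least 4 pooled SD apart — the separation the battery
is defined to test. Particle features are pooled across videos, split
8:1:1, the centroid model is trained on the training share, and the
battery reports the fraction of ground-truth particles that are both
correctly counted and correctly classified. Under these conditions the
rate is ~98% (the residual errors are retardance draws landing between
adjacent classes), which the acceptance suite requires to be at least
96%.

What passing does *not* show: performance on real water samples. The
generator has no turbidity or multiple scattering, no polarization
aberrations of real optics, no camera-specific radiometric response, no
particle rotation during transit, uniform within-particle birefringence,
and a synthetic retardance table. The battery validates the pipeline's
internal consistency under the instrument's stated geometry, not field
accuracy.

## Numerical choices and degenerate inputs

* Population (N = 4) SD for SSD — a fixed rescaling that keeps closed
  forms exact.
* Single-argument arctangent for AoP — matches the stated `[-pi/4,
  pi/4]` range; the two-argument form would double it.
* Blank or constant images segment to zero particles, not an error;
  empty masks raise explicit empty-region errors in every morphometric
  function.
* Bland-Altman uses the sample SD (n-1) and the 1.96 normal quantile —
  the classic construction, with no proportional-bias regression.
* All randomness flows through explicit integer seeds (scene seed,
  per-particle seeds derived below 2^31, split seed); fixed seeds give
  bit-identical renders, splits and pipelines.
* 16-bit TIFF for mosaics (physical scale in a plain-text sidecar),
  32-bit-float TIFF for feature maps (range sidecar), RGB PNG for label
  masks (id split across two 8-bit channels), CSV for particle and
  track tables, JSON for configuration, models and summaries; all
  writers are atomic (temp file + rename).

## Known limitations

Twin-image suppression is limited to the complex-smoothing detector;
no iterative phase retrieval is attempted. Overlapping particles are
segmented as one; the tracker carries no appearance features, so
crossing trajectories at high density would swap identities. Glass
(non-birefringent, transmittance near 1) is polarimetrically silent by
design and detectable only through its weak amplitude contrast. The
paper-reported headline numbers from the physical instrument (96%
accuracy on 1000 captured images, Bland-Altman SD of bias 0.05935 on
n = 39 caliper pairs, 20 um calibrated resolution) are measurements on
undeposited physical data and are out of the package's reach; the
battery is the package's own, fully reproducible surrogate.
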