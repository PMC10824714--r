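# holopol

Polarization digital holography turns a single camera frame into two
measurements at once: an in-line (Gabor) hologram that encodes the
outline, size and focus depth of transparent particles flowing in
water, and a four-angle polarimetric capture that reveals which of
those particles are birefringent — the optical fingerprint separating
common plastics (PC, PET, PVC, PP, PS, PMMA) from glass and other
isotropic debris. `holopol` is a toolkit for researchers building or
evaluating such instruments for microplastic monitoring: it simulates
the full acquisition physically (with complete ground truth), recovers
the polarimetric feature maps, reconstructs fields, measures and
tracks particles across video frames, classifies their material, and
quantifies measurement agreement.

## What it computes

**Polarimetry.** From the 2x2 polarization mosaic (analyzers at 0, 45,
90, 135 degrees) the linear Stokes maps

    I = I0 + I90,   Q = I0 - I90,   U = I45 - I135

and the derived features

    DoLP = sqrt(Q^2 + U^2) / I           in [0, 1]
    AoP  = (1/2) atan(U / Q)             in [-pi/4, pi/4]
    SSD  = population SD of {I0, I45, I90, I135}

For a uniform retarder of retardance `delta` under circular
illumination, `DoLP = |sin(delta)|` and `SSD = |sin(delta)|/(2*sqrt(2))`
times total intensity — closed forms the test suite verifies against an
independent Mueller-calculus oracle.

**Holography.** Hologram formation `I = |U_R + U_O|^2`, DC suppression,
and angular-spectrum propagation

    Gamma = IFFT{ FFT{E_R* h} * exp(-i 2 pi z / lambda
                                    * sqrt(1 - lambda^2 (fx^2 + fy^2))) }

with evanescent components zeroed, plus autofocus by a gradient-energy
metric over a depth scan.

**Morphometry, tracking, classification, agreement.** Per-particle
maximum/minimum Feret diameters (rotating calipers on the pixel-corner
convex hull), perimeter-equivalence circularity `2*sqrt(pi*A)/P`,
sphere-equivalent volume, shape classes (fragment, pellet, fiber, film,
foam, bead); a deterministic constant-velocity greedy tracker with
confirm/terminate logic for counting in flow; a nearest-centroid
material classifier on SSD/DoLP statistics with a stratified 8:1:1
split; and Bland-Altman bias and 95% limits of agreement.

**Synthetic scenes.** A first-class simulator renders
polarization-mosaic holograms and videos of birefringent particles
(632.8 nm, 3.45 um pixels, 2464x2056 mosaic, 5x10 mm channel at
8 ml/min by default) via Jones calculus and angular-spectrum
propagation, with per-frame label masks, trajectories and counts as
ground truth.

## Worked example

```r
library(holopol)
cfg  <- optical_config()            # 632.8 nm, 6.9 um channel pitch, z = 5 mm
px   <- object_pixel_size(cfg)
mats <- default_materials()

scene <- scene_spec(
  particles = list(
    particle_spec("bead",  250e-6, c( 60, 190) * px, 0.4, mats$PET),
    particle_spec("fiber", 320e-6, c(190,  70) * px, 1.1, mats$PMMA)),
  field_of_view = c(256, 256), seed = 42)

rendered <- render_polarized_hologram(scene, cfg)
mosaic   <- mosaic_sample(rendered$stack)        # interleaved sensor frame
frame    <- process_frame(mosaic, cfg)           # split, features, reconstruct, segment
frame$detections[, c("cx", "cy", "mfd_um", "width_um", "circularity",
                     "shape", "ssd_mean", "dolp_mean")]
#>    cx  cy mfd_um width_um circularity shape ssd_mean dolp_mean
#> 1  60 190    258    253.7       0.973  bead   0.2945     0.965
#> 2 190  70    328     44.6       0.550 fiber   0.0475     0.158
```

The strongly birefringent PET bead (drawn retardance near 1.32 rad,
`|sin(delta)| = 0.968`) is measured at DoLP 0.965; the weakly
birefringent PMMA fiber reads 0.158 — the separation the material
classifier feeds on. Sizes and shapes come out right: 258 um and
circularity 0.97 for the 250 um bead, a 328 x 45 um fiber for the
fiber. Comparing measured against ground-truth Feret diameters:

```r
est <- frame$detections$mfd_um[order(frame$detections$cx)]
ref <- c(max_feret(rendered$truth$labels == 1, px * 1e6),
         max_feret(rendered$truth$labels == 2, px * 1e6))
bland_altman(est, ref)
#> Bland-Altman agreement (n = 2)
#>   bias 0, SD of differences 0
#>   95% LOAs [0, 0]; 100.0% of pairs inside
```

For videos, `render_video()` produces flowing-particle mosaics with
ground truth, and `run_pipeline()` (or the `inst/cli/holopol` script)
runs detection, tracking, counting, classification and report writing
in one call. The methods vignette
(`vignettes/holopol-methods.Rmd`) documents the optical model, every
tunable parameter, and the design decisions.

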