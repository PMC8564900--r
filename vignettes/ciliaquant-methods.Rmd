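---
title: "ciliaquant: models, measurement rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ciliaquant: models, measurement rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaquant)
```

## The measurement problem

The photoreceptor connecting cilium (CC) is a thin cylindrical bridge,
roughly 1100 nm long and 300 nm across, between the inner and outer
segments of rod cells. Questions about where a protein sits inside it —
how far it extends along the axis, at what radius it sits between the
microtubule axoneme and the ciliary membrane, whether it is distributed
symmetrically about the axis — are at or below the resolution limit of
conventional fluorescence microscopy, so they are answered with
super-resolution images (SIM reconstructions, STORM renderings) and
electron microscopy, reduced to numbers by a small set of measurement
rules. `ciliaquant` implements those rules as tested, reusable code:

1. **Straighten** a curved cilium along a centerline polyline
   (equal-arc-length resampling, bilinear interpolation).
2. **Row-average profile**: the mean intensity of each pixel row along
   the straightened cilium — the 1D signal all edges are called on.
   Column averages give the transverse profile for radii.
3. **Fractional-threshold edges**: the signal boundary is where the
   profile crosses `background + f * (max - background)`, with
   `f = 0.33` for CC channels, `f = 0.5` (FWHM) for hRPE-1 primary
   cilia and `f = 1/e` for STORM clusters. Crossings are located
   sub-sample by linear interpolation; lengths are reported from the
   distal edge of the CEP164 channel (the inner-segment/CC interface)
   and restricted to a 1.1 µm analysis window; radii are the larger of
   the two lateral distances from the reference channel's transverse
   maximum.
4. **STORM localization**: per-frame candidate detection, elliptical 2D
   Gaussian PSF fitting, event acceptance at the published
   identification settings (height 400–65,636 counts, width 200–700 nm,
   initial fit width 350 nm, axial ratio ≤ 2.5), frame linking within
   1 pixel, Gaussian rendering.
5. **TEM diameters**: cross-sections are not perfectly circular, so two
   perpendicular principal-axis diameters are measured and the shorter
   one kept.
6. **Group statistics**: mean ± SD (n) summaries, Student's two-tailed
   pooled-variance t test for two-way comparisons, one-way ANOVA with
   Tukey (all pairs) or Dunnett (vs control genotype) correction.

Because the underlying retinal image data are not deposited anywhere,
every stage is validated against a synthetic cilium generator with known
ground truth rather than against the original images.

## The synthetic cilium model

A cilium is a cylinder with axial coordinate `z` (`z = 0` at the IS/CC
interface, i.e. the distal edge of CEP164; distal positive). Structural
radii derive from TEM cross-section diameters, halved — TEM being the
least-blurred measurement available — while fluorescence-derived widths
are treated as label-position estimates, not structure:

| preset | axoneme ring radius | membrane radius | length |
|---|---|---|---|
| `WT_adult` | 93 nm (186/2) | 130.55 nm (261.1/2) | 1100 nm |
| `WT_P10` | 93 | 130.55 | 1000 nm |
| `rd16_P10` | 85.75 (171.5/2) | 122.9 | 820 nm |
| `NN_P10` | 85.8 (171.6/2) | 119.85 | 1000 nm |
| `KO_P10` | 80.65 (161.3/2) | 108.65 | 820 nm |

Values not printed anywhere had to be fixed once: the lumen radius is
the ring radius minus 30 nm (the approximate footprint of a microtubule
doublet); mutant P10 lengths follow the measured shortening pattern
(rd16 and KO significantly shorter, scaled by the ~0.82 ratio of the
reported rd16/WT CEP290 lengths of 750 vs 913 nm; NN not significantly
different). The `hRPE1` preset moves centrin to the basal body, gives
CEP290 a 200 nm basal patch whose distal edge sits just distal to the
centrin patch, and puts NPHP8/MKS3 in a ~300 nm distal transition zone.

Each channel draws emitters with a Poisson count
(`density × axial extent × labeling efficiency`), uniform axial
positions, and one of five radial laws: uniform disk (`lumen_fill`,
`basal_patch`), area-uniform annulus, thin uniform shell
(`membrane_shell`), or Gaussian clusters around the nine doublet
azimuths (`doublet_ring`, whose radial law is therefore Rice-distributed
— the property tests check exactly that). Azimuthal asymmetry is a von
Mises concentration (sampled by Best–Fisher rejection; `kappa = 2` for
CEP290 reproduces a clearly one-sided annulus while `kappa = 0` is
uniform). Emitter densities (600–2500 per µm depending on marker) and
photon budgets were chosen once as realistic for well-stained samples
and are constructor arguments, not tuned constants.

Bent fixtures come from an exact isometry: the straight axis is mapped
onto a circle of radius `1/curvature` in the x–z plane, preserving arc
length and radial offsets, so the straightening round trip has a known
answer.

### Imaging

SIM is emulated as Gaussian-PSF imaging of reconstructed-resolution
images (the commercial reconstruction itself is out of scope): each
emitter deposits a pixel-integrated isotropic Gaussian carrying its
photon budget, then Poisson shot noise, constant background and
Gaussian read noise are applied. The default PSF FWHM of **120 nm** at
**40 nm/px** is a documented assumption — the effective PSF of the
reconstructions is not stated anywhere — and is exposed in
`imaging_model()`. Photon conservation (noiseless image integral =
summed budgets to 0.1%) is a tested invariant.

STORM raw frames use a two-state blinking model: each fluorophore is on
per frame with probability `on_probability`, emitting a normal photon
count rendered at the raw pixel size (160 nm) with a 350 nm FWHM raw
PSF; a 50,000-frame acquisition is the default scale, tests use far
fewer. No drift, no 3D astigmatism, no multi-emitter overlap resolution,
no photophysics beyond the two states.

## Numerical and convention choices

* **Width convention.** The published identification settings (width
  200–700 nm, initial fit 350 nm) are only physically consistent with a
  single-molecule raw PSF if read as *full widths at half maximum* — a
  350 nm Gaussian *sigma* would be an ~820 nm FWHM spot. The default is
  therefore `width_convention = "fwhm"`, with `"sigma"` selectable,
  since fitting software rarely documents which it reports.
* **Fitting.** PSF fits are least squares (Nelder–Mead, then BFGS),
  followed by one variance-weighted refit with weights from the
  shot-noise model; the weighted pass takes plain least squares (which
  loses ~30–60% precision on Poisson data) to near the
  maximum-likelihood precision, which is what makes the 1.5× photon
  limit achievable. Non-convergence is a `fit_failure` reason code,
  distinct from filter rejections, so acceptance statistics are
  auditable. Filters are applied in a fixed order (height low/high,
  width low/high, axial ratio) and record the first failed rule.
* **Event amplitudes.** Blinking photon budgets are integrated counts
  at unit camera gain; the default (5000 ± 800) keeps typical fitted
  amplitudes (~900 counts) inside the published 400–65,636 count window.
* **Edges.** Thresholds use the literal fraction of the maximum with
  `background = 0` by default (the published rule mentions no background
  term); a robust background can be supplied and makes the rule
  well-defined on noisy data. Edge positions are linearly interpolated
  between bracketing samples and only rounded at reporting time.
  Profiles are not smoothed by default. Tied maxima are averaged (so a
  symmetric two-peak reference centers at 0). A side that never drops
  below threshold is clamped to the profile end and flagged
  `truncated`; a distal edge beyond the 1.1 µm window is clamped and
  flagged `overrun`. The window is disabled (`window_nm = Inf`) in
  hRPE-1 mode.
* **Origin.** Whether the interface origin is CEP164's distal 33% edge
  or its intensity maximum is not stated; the default is the distal
  edge (`origin_mode = "distal_edge"`), the maximum is selectable.
* **Detection threshold.** The published settings list no pre-fit
  detection threshold; `detect_candidates()` exposes one (default 50
  counts above the frame median) with non-maximum suppression within
  one initial fit width.
* **Dunnett.** No reference implementation is named for the post hoc
  procedure, so adjusted p values integrate the many-to-one multivariate
  t (correlation `sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`) by Monte
  Carlo with a fixed internal seed and ~5e-4 absolute tolerance;
  `p_adj` is clamped to `[p_raw, 1]`. Tukey goes through `ptukey` and is
  cross-checked against `stats::TukeyHSD`. The t test is equal-variance
  Student (as named), with `p = 1` flagged for the all-equal
  zero-variance case.
* **Pooling.** Cilia are pooled across animals without a nesting term,
  replicating the source analysis rather than correcting it.
* **Pixels.** Pixel indices map to physical coordinates at pixel
  centers; images store nm/px and origin as metadata. With no TIFF
  library available, rasters travel as tab-separated text with a
  metadata header, frame stacks as concatenated frames in one file;
  tables are CSV and configuration/provenance YAML.

## What a green test does and does not establish

The generator reproduces the *geometry* of the measurement problem:
radial layering, axial extents, PSF blur, shot noise, blinking
statistics. It does not reproduce staining variability between animals,
fixation-induced shrinking/stretching (offered as the explanation for
SIM/STORM length differences), chromatic registration error, axonemal
flattening in the image plane, or out-of-focus light. Recovery tests
(mean centrin length within 10% of truth; radial ordering
centrin < AcTub ≤ CEP290 in ≥ 90% of simulated cilia; bent/straight
round trip within 5% RMS; ellipse minor axes within 1 px over random
orientations; type-I error within [0.04, 0.06] at α = 0.05) therefore
establish that the *pipeline* is faithful, not that the biological
numbers are reproduced — the original raw images are not publicly
available, so headline values like 984 ± 201 nm cannot be recomputed
from data.

## Known limitations

2D thin-section approximation throughout; no automatic cilium
segmentation (centerlines are inputs); no drift correction or dual-color
registration in the STORM stage; Dunnett p values are Monte Carlo (to
~1e-3) rather than closed form; the layer-fraction tool assumes layers
are horizontal bands.
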