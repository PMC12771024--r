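---
title: "Vessel and plaque morphometry for three-photon z-stacks: methods and design"
author: "morph3p"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel and plaque morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`morph3p` quantifies longitudinal two-channel three-photon (3P) microscopy
stacks of mouse cortex: an intravascular dye channel outlining vessel lumens
and an amyloid-binding dye channel marking plaques. Stacks are 3D arrays
indexed `(z, y, x)` with the shallowest plane first, carrying a physical
voxel spacing; every derived quantity — radii, lengths, volumes, distances —
is an index difference multiplied by that spacing, with voxels treated as
centered points on a 0-based grid. The default spacing, `(dx, dy, dz) =
(0.98, 0.98, 5)` µm, matches 512 × 512 pixel planes over a 500 × 500 µm
field with 5 µm axial steps, so the grid is roughly five-fold coarser along
z than in plane. That anisotropy drives several design decisions below.

## Vascular morphometry

Given a binary vessel mask (imported from an external segmenter such as a
dedicated vessel-segmentation CNN, or produced by the built-in Otsu
baseline), the chain is:

1. **Skeletonization** to a one-voxel-wide curve (topology-preserving
   thinning, see *Numerical choices*).
2. **Segment splitting**: a vessel segment is a maximal branch-point-free
   skeleton path between terminals (nodes with one neighbor, or three or
   more, under 26-connectivity). Paths shorter than 3 nodes, or shorter
   than 5 µm of path length, are discarded as skeletonization spurs.
3. **Per-segment metrics**:
   - radius at each centerline point = Euclidean distance to the nearest
     background voxel, computed with an exact anisotropic distance
     transform in physical units;
   - diameter `D = 2 * median(r_j)` (even counts average the two central
     values, making `D` deterministic);
   - length `L` = sum of consecutive centerline point distances;
   - tortuosity `T = L / ||p_N - p_1||`, 1 for a straight vessel,
     undefined (NA) for closed loops;
   - centroid = unweighted mean of the segment's skeleton coordinates;
   - inter-vessel distance (IVD) = minimum distance from the segment's
     centroid to any other segment's centroid.
4. **Totals**: total vascular volume is exactly
   `N_vessel * dx * dy * dz` where `N_vessel` counts mask voxels.

Mask quality is screened with the Dice coefficient
`2|A∩B| / (|A|+|B|)` against a manual annotation; values below 0.70 flag
the stack for manual correction rather than silently proceeding.

**Physical-unit radii.** Whether centerline radii should be measured in
voxels or micrometres is genuinely open on anisotropic grids; the two can
differ five-fold along z here. The package measures in micrometres,
because diameters are only comparable across differently oriented vessels
in physical units. This is stated prominently since it is the largest
single convention-dependent effect in the pipeline.

## Plaque morphometry

Semi-automatic segmentation computes four multilevel-Otsu thresholds over
the full 3D intensity histogram (five classes) and takes the two highest
classes as plaque; per plane, small holes are filled and objects under
5 px removed; components are then labeled in 3D (26-connectivity).
Components whose *largest single-plane cross-section* is smaller than
49 µm² are excluded (strict inequality). Volume is the sum of per-slice
areas times the axial step, and the equivalent-sphere radius
`r = (3V / 4π)^{1/3}` summarizes each plaque for cross-session comparison.
The nearest-vessel distance of each plaque centroid is an exact minimum
over vessel voxel centers.

The 49 µm² criterion is area-based but applied after 3D labeling; reading
it as a per-plane area keeps the units literal, and the alternative
(total summed area) is selectable via `plaque_area_mode = "total"`.
Fully manual workflows are supported by importing externally edited masks
(`segmentPlaques(mode = "manual_mask")`); no interactive editor is built.
Multilevel Otsu is computed on the whole volume, not per plane, because
per-plane thresholds fragment plaques across depth once signal attenuates;
this is also why depth normalization precedes segmentation in the
pipeline order.

## Preprocessing

The chain order is fixed: adaptive histogram equalization → crosstalk
removal → dura removal → per-plane normalization → denoising. Each step:

- **CLAHE**, per plane, tiles of 1/8 of the plane per axis, relative clip
  limit 0.01 (fraction of a tile's pixels any histogram bin may hold).
  Per-plane rather than 3D equalization was chosen because axial intensity
  decay would otherwise dominate every local histogram.
- **Crosstalk removal** is clamped linear unmixing,
  `corrected = max(target − α·source, 0)`, with a single scalar per channel
  pair. `α = "auto"` estimates the coefficient as the least-squares slope
  of target on source over voxels at or above the source's 99th intensity
  percentile, where the mixing signature is cleanest. Linear unmixing is
  the minimal defensible model for spectral bleed-through; it is not
  presented as any published pipeline's exact method.
- **Dura removal** discards shallow planes above a boundary. With a
  third-harmonic-generation (THG) stack, the boundary is found from the
  THG signal, which is strong at the dura: within the top 20 % of planes,
  the deepest plane whose mean exceeds the global THG mean + 2 SD, plus
  one. The 20 % restriction prevents deep bright planes from being misread
  as dura.
- **Normalization** rescales each plane's `[min, max]` onto the range of
  the reference plane — the deepest plane that is neither overexposed
  (max ≤ 95 % of the bit-depth maximum) nor constant. Constant planes
  cannot define a range and are skipped both as reference candidates and
  as rescaling targets; a degenerate reference disables scaling with a
  warning instead of producing NaNs.
- **Denoising** is a median filter whose kernel is sized physically: the
  nominal radius (default 1) applies in plane, and the axial radius is
  `round(radius * dx / dz)` — zero planes at the default spacing, i.e. a
  3 × 3 in-plane median. A cubic 3 × 3 × 3 kernel spans 15 µm axially at
  5 µm steps and erases any vessel confined to one plane, which is most
  capillaries at this sampling; the physically sized kernel is therefore
  the default, and a larger radius remains available for isotropic data.
- **Motion assessment** binarizes each plane (per-plane Otsu), tracks up
  to 5 single-vessel structures across consecutive planes by largest
  pixel overlap, and reports the per-plane shift of each structure's
  intensity-weighted centroid, in pixels. Only assessment is provided; no
  motion correction is applied, matching a workflow in which sub-2-pixel
  shifts were deemed negligible.

## Image-quality metrics

- **Signal strength** of a plane: mean of the top 0.5 % of pixels
  (`k = max(1, floor(0.005 n))`, so the metric is defined on small frames
  and depends only on the intensity multiset).
- **SBR**: mean of the 15 brightest over the 15 darkest samples of a line
  profile. "Profile" is read as a 1D line through the brightest vessel —
  by default the image row through the plane's maximum-intensity pixel —
  rather than the whole frame, consistent with line-profile-based depth
  reporting; an all-zero dark end signals infinite SBR explicitly.
- **FWHM** for bead-based resolution: baseline = profile minimum, half
  level midway to the maximum, crossings located by linear interpolation;
  truncated peaks are an error, not a guess.

## Between-session statistics

Distribution metrics (diameter, length, tortuosity, IVD, plaque radius)
are compared across two sessions with two-sided Mann–Whitney U tests,
unpaired, because segments are not tracked one-to-one across sessions.
The U statistic counts pairs with half-credit for ties. The p-value is
exact — full enumeration of the `choose(n+m, n)` rank assignments — when
`min(n, m) ≤ 8` and there are no ties, and otherwise uses the normal
approximation with tie and continuity corrections. Two-sided exact p is
`min(1, 2 min(P(U ≤ u), P(U ≥ u)))`. A Shapiro–Wilk screen is reported
per sample but is advisory: the nonparametric test is used regardless, so
normality never gates the pipeline. Scalar totals (vessel volume, plaque
volume) are reported as percent change `100 (v₂ − v₁)/v₁`. Stars follow
p < 0.05 / 0.01 / 0.001. No multiple-testing correction is applied by
default, matching per-metric reporting; `holm = TRUE` enables a Holm
adjustment.

# The synthetic phantom

Every quantitative claim in the test suite is validated against
`generatePhantom()`, which renders two channels with exact analytic ground
truth:

- **Vessels** are capsules around polylines: a voxel is foreground when
  its center lies within the tube radius of the centerline, with distances
  computed in physical micrometres against every polyline segment
  (brute-force; the stacks are small). Ground-truth length and tortuosity
  are polyline sums, so recovery errors measure the analysis chain, not
  the fixture.
- **Plaques** are spheres with analytic volume `(4/3)πr³`.
- **Depth attenuation** multiplies signal by `exp(−depth / L_att)`;
  the default `L_att = 300` µm is a typical effective attenuation length
  for ~1300 nm excitation in cortex, producing a ~2.9× signal drop over
  the default 315 µm stack.
- **Noise**: optionally Poisson counts on the attenuated signal followed
  by additive Gaussian read noise (default SD 1000 = 10 % of the
  10000-count peak when enabled), then clamping to the 16-bit range. The
  clamped background is deliberately realistic: it makes the background
  histogram bimodal, which is exactly the regime where naive global
  thresholds fail (see *Numerical choices*).
- **Crosstalk** mixes channels symmetrically, `observed_A = A + α·B`.
- **Jitter** shifts individual planes by integer pixels, filling exposed
  edges with background — the failure mode the motion assessment must
  detect.

Order of corruption: attenuation, background, noise, crosstalk, jitter.
Truth masks are pre-noise and pre-jitter. Identical specs (including the
seed) render voxelwise-identical stacks.

The default study conditions are a 256 × 256 × 64 stack at the standard
spacing containing five in-plane sinusoidal tubes of radius 2–5 µm at
increasing depth (tortuosity 1.00–1.06) and four spheres of radius
8–15 µm. These sizes keep the full suite in minutes while exercising the
clinically relevant regimes: capillary-scale vessels one plane thick, and
plaques spanning 3–7 planes.

**What the phantom does not emulate:** point-spread blur (no PSF
convolution), partial-volume intensities (voxels are binary in/out before
noise), scattering heterogeneity, vascular tree branching statistics,
pulsation or non-rigid motion, and dye kinetics. Passing the phantom
suite therefore demonstrates the correctness of the geometry and
statistics implementations and their behavior under noise, attenuation,
crosstalk and jitter — not segmentation performance on real tissue, where
an external CNN segmenter plus the Dice/manual-correction loop remains
the intended path.

# Numerical choices

- **Distance transform**: exact separable squared-distance transform
  (lower-envelope-of-parabolas), generalized with per-axis sample spacing
  so anisotropic physical distances are exact, not approximated.
- **Skeletonization** is iterative thinning that deletes only *simple
  points* of the (26, 6) foreground/background adjacency pair — exactly
  one 26-connected foreground component in the punctured neighborhood and
  one 6-connected background component in the 18-neighborhood — in six
  directional sub-iterations, keeping curve end points (one neighbor).
  Two safeguards matter on this data:
  1. Candidates are prefiltered by simplicity *at pass start*; without
     this, sequential deletion cascades through voxels that only become
     simple mid-pass and can consume an entire flat structure.
  2. A candidate is peeled only if its opposite-direction neighbor is
     foreground. A voxel that is one-thick along the pass direction is a
     membrane there, not a border; classical thinning families (including
     widely used reference implementations) otherwise annihilate
     one-plane-thick vessels outright, which we verified on flat-bar
     fixtures of widths 2–12.
  For anisotropic spacing the mask is additionally replicated to a
  near-isotropic grid along z, thinned, mapped back, and re-thinned to
  remove mapping duplicates — the standard make-isotropic-then-skeletonize
  practice, which centers the skeleton within multi-plane vessels.
- **Centerline smoothing**: a 5-node moving average (endpoints fixed) is
  applied before measuring length and tortuosity. The voxel staircase
  otherwise inflates the path length of oblique vessels by several
  percent, which propagates directly into tortuosity; window 5 (~5 µm of
  arc at this sampling) removes the stair frequency without flattening
  real curvature at the 100 µm scale. Set `smoothWindow = 0` to disable.
- **Otsu thresholds** (single and multilevel) are computed by exact
  dynamic programming over a 256-bin histogram, maximizing between-class
  variance; cost is independent of volume size. The baseline vessel
  segmenter guards against the known failure of global Otsu on
  low-foreground images: if the threshold marks more than 10 % of voxels
  as vessel — far above any plausible cortical vascular volume fraction —
  the split fell inside a bimodal background and the segmenter escalates
  to the three-class top split. Components below 27 voxels are removed.
- **Degenerate inputs** fail loudly and specifically: constant stacks
  cannot be thresholded; empty masks cannot be skeletonized; both-empty
  masks have undefined Dice; coincident endpoints have undefined
  tortuosity; a zero dark mean yields an explicit infinite SBR; a
  truncated FWHM peak is an error. Constant planes pass through
  equalization and normalization unchanged.
- **Tie-breaks**: even-count medians average the two central values;
  `filterSmallRegions` preserves original label order when re-indexing;
  the depth-profile line takes the first maximum in column-major order.

# Parameters at a glance

| key | default | unit | role |
|---|---|---|---|
| `dice_threshold` | 0.70 | – | QC flag for manual mask correction |
| `min_plaque_area` | 49 | µm² | strict lower bound on max slice area |
| `plaque_area_mode` | max_slice | – | which area the filter tests |
| `top_fraction` | 0.005 | – | pixel fraction for signal strength |
| `n_extreme` | 15 | px | SBR extreme-sample count |
| `saturation_fraction` | 0.95 | – | overexposure cutoff for normalization |
| `clip_limit` | 0.01 | – | CLAHE relative clip limit |
| `tile_grid` | 8 | tiles | CLAHE tiles per plane axis |
| `median_radius` | 1 | px | in-plane denoising radius |
| `min_segment_nodes` | 3 | nodes | spur pruning (node count) |
| `min_component_voxels` | 27 | voxels | baseline-segmenter speck removal |
| `min_object_px` | 5 | px | plaque in-plane cleanup |
| `crosstalk_alpha` | auto | – | unmixing coefficient |
| `n_motion_structures` | 5 | – | structures tracked by motion QC |

All are config keys (`defaultConfig()` / `loadConfig()`), so a YAML file
reproduces a full analysis.

# Problem sizes and runtime

The test suite validates on 256 × 256 × 64 phantoms for the full-chain
recovery checks, 192 × 192 × 48 phantoms with 50 tubes per session for
the statistical power check (8 replicate pairs), 2000 replicates for
type-I-error calibration at n = m = 20, and ≤ 32³ volumes for the exact
brute-force oracle comparisons. These sizes were chosen so the complete
suite runs in a few minutes on one CPU while keeping every geometric
regime of the default spacing represented.

# Known limitations

- Skeleton-based lengths on strongly oblique vessels retain a residual
  percent-level staircase bias after smoothing.
- The segment definition (maximal branch-free path) assigns branch-point
  voxels to multiple segments' endpoints; diameters are not corrected for
  junction bulging, and no exclusion zone is applied near branch points.
- The baseline Otsu segmenter is a classical stand-in for QC and phantom
  work, not a competitor to learned segmenters on real data.
- Nearest-vessel distances use plaque centroids, not plaque surfaces, so
  they overestimate surface-to-vessel proximity for large plaques.
- Inter-session registration is out of scope; fields of view are assumed
  re-identified at acquisition time via vascular landmarks.
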