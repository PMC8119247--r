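---
title: "Color-coded overview images from postmortem CT: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-coded overview images from postmortem CT: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmctviz)
```

## The model

A postmortem CT volume is a scalar field of Hounsfield units (HU): air
≈ −1000, soft tissue ≈ 0–60, trabecular/cortical bone roughly 300–1500,
and metal far above 2000. `pmctviz` compresses such a volume into one 2D
color image per view in which three HU regimes are made legible at a
glance: bones and faint soft tissue in gray, radiopaque foreign material
in saturated red, and intracorporeal gas in saturated blue.

The central difficulty is that gas inside the body and air outside the
body are radiologically identical. A plain minimum intensity projection
(minIP) would be dominated by the surrounding room air and body bag. The
algorithm therefore first classifies *exterior* air by connectivity, not
by intensity alone: seeded region growing absorbs every voxel with
HU ≤ −200 reachable from the eight volume corners. Corners of a
thorax/abdomen scan are always outside the body, so the grown region is
exactly the ambient air plus anything air-connected to it, while gas
pockets sealed inside the body are untouched. The *selective* minIP then
takes each ray's minimum over unflagged voxels only, so it sees nothing
but intracorporeal gas (rays that contain only flagged voxels receive the
sentinel +3071 HU, the top of the conventional 12-bit CT range, which no
threshold can mistake for gas).

Compositing applies three per-pixel rules, in order:

1. gray = window(0.7 · MIP + 0.3 · average), where MIP is the maximum
   intensity projection and "average" is the unmasked ray mean;
2. MIP strictly above +2800 HU ⇒ pure red;
3. selective minIP strictly below −220 HU ⇒ pure blue.

Because the rules are sequential, blue overwrites red on the rare ray that
contains both metal and gas. Threshold values themselves never fire — both
comparisons are strict — and every output pixel is of exactly one of three
classes: gray (r = g = b), pure red, pure blue.

## Parameters

All constants live in `pmct_config()`:

| parameter | default | meaning |
|---|---|---|
| `air_threshold_hu` | −200 HU | inclusive ceiling for "air" during region growing |
| `red_threshold_hu` | +2800 HU | strict MIP threshold for radiopaque material |
| `blue_threshold_hu` | −220 HU | strict minIP threshold for gas |
| `mip_weight`, `avg_weight` | 0.7, 0.3 | gray blend; must sum to 1 |
| `window_center_hu`, `window_width_hu` | 500, 1000 HU | display window of the blend |
| `table_seeds_enabled` | TRUE | seed the hollow scanner-table interior |
| `connectivity` | "face" | region-growing neighbourhood |
| `table_shell_max_mm` | 25 mm | thickest accepted table shell |

The −200/−220 pair is deliberately asymmetric: the growing threshold is
slightly more permissive than the blue threshold, so partial-volume voxels
at the body surface (between −220 and −200 HU) are removed as exterior air
rather than rendered as a thin false-gas rim.

## Design choices

**Connectivity.** Face (6-)connectivity is the default because it is the
conservative choice: a diagonal single-voxel gap in the body surface does
not let the exterior region leak into the body, as 26-connectivity would.
Both are available and both are verified against an independent
brute-force flood fill in the test suite.

**Threshold inclusivity.** The region-growing comparison is inclusive
(≤ −200): a voxel at exactly −200 HU is absorbed, one at −199 never is.
The color rules are strict (> 2800, < −220): the threshold values
themselves never color a pixel.

**Table seeding.** Hollow, air-filled scanner tables are not connected to
the corner-reachable background, so their interior would otherwise render
as false gas. Per axial slice, the detector locates the posterior-most
structure, scans anteriorly through it, and — if it crosses a thin
above-threshold run — takes the first below-threshold voxel beyond it as a
candidate seed; the scan repeats inward from the left and right borders at
that height. Two guards make this concrete realization robust, since the
scan geometry alone cannot distinguish a table from a body wall:

* a run is only accepted as "table shell" if at most `table_shell_max_mm`
  (default 25 mm) thick — table shells are a few millimetres of
  plastic/carbon, body walls are several centimetres, so scans through a
  table-less slice emit nothing rather than seeding through the body into
  enclosed gas;
* a candidate already inside the corner-grown exterior mask is discarded:
  table seeds exist precisely for air the corners cannot reach, so the gap
  between a solid table top and the body never seeds (and a solid table
  yields an empty seed list).

Seeding can only grow the exterior mask (a superset relation the tests
assert), and disabling it is a no-op on volumes without a table.

**View geometry.** The canonical frame is x: subject-left→right,
y: anterior→posterior, z: inferior→superior; both loaders reorient into it
(NIfTI via qform/sform, DICOM via ImageOrientationPatient, axis-aligned
orientations only). The anterior–posterior view collapses y (image axes
z × x), the lateral view collapses x (z × y), both rendered head-up.

**Blend-then-window.** The gray rule blends MIP and average in HU and
windows the blended value once. The alternative — windowing the average
first and mixing display levels with HU — would make the gray scale a
mixture of units; blending in HU keeps the mapping monotone in both inputs
and invertible (a property the acceptance sweeps exploit to recover the
weights from outputs alone). Display levels are rounded half-up.

**Anisotropy.** CT reconstructions typically have coarser slice spacing
than in-plane spacing. The three projections are linearly resampled to
square pixels (the smaller of the two spacings) *before* thresholding and
compositing, so color boundaries are decided on interpolated HU rather
than interpolated colors; an already-isotropic image passes through
unchanged, and interpolation never leaves the input value range.

**Degenerate inputs.** Seeds landing on above-threshold voxels are
silently skipped (a corner could in principle touch table material); an
entirely empty seed list produces an empty mask with a warning; rays fully
inside the exterior mask get the +3071 sentinel.

## The phantom generator

`generate_phantom()` renders a parametric scene with exact ground truth:
background air (−1000 HU), an ellipsoidal soft-tissue body (40 HU)
enclosing gas pockets (−800 HU), bone structures (1200 HU) and metal
(3200 HU), plus an optional arc-shaped table below the body whose interior
is hollow (watertight, air-filled) or solid. Optional Gaussian noise is
clipped at 3σ and the spec is rejected unless 3σ stays below the distance
of every painted class to its nearest decision threshold, so ground-truth
masks remain exact under noise. `standard_fixtures()` bundles the study
conditions used throughout the tests (44 × 52 × 28 voxels, isotropic 1 mm
— small enough that the full suite and the behavioral sweeps complete in
about a minute each):

* `body_with_gas` / `body_with_metal` — the blue and red pixel sets must
  equal the projected footprints of the ground-truth masks *exactly*;
* `body_with_hollow_table` / `body_with_solid_table` — a discriminating
  pair for the table detector;
* `open_airway` — a gas region connected to the outside through a channel.
  Corner-seeded growing absorbs it, so it is *not* rendered blue. This is
  the method's known failure mode for ventilated airways (an open oral
  cavity removes the lungs from the gas visualization), reproduced here as
  a regression rather than "fixed", because it is a property of the
  algorithm.

What the phantoms do not emulate: anatomical texture, beam-hardening and
metal streak artifacts, partial-volume gradients at tissue interfaces, and
noise that crosses decision thresholds. Passing tests therefore establish
the correctness of the segmentation/projection/compositing machinery and
its thresholds, not clinical image quality on real PMCT data.

## Known limitations

* Exterior removal is purely connectivity-based: any gas path to the
  outside (open airways, penetrating wounds) removes the connected gas
  from the visualization.
* Superimposition can hide findings (an air-filled lung over a gas
  embolism; an implant over a fracture); the MIP layer gives anatomical
  context, not a fracture diagnosis.
* Orthographic projection discards depth: object position must be read
  from the two perpendicular views together.
* The DICOM reader supports uncompressed little-endian single-frame CT
  with axis-aligned orientations; enhanced multi-frame objects, compressed
  transfer syntaxes and gantry tilt are out of scope.
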