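---
title: "Quantifying insulin polarisation at the capillary interface: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying insulin polarisation at the capillary interface: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletpol)
```

## The problem

Pancreatic beta cells inside islets of Langerhans are polarised with respect
to the islet vasculature: each cell contacts a capillary over a restricted
patch of its surface, insulin granule fusion is targeted there, and insulin
content itself appears enriched at that vascular face. Testing this on
confocal image volumes of intact islets requires, per optical plane:
identifying beta cells (semantic masks), separating touching cells into
instances, finding each cell's vascular and avascular faces against a
laminin channel (laminin marks the capillary basement membrane), and
comparing insulin intensity sampled towards the cell centre from both faces.
`isletpol` implements that pipeline, plus a synthetic image generator with
known ground truth so every stage can be validated quantitatively without
access to the original microscope data.

## Pipeline model

Given a binary beta-cell mask for a plane (ground truth, supplied
externally, or predicted by the built-in U-Net):

1. **Instance segmentation** (`instance_segment`). Marker-controlled
   watershed on the negated Euclidean distance transform of the mask,
   smoothed with a Gaussian (`gaussian_sigma`, default 2 px). Markers are
   local maxima of the smoothed distance map separated by at least
   `min_marker_distance` (default 10 px), detected per connected component
   so no component is left unmarked. Flooding is 4-connected and restricted
   to the mask; ties are resolved by a fixed scan order, so results are
   deterministic. Masks of disjoint convex cells reduce exactly to
   connected-component labelling. Instances with area not exceeding
   `min_area_px` (default 490 px) are discarded; the threshold is strict
   ("greater than"), operates in resized-image pixels, and corresponds to
   the area of a cell of roughly 4.5 um radius at 0.3604 um/px.

2. **Face detection** (`boundary_region`, `find_face_points`). Each cell's
   boundary region is its Euclidean-disc dilation (radius
   `boundary_width_px`, default 10 px) minus the cell itself. A
   `laminin_window_px` x `laminin_window_px` window (odd, default 9) is
   scanned over every position whose centre lies in the region; the window
   mean uses all in-bounds window pixels (membership in the region is
   required of the centre only, and the region may overlap neighbouring
   cells — no exclusion rule is applied). The vascular point is the argmax,
   the avascular point the argmin; ties go to the first position in
   row-major scan order (horizontal before vertical), so constant laminin
   deterministically yields the first region pixel.

3. **Line scans** (`scan_line`, `insulin_along_line`). Bresenham lines are
   drawn from each face point to the cell centre, defined as the rounded
   unweighted centroid of the mask pixels (the reference method says only
   "cell centre"; the centroid is the simplest deterministic choice).
   Rounding is half-up, not banker's, for platform stability. At every line
   coordinate inside the cell, insulin is averaged over an
   `insulin_window_px` square window (default 10) intersected with the cell
   mask and the image; the maximum such mean is the face's insulin value.
   An even window must be anchored somehow: we use offsets -w/2 .. w/2-1
   around the coordinate in both axes. If no line coordinate falls inside
   the cell (possible for strongly concave cells whose centroid lies
   outside), the record is flagged `NA`, excluded from statistics and
   counted in the log — never fabricated.

4. **Statistics** (`paired_t_test`, `summarize_faces`). Cells with both
   face values are compared by a paired two-tailed Student's t test
   computed in closed form (`t = mean(d) / (sd(d)/sqrt(n))`, sample SD,
   `df = n - 1`). Records with any missing face value are dropped listwise.
   Reports give means with both SEM and SD: reference conventions for the
   "±" dispersion are ambiguous (stated SEM, magnitudes suggesting SD), so
   both are always emitted. No multiple-testing correction is applied to
   the two planned tests. `manual_linescan` reproduces the manual protocol
   (face-to-face line, mean over the first `round(depth_um /
   pixel_size_um)` in-cell pixels from each face, default 2 um) as a
   cross-check of the automated readings.

## The U-Net

No deep-learning framework is part of the package's dependency set, so the
segmentation model is a self-contained compact U-Net: two-convolution
blocks (3x3, ReLU) per level, 2x2 max-pooling down `depth` levels (default
2), nearest-neighbour upsampling with skip concatenation back up, and a
1x1 sigmoid head; convolutions are evaluated as im2col + GEMM in compiled
code, with hand-derived backpropagation verified against finite differences
in the test suite. Training minimises per-pixel binary cross-entropy with
Adam, single-image batches, early stopping on validation loss (patience
`early_stop_patience`, best weights restored; fractional mean stopping
epochs across folds are expected and reported). Everything is seeded and
single-threaded, so training is bit-reproducible on CPU. Binarisation uses
`threshold = 0.5` by default (no reference value is stated).
`cross_validate_unet` partitions by image — never by pixel — into K folds
(default 10), trains on K-1 with the held-out fold as the early-stopping
monitor, pools confusion counts over all pixels of the held-out images for
that fold's metrics (precision/recall/F1 with zero-denominator ratios
defined as 0), and averages across folds; optional pre-training on a second
dataset provides the transfer-learning arm. This is a desk-scale
evaluation harness: reproducing published full-scale metrics would require
the original image corpus and is out of scope.

## What the synthetic generator emulates

`simulate_islet` draws, from one seed:

- **Capillaries**: correlated random-walk centrelines (reflecting at the
  frame so network length is stable across seeds; later walks branch off
  earlier ones, keeping the network connected), dilated to half-width
  `capillary_width_px` (default 5 px ~ 3.6 um vessel width). At the
  512 px default this occupies roughly 5-15% of the frame.
- **Cells**: seeded region growing from sites just outside the vessel wall,
  on a distance-to-seed metric roughened by a smooth random field —
  irregular, close-packed, non-overlapping cells. A cell may press against
  the vessel only over a compact arc near its seed (`contact_halfwidth_px`,
  default 5 px); elsewhere a thin extracellular gap remains, mirroring how
  beta cells contact vessels over restricted patches. The ground-truth
  contact point is the boundary pixel nearest the capillary, ties resolved
  towards the middle of the contact arc. Default geometry is 28 cells of
  radius 25 ± 2.5 px at 512 px. This makes typical instances ~1000 px in
  area — the operational size range implied by a 490 px minimum-area filter
  — rather than scaling strictly from the printed voxel pitch, whose
  combination with that filter is internally inconsistent anyway.
- **Laminin**: a dim lumen (`laminin_tube`, 60) with a basement-membrane
  sheath on the outer rim (`laminin_sheath`, +30) and, crucially, an
  interface enhancement (`laminin_interface_boost`, +140) forming a band
  straddling the tube edge wherever a cell presses against it — basement
  membrane is brightest where endothelium meets the endocrine cell. Without
  this structure a uniform tube makes the 9x9 windowed argmax tie along the
  vessel and face detection becomes a tie-break lottery; with it, the
  argmax clusters at the true contact.
- **Insulin**: inside cell c, `base_insulin * (1 + (r - 1) * g(p))` where
  `r = enrichment_ratio` and g is 1 at the contact point, holds a cortical
  plateau out to `enrichment_plateau` x (contact-to-centroid distance,
  default 0.55), and decays by a cosine ramp to 0 at `enrichment_extent` x
  that distance (default 0.68). g is exactly 1 at the contact and exactly 0
  at the cell pixel farthest from it, so with noise off the
  contact-to-farthest intensity ratio is exactly r, and r = 1 renders each
  cell uniform. A *cortical* profile, rather than a linear decay across the
  whole cell, was a deliberate design decision: the biology being emulated
  is granule docking at the vascular membrane, and a whole-cell linear
  gradient would leave substantial enrichment at the cell centre — which
  the avascular scan line samples — so the parameter r would no longer mean
  what its name says (the vascular:avascular ratio as measured at the
  faces). The plateau/extent defaults are set by the sampling geometry:
  the plateau must cover the 10 px insulin window at the contact, and the
  enrichment must vanish at least half a window before the centroid so the
  centre-end windows of either scan line read baseline.
- **Granules and noise**: granule speckles are small discs that *multiply*
  local insulin by `1 + granule_contrast` (default 0.25, expected
  `granule_density` = 20 per cell). Multiplicative speckle preserves the
  programmed face ratio in expectation; additive speckle would add an
  unpolarised floor and bias the recovered ratio towards 1. Additive
  Gaussian noise (`noise_sd`, default 6 grey levels) is applied to all
  channels before 8-bit clipping; nuclei are blurred discs at the
  centroids.

What the generator does **not** emulate: point-spread-function optics,
z-correlated structure (planes are independent draws), alpha/delta cells,
non-beta tissue, autofluorescence gradients, or realistic 3-D vessel
topology. Passing tests therefore demonstrate that the *pipeline* measures
what it claims on images with known truth of matched statistical structure
— not that any particular biological dataset will behave identically.

## Numerical choices and degenerate inputs

- Coordinates are 0-free: (row, col) with origin top-left, 1-based in R.
- 4-connectivity throughout instance handling prevents corner-touching
  cells from merging; boundary pixels are those with a differing
  4-neighbour or an image edge.
- Window means at image borders average the in-bounds pixels only.
- Empty masks: `instance_segment` returns zero instances;
  `boundary_region`, `cell_centre` and `find_face_points` raise errors
  (there is nothing meaningful to return).
- All differences `a - b` identically zero make the paired t statistic
  undefined; a degenerate flag is returned instead of a number.
- Zero-width capillaries produce an empty laminin mask; cell contacts then
  refer to the stored centreline.
- All randomness flows from explicit seeds; repeated runs are
  bit-identical, including U-Net training.

## Problem sizes used in the tests

The test-suite simulations use the package's own reduced conditions chosen
to keep the suite complete and deterministic: full 512 px islets where the
spatial structure matters (ratio recovery pooled to >= 200 cells across
seeds; face localisation on noise-free islets), 256 px / 8-cell islets for
the 100-replicate type-I study, 160 px disc maps for watershed counting,
and 32 simulated 128 px planes with a depth-2, 8-filter U-Net for the
training experiment. Oracle-equivalence properties run on hundreds of small
random inputs against independent brute-force implementations written as
direct restatements of each definition.

## Known limitations

- The watershed under-segments long chains of cells sharing flat contacts
  (no distance valley exists); this is inherent to distance-based
  watershed, and the instance-count validation therefore uses the classic
  disc geometries the transform is defined for.
- The avascular point under flat background laminin is tie-broken by scan
  order; with noise it is effectively a random low-laminin direction. Its
  scan line can approach the contact cortex in unlucky geometries, which
  mildly inflates avascular readings — an inherent property of the
  max-along-line estimator rather than of this implementation.
- The measured vascular:avascular ratio is attenuated relative to the
  programmed r (window averaging over the enrichment edge, granule
  max-selection on the flat side); with the default geometry the
  attenuation is a few percent of r, which is why recovery is validated to
  within ±10%.
- Volumes store the z-anisotropy (z/xy, 3.7 at the 0.0902/0.3362 um voxel)
  as sidecar metadata rather than resampling voxels: lossless, and how 3-D
  viewers consume it.
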