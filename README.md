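# isletpol

Automated quantification of insulin polarisation in pancreatic beta cells
imaged within intact islets of Langerhans.

Beta cells contact islet capillaries at a restricted *vascular face*, and
insulin — both its secretion machinery and its content — is enriched there.
Given multi-channel confocal planes (insulin + laminin, where laminin marks
the capillary basement membrane) and binary beta-cell masks, `isletpol`
answers, per cell: *how much more insulin sits at the vascular face than at
the avascular face?*

The pipeline, per plane:

1. **Instance segmentation** — marker-controlled watershed on the smoothed,
   negated Euclidean distance transform of the semantic mask (markers =
   local distance maxima ≥ 10 px apart, 4-connected flooding), followed by
   a strict minimum-area filter (> 490 px).
2. **Face detection** — a 10 px morphological boundary region (disc
   dilation minus mask) around each cell; a 9 × 9 window scanned over the
   region identifies the laminin argmax (vascular face) and argmin
   (avascular face), ties resolved in row-major scan order.
3. **Line-scan quantification** — Bresenham lines from each face point to
   the cell centroid; at every in-cell line coordinate, insulin is averaged
   over a 10 × 10 window intersected with the cell, and the maximum mean is
   the face's value:
   `I_face = max over line coords p in cell of mean{ insulin(q) : q in W(p) ∩ cell }`.
4. **Paired statistics** — per-cell vascular vs avascular values compared
   with a paired two-tailed Student's t test,
   `t = mean(d) / (sd(d)/√n)`, df = n − 1; reports give mean ± SEM (and SD).

A compact, self-contained U-Net (compiled im2col/GEMM convolutions,
hand-derived backpropagation, Adam, early stopping; bit-reproducible on
CPU) provides desk-scale semantic segmentation with image-wise K-fold
cross-validation; the pipeline equally accepts externally produced masks.
A seeded synthetic islet generator — connected capillary networks,
irregular close-packed cells with known contact points, programmed
vascular enrichment ratio `r`, granule speckle and noise — supplies ground
truth for end-to-end validation. See the methods vignette
(`vignettes/insulin-polarity-methods.Rmd`) for the model and every design
decision.

## Worked example

```r
library(isletpol)

islet   <- simulate_islet(synth_params(seed = 1))   # 512 px plane, r = 1.4
lm      <- filter_instances(instance_segment(semantic_mask(islet)), 490)
records <- analyse_islet(list(islet$channels), list(lm), islet_id = "demo")
summarize_faces(records)
```

```
face report over 26 complete cell records (0 dropped)
  laminin  vascular   118.26 +/- 0.47 (SEM; SD 2.41)
  laminin avascular     3.75 +/- 0.08 (SEM; SD 0.39)
  insulin  vascular   145.29 +/- 1.69 (SEM; SD 8.60)
  insulin avascular   108.64 +/- 0.91 (SEM; SD 4.66)
  laminin: paired t test: t = 239.6521, df = 25, p = 1.52e-43, mean diff = 114.5052 (n = 26)
  insulin: paired t test: t = 20.0545, df = 25, p = 6.34e-17, mean diff = 36.6483 (n = 26)
```

Reading the output: 28 cells were simulated with a programmed vascular :
avascular enrichment of 1.4; the watershed recovered 26 instances above the
area filter. The detected vascular faces carry ~30× the avascular laminin
(they sit on the capillary wall), and insulin at the vascular face exceeds
the avascular face by ~37 grey levels (ratio ≈ 1.34 — the estimator is
mildly attenuated relative to the programmed 1.4, see the vignette), with
the paired test overwhelmingly rejecting symmetric insulin.

`run_pipeline()` (or the `inst/scripts/isletpol` wrapper) chains
simulate → masks (ground truth or trained U-Net) → instances → polarity →
statistics from one YAML config and seed, writing channel PNGs, label
maps, a records CSV, a JSON report, a stacked mask volume (multi-page
TIFF, z-anisotropy 3.7 in a sidecar) and a manifest.

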