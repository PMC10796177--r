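---
title: "Whole-slide renal biopsy analysis with renalwsi: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide renal biopsy analysis with renalwsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalwsi)
```

## The problem

Histological evaluation of paediatric renal biopsies hinges on finding and
measuring kidney structures on whole-slide images (WSIs): counting glomeruli,
deciding whether each shows a crescent (the hallmark of rapidly progressive
glomerulonephritis), counting nucleated cells in the glomerular tuft, and
scoring mesangial or endocapillary hypercellularity on PAS-stained sections.
WSIs are far too large for a segmentation model to ingest whole, so practical
pipelines tile the slide into overlapping patches, run a detector per patch,
and fuse the patch detections back into one whole-slide result.

`renalwsi` re-implements that pipeline as a reusable, fully testable
framework. The deep networks that fill the per-patch detection slots in a
production system are deliberately out of scope; they are represented by a
pluggable backend interface plus deterministic reference backends that are
exact on the package's own synthetic slides. What this package lets you test
is everything *around* the model: the tiling geometry, the coordinate
algebra, the suppression and integration logic, the morphometry, and the
evaluation statistics.

## Coordinate conventions

Everything shares one convention: 0-based pixel coordinates, x rightward,
y downward, boxes `(x, y, w, h)` covering the half-open region
`[x, x+w) x [y, y+h)`. Pixel `(r, c)` occupies the unit cell
`[c, c+1) x [r, r+1)`; rasterisation includes a pixel iff its centre lies
inside the polygon (even-odd rule). Half-open boxes make intersection-
over-union and the exact 4x magnification relation (10x at 1 um/px, 40x at
0.25 um/px) free of off-by-one ambiguity. Mask re-vectorisation traces the
component boundary along pixel cracks, so the traced ring's shoelace area
equals the pixel count exactly for simply connected masks.

## The pipeline

1. **Foreground gating.** The slide is converted to Rec. 601 luminance and
   thresholded by Otsu's criterion (exhaustive maximisation of between-class
   variance over the 256 cut points; ties broken by the midpoint of the tied
   range). Tissue is darker than glass, so foreground is luminance strictly
   below the threshold. A single-valued histogram yields an empty foreground.
2. **Tiling.** Sliding windows of side `n` (700 px at 10x, 2800 px at 40x)
   with stride `n/2` are placed on the lattice `{0, n/2, n, ...}`; the last
   origin per axis is clamped so the final window ends exactly at the slide
   edge. Windows containing no foreground pixel are dropped; every foreground
   pixel remains covered. Patches are padded (right/bottom, value 255) to
   `n x n` and rescaled bilinearly to the model input side: 768 px at 10x,
   1024 px at 40x. The pad-then-rescale record (`patch_transform`) makes the
   mapping exactly invertible; round trips are well below the 0.5 px
   contract.
3. **Per-patch segmentation.** A backend maps a patch to scored instances in
   patch space. Detections below a score threshold (default 0.05 — whether a
   pre-suppression cut is applied is not fixed by the protocol, so it is a
   configurable parameter) are discarded.
4. **Whole-slide fusion.** Instances are mapped back to slide coordinates and
   deduplicated by greedy non-maximum suppression at IoU 0.5, *per class*:
   a glomerulus detection must never suppress the tuft nested inside it.
   Ties in score are broken by larger area, then input order; suppression
   uses strict `IoU > 0.5`, so ties at exactly the threshold survive.
   Suppressed duplicates are discarded whole (no mask averaging).
5. **Crescent classification.** Each detected glomerulus is cropped from the
   H&E 10x slide by its bounding box, padded to a square (preserving aspect
   ratio) and resized to 224 x 224. The classifier returns the crescentic
   probability; the label is crescentic iff the score reaches 0.5.
6. **Nuclei integration.** Nuclei detected on H&E 40x tiles are suppressed at
   40x, rescaled by exactly 1/4 into 10x space, and each nucleus is assigned
   to the structure containing its centroid — glomerular tuft first, then
   smaller structures before larger; nuclei contained by nothing are kept and
   flagged interstitial.
7. **PAS transfer and hypercellularity.** Detected 10x glomerulus boxes are
   multiplied by 4, cropped from the PAS 40x slide, and the hypercellularity
   backend detects mesangial / endocapillary regions inside them. A
   glomerulus is flagged mesangial-hypercellular iff at least four nucleus
   centroids fall in one detected mesangial region, and
   endocapillary-hypercellular iff at least two fall in one endocapillary
   region — the operational definitions used at annotation time.

The nuclei suppression threshold question (apply NMS before or after the 1/4
rescale) is not settled by the protocol; suppression happens at 40x before
rescaling, and the threshold is configurable. Likewise, the PAS route reuses
the glomerulus boxes detected on H&E 10x: the package's data model carries no
separate PAS 10x raster, and synthetic pairs are perfectly registered, so the
x4 box transfer is the whole content of that step.

## Evaluation and statistics

Detection quality is scored with PASCAL VOC 2010 11-point interpolated
average precision at IoU 0.5 (AP50). Matching is greedy in descending score;
each detection takes the unmatched ground truth of highest IoU when that IoU
reaches 0.5, otherwise it is a false positive; duplicates of an already
matched object are false positives. The interpolated precision at recall `r`
is the maximum precision over all attained recalls `>= r`, and 0 at recall
levels never attained (the maximum over an empty set is otherwise undefined;
this is the standard VOC convention and makes the curve monotone). mAP is the
unweighted mean over classes. True negatives are undefined for detection, so
specificity is only computed where the caller supplies classification-level
confusion counts.

Agreement between pipeline and reference glomerulus counts uses the Spearman
rank correlation (mean ranks under ties, two-sided p from the t
approximation with n-2 df) and the intraclass correlation in its two-way,
absolute-agreement, single-measurement form (ICC(A,1)), with the F-based 95%
confidence interval using Satterthwaite degrees of freedom. Group
comparisons (e.g. glomerular area across the age bins 1-5, 6-10, 11-15,
16-20 years) use one-way ANOVA followed by Tukey HSD on the studentized
range, with the Tukey-Kramer standard error because cohort bins are
unbalanced. All tests are two-sided at alpha = 0.05. The annotation triage
rule selects the images in the lowest 20% of per-image mAP (ceiling of
`0.2 N`, ties at the cut included).

## The synthetic world

`generate_slide_pair()` renders a paired pseudo-histology triple — H&E 10x,
H&E 40x, PAS 40x — with exhaustive ground truth. It is a *stated world*, not
a photorealistic simulator:

* Geometry is drawn once on the 40x integer grid in multiples of 4 and
  divided by 4 for 10x, so every cross-magnification coordinate relation is
  exact by construction.
* Each class has a fixed, documented colour signature (`he_palette()`,
  `pas_palette()`), pairwise separated by at least ~50 in max-channel
  distance so that bilinear resampling blends never match the wrong class
  rule. Tissue is a single irregular polygon darker than the white glass
  background, which is what makes the Otsu gate meaningful.
* Glomeruli are disks: Bowman's capsule ring (thickness `max(4, 0.12 r)`),
  Bowman's space, and an inner tuft of radius `0.62 r`. Default radii span
  30-60 px at 10x (60-120 um diameters, the paediatric range). Crescents are
  partial annuli spanning ~110-200 degrees of Bowman's space, so the
  reference classifier's annulus fraction separates the classes with a wide
  margin.
* Tubules and arteries share one wall colour and differ only in wall
  thickness fraction (distal 0.15, proximal 0.33, artery 0.55 of the outer
  radius); the reference backend separates them at measured fractions 0.24
  and 0.45, mirroring how a morphology-based rule would.
* Nuclei are small dark ellipses planted collision-free inside tufts (8-18
  per tuft by default; the achieved count is recorded and is the ground
  truth). Hypercellular glomeruli receive a mesangial region planted with
  4-5 nuclei and/or an endocapillary region with 2-3, exactly bracketing the
  >= 4 / >= 2 flag thresholds.
* The same configuration and seed always reproduce byte-identical rasters.

Because detection is exact on this world by design, a green end-to-end test
establishes that the *plumbing* — tiling, inverse transforms,
cross-magnification scaling, per-class NMS, integration, counting — is
correct. It does not establish anything about segmenting real stained
tissue: no staining variation, texture, blur, artefacts, overlapping or
out-of-focus structures are simulated. That is exactly the part the
pluggable backend interface leaves to trained models.

`generate_cohort()` ties slide metadata (age, sex, diagnosis) to the
generator; scaling the glomerulus radius range by age group (defaults 1.0 /
1.2 / 1.4 / 1.6 across the four bins) plants a monotone area-by-age effect
that the ANOVA harness must recover, and an optional per-slide glomerulus
count sampler provides the variance needed by the count-agreement harness.

## Numerical choices and edge cases

* Bilinear resampling uses the half-pixel-centre convention and preserves
  constants; patch pixels are rounded (not truncated) back to 8-bit.
* The reference backends drop components touching the patch border: with
  stride `n/2`, any object of diameter at most `n/2` is fully contained in
  some tile, so border drops cost no recall after fusion but prevent partial
  duplicates whose IoU with the full detection could fall below the
  suppression threshold.
* Rule-backend scores are the fraction of component pixels matching the
  class colour rule (1.0 by construction), so NMS tie-breaking (area, then
  input order) is what determines survivors among exact duplicates —
  deterministic by design.
* Roundness is the isoperimetric ratio `4 pi A / P^2` and "length" is the
  major axis of the second-moment ellipse (computed in closed form from the
  polygon); the source protocol names both features without formulas, so
  these definitions are package choices, documented here.
* `icc_absolute_single()` returns a degenerate CI of (1, 1) when both the
  rater and error mean squares vanish (identical columns); the F-based
  interval is undefined there.
* Otsu on a single-valued histogram returns that value, giving an empty
  foreground (strict `<` comparison).
* Perimeters of *detected* instances are crack-boundary (staircase) lengths:
  a digital disk traced along pixel edges has perimeter about `8 r`, not
  `2 pi r`, so its isoperimetric roundness sits near `pi^2/16 ~ 0.62` even
  though the region is circular. Roundness is therefore comparable between
  detected instances but not directly against analytic polygons; smooth
  ground-truth polygons (and the ideal-disk test case) are unaffected.
* Raster files are written as binary PPM (P6): lossless, base-R readable,
  and codec-free; annotations travel as GeoJSON FeatureCollections
  (QuPath-compatible), tables as CSV.

## Known limitations

* The reference backends are tied to the synthetic palette; on real slides
  they detect nothing useful. Plug trained models in through
  `wsi_backend()`.
* Ground-truth nuclei exist only at 40x (they are not resolvable at 10x),
  so nucleus instances have no 10x ground-truth twin; the pipeline's 1/4
  rescale is tested against the exact scaling law instead.
* The morphometric feature set is the documented core (area, perimeter,
  roundness, major axis, equivalent diameter, per-class counts and nuclei
  counts); the long tail of pathomorphological features in the source
  supplementary material is not enumerated in its main text and is out of
  scope.
* Crescent subtyping (cellular vs fibrous) and podocyte identification are
  out of scope.
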