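---
title: "Unsupervised whole-heart CT segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised whole-heart CT segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartseg)
```

## The model

`heartseg` segments the whole heart (four chambers, coronary region,
descending aorta) from axial chest CT without training data. Its premise
is topological: in a mid-thoracic axial slice, air surrounds the body,
the dark lungs flank the heart, and the bright vertebral body sits below
it. Each structure is isolated by a data-derived intensity threshold and
a morphological operation that converts intensity evidence into a
geometric mask:

1. A per-volume range normalization maps HU to grayscale 0–255 (the
   darkest voxel to 0, the brightest to 255, rounding half-up).
2. **Foreground**: 1-D K-Means with $k=2$ splits air from tissue. The
   threshold is the *mean* of the two centroids — a mean-thresholding
   criterion: it lands between the cluster centers regardless of where
   the histogram mass sits. The strict mask $X > \tau$ is opened twice
   (removing 1-pixel table-streak lines) and convex-hulled so the body,
   including any dark cavities, is a single filled region.
3. **Lungs**: within the body hull, everything below the same $\tau$ is
   lung; closing twice fills intrapulmonary vessel holes. The convex
   hull of both lungs necessarily covers the mediastinum between them.
4. **Intermediate heart mask**: lung hull minus lungs.
5. **Spine**: within the intermediate mask (zeros injected elsewhere),
   $k=3$ K-Means separates injected background, soft tissue and bone;
   the threshold is the *maximum* centroid, so only confidently-bone
   pixels survive. After opening and closing, the spine's top anchor
   $(x_0, y_0)$ and centroid row $y_c$ seed a downward fill: everything
   below the spine top is suppressed.
6. **Heart**: intermediate mask minus the spine fill.
7. **Cross-slice refinement**: processing cranial to caudal, the last
   slice whose lung-mask top row did not sink is remembered; once the
   lungs recede (top row moves down, the liver appears), the remembered
   hull is OR-ed into the current one so the heart stays covered.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_slices` | 56 | slices | cranial slices covering the heart in the target acquisition (2.5 mm spacing ≈ 14 cm) |
| k (foreground / spine) | 2 / 3 | clusters | air-vs-tissue; background/soft-tissue/bone |
| `n_iter` | 2 | — | opening/closing applied twice at each stage |
| `selem` | `cross3` | — | 4-connected 3×3 element, the common library default; `square3` available |
| `n_init` | 10 | restarts | K-Means++ restarts per clustering |
| `seed` | 0 | — | seeds the K-Means draws; every run is reproducible |
| `spine_hull_side` | `both` | — | side(s) of $x_0$ filled below the spine top (see below) |
| `r_min`, `p_min` | 0.8, 0.5 | recall/precision | image-classification surrogate thresholds |

## Numerical and design choices

**Normalization scope.** The grayscale extremes are taken per volume,
not per slice, so thresholds are comparable along the slice axis of one
acquisition. A fixed window (`window = c(-1000, 1000)`) is available for
cross-volume comparability. Quantization rounds half-up; a constant
volume is a degenerate-input error.

**Histogram clustering.** Intensities occupy 256 discrete levels, so
K-Means runs on the histogram — mathematically identical to clustering
the 262,144 pixels of a slice, at O(256·k) per iteration. Lloyd
iterations with k-means++ seeding and 10 restarts follow library
convention, but restarted Lloyd provably can miss the optimum on
multimodal histograms; we observed misses at this problem size. Because
the optimal 1-D clustering is contiguous in the sorted values, the exact
optimum is computable by dynamic programming in O(k·256²), and
`kmeans_1d()` polishes the restart winner with it. The returned inertia
is therefore the global minimum of the objective, and the "inertia
matches exhaustive enumeration" property holds by construction, not by
luck. Convergence tolerance 1e-4 on centroid movement; empty clusters
re-seed at the farthest occupied bin.

**Exact silhouette.** How the original evaluation sampled pixels for
silhouette scoring is not stated anywhere we could rely on; we compute
the exact mean silhouette from the histogram via bin-pair distances
(O(256²)), which equals the brute-force definition on the expanded pixel
multiset (property-tested against a literal O(n²) oracle). Pixels in
single-member clusters score 0 by the standard convention. The spine
clustering is scored over mediastinal pixels only (`roi` scope): the
injected zeros outside the region would otherwise dominate the score;
since the background cluster then has no members, scoring proceeds over
the populated clusters. Both choices are configurable and are
comparability caveats against externally reported silhouette values.

**Convex hull.** The hull is the exact set of pixels whose centers lie
in the convex polygon of the foreground pixel centers (scanline-filled,
verified against an independent point-in-polygon oracle; row/column runs
are contiguous; idempotent; extensive). The iterative hit-or-miss
approximation with four directional elements is retained behind
`hull_mode = "hitmiss"` for fidelity experiments, since published
variants of this construction yield a quadrant-limited approximate hull.

**Spine fill direction.** The literal fill condition (`y > y0` and
`x < x0`) suppresses only the left side below the spine top, leaving
right-of-spine tissue in the heart mask. The default fills both sides,
which matches the intended symmetric suppression; `left`/`right`
reproduce one-sided variants.

**Anchors.** Region anchors use the largest 8-connected component,
1-based `(x = column, y = row)` coordinates with the origin at the top
left; centroid ties round half-to-even (base R `round()`).

**Strict inequalities.** All three thresholds use strict comparisons;
pixels exactly at a threshold fall on the excluded side.

**Image-level evaluation.** The original assessment was human visual
inspection. The automated surrogate classifies a slice TP when pixel
recall of the target is at least `r_min` and precision at least `p_min`,
FN when recall fails, FP otherwise. Recall is scored against the mode's
own target (whole heart, or chambers only), but precision is scored
against the whole heart in both modes: "spill" means leakage into
non-heart tissue, and the coronary margin is heart. Scoring four-chamber
precision against the chambers alone would mark every correct whole-heart
segmentation FP in four-chamber mode, inverting the expected dominance
of four-chamber over whole-heart rates. The thresholds are stated
configuration, not claimed equivalents of human judgment.

## The phantom: what it emulates, and what it does not

`generate_phantom()` draws a 512×512×56 (tests: 128 or 96) int16 HU
volume: elliptical body with fat interior and a muscle annulus; two
lungs, each an upper lobe drawn as a rounded-rectangular superellipse
whose medial border hugs the cardiac silhouette plus a lower lobe
reaching down beside the vertebral column; a rounded cardiac envelope
(chambers at +35 HU inside a pericardial/coronary margin) with the
descending aorta left of midline; a vertebral body with a vertical
density gradient (bright superior endplate, 1000→400 HU, mean 700);
Gaussian HU noise (sd 10) inside the body; and 1-pixel streak lines near
the bottom of the frame outside the body. From `liver_onset_slice`
(default 31) the lung lobes shrink linearly and sink towards the lung
base while liver tissue (+60 HU, deliberately heart-like) fills the
vacated right lung bed.

Geometric proportions were chosen once, on anatomical grounds: the
heart fills the cardiac mediastinum, so the lungs' medial borders run a
few pixels from the pericardium, their tops level with the cardiac
silhouette, and the vertebral body starts at the heart's lower border.
The spine's brightest-at-top gradient mirrors cortical endplate density
and makes the detected bone mask's top row coincide with the anatomical
spine top.

What passing phantom tests shows: the cascade's mask algebra, threshold
criteria, refinement logic and evaluation arithmetic are correct, and
the pipeline recovers a heart-shaped target under the stated topology
with realistic HU contrasts and noise. What it does not show: robustness
to real anatomical variability — irregular lung borders, partial-volume
effects, beam hardening, metal artifacts, pathology — or to acquisitions
that violate the topology (e.g. pleural effusion filling a lung base).
Quantities measured on the phantom are not comparable to clinical-data
results.

## Problem sizes used in validation

Unit tests run on 96×96 phantoms of 1–3 slices; the end-to-end
validation uses 128×128×56 phantoms, ten seeds for the heart-recovery
property (mean pixel IoU over the lungs-surrounded slices 1–30 ≥ 0.8)
and three seeds for the refinement comparison on liver slices. These
sizes keep the full suite around a minute while exercising every stage
at realistic aspect ratios; a 512×512 slice segments in well under a
second, so full-resolution use is routine.

## Known limitations

- Liver tissue is intensity-indistinguishable from myocardium; caudal
  slices over-segment once the liver enters the lung bed. The
  refinement keeps the heart covered but does not remove the liver —
  by design, this matches the method's documented failure mode.
- The descending aorta below the spine-top row is suppressed by the
  spine fill; whole-heart recall on caudal slices loses the DA.
- Single-frame little-endian DICOM only (explicit or implicit VR);
  multi-frame/enhanced DICOM and resampling are out of scope.
- The refinement assumes cranial-to-caudal slice order; volumes sorted
  the other way must be reversed first.
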