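---
title: "Quantifying adherens junction discontinuity in endothelial monolayers"
author: "ajdisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adherens junction discontinuity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ajdisc)
```

## The measurement problem

Endothelial cells form a barrier whose integrity depends on adherens
junctions: cadherin-5 (VE-cadherin) concentrated in a continuous band
along every cell–cell border. Inflammatory stimuli such as TNF fragment
this band; the junctional signal becomes punctate and interrupted, and
the barrier leaks. Immunofluorescence images of a stained monolayer make
the phenotype visible, but "discontinuous junctions" needs a number
before groups can be compared.

The statistic this package computes is the **ratio of junction
discontinuity**: for one cell, the percentage of the pixels of its
closed outline at which a fixed-threshold binary junction mask is zero,

$$\mathrm{ratio}\,(\%) \;=\; 100 \cdot
  \frac{\#\{\,p \in \text{outline} : \mathrm{mask}(p) = 0\,\}}
       {\#\{\,p \in \text{outline}\,\}}.$$

An intact cell scores near 0; a cell whose junction band has vanished
scores 100.

## The two-track operator chain

A single raw 8-bit cadherin-5 channel feeds two tracks that share only
the first step, rolling-ball background subtraction (radius 20 px):

* **Geometry track** (where is each cell?): Gaussian blur at
  $\sigma = 2$ px applied twice, a fixed 3×3 sharpen
  (centre 12, neighbours −1, divisor 4), Huang fuzzy auto-threshold,
  binarization (foreground strictly above the threshold), binary 3×3
  dilation twice, automated bridging of broken junction walls, and
  topology-preserving skeletonization. Interior faces of the skeleton
  are traced as closed 8-connected pixel loops — one per cell — and 25
  outlines per image are sampled uniformly at random (seeded).
* **Scoring track** (is signal present?): the background-subtracted raw
  channel is binarized with the fixed inclusive range 21–255 on the
  8-bit scale. No blur, no sharpening, no dilation: the mask keeps the
  real gaps that the geometry track deliberately repairs.

The split matters. The geometry track must produce *closed* outlines
even for badly disrupted cells, so it smooths and bridges aggressively;
the scoring track must *not* hallucinate continuity, so it applies only
the fixed threshold. Each outline is then read off the scoring mask with
a plot-profile (one sample per outline pixel, in path order) and
converted to the per-cell percentage. Pooled per-cell ratios are
compared across conditions with the Kruskal–Wallis rank test.

All parameters are surfaced in `pipeline_config()`; the defaults (20 px
ball, $\sigma = 2$ twice, dilation twice, 21–255, 25 cells/image) are
the published recipe and should only be changed to explore sensitivity.

## What replaces the interactive steps

The original protocol includes manual line-tool corrections before
skeletonization. A reusable pipeline cannot contain interactive editing,
so `close_gaps()` automates it: at every open end of the mask's
centerline it measures the physical width of the break (distance from
the end's own wall to mask pixels that are only reachable the long way
around) and draws a straight bridge when that width is at most
`bridge_max` (default 10 px), iterating to a fixed point. Forks and
stubs on intact walls are geodesically near their surroundings and are
left alone. Breaks wider than `bridge_max` stay open, and the two
adjacent cells then merge into one face that is discarded — mirroring
what an operator would refuse to invent.

Skeletonization is distance-ordered homotopic thinning: simple pixels
(whose removal provably preserves foreground 8-connectivity and
background 4-connectivity) are deleted in increasing order of distance
to the background. Spurs shorter than 5 px and enclosed holes smaller
than 64 px² are removed as artifacts of thresholding thick walls; both
cutoffs are far below any plausible cell-scale structure.

## Border policy

A cell whose outline is interrupted by the image frame is not a complete
cell and is never scored. Faces touching the frame are flagged, as are
faces whose traced path comes within 5 px of it: where two junction
walls converge just inside the frame, their dilated images can fuse and
seal a border cell's face, and the proximity rule catches exactly this
case.

## The synthetic monolayer generator

No reference micrographs are distributed with the protocol, so the
package ships a generator (`generate_monolayer()`) whose output has
known ground truth:

* **Tessellation** — `n_cells` seed points sampled uniformly with a
  minimum-separation rejection rule, followed by two Lloyd relaxation
  steps. Confluent monolayers are close to centroidal Voronoi
  tessellations: compact, convex cells with vertex angles near 120°.
  Without relaxation, raw Voronoi cells often carry needle-thin acute
  corners that no diffraction-limited image could resolve — an artifact
  of the sampling, not a feature of the biology. Tessellations in which
  a cell merely grazes the frame (inside the 8 px border zone but with
  under 12 px of frame contact) are resampled, because such a cell's
  border status is ambiguous at the pixel level for the truth and the
  tracing alike.
* **Junction signal** — the shared borders are rasterized
  (`junction_mask`) and rendered as a ridge with Gaussian cross-section
  (default $\sigma = 1.5$ px, peak 180), matching the bright, narrow
  junctional band of a stained monolayer.
* **Gaps (the ground truth)** — contiguous runs (Poisson-distributed
  length, mean 12 px) are deleted along border polylines until a
  requested fraction of the junction length is gone. Runs, not scattered
  pixels: the disease phenotype is run-like interruption of the band,
  and run-like gaps survive Gaussian rendering. The realized fraction is
  recorded per image and per cell; a safety rule keeps any single cell
  from losing its entire border below a requested fraction of 1.
* **Nuisance structure** — a smooth low-frequency illumination field
  (amplitude 40 by default, exercising the rolling-ball step) and
  additive Gaussian noise ($\sigma = 8$), both inside an 8-bit budget
  chosen so the peak cannot saturate by construction.

Defaults (512×512 px, 60 cells) give roughly 25–30 complete interior
cells per field, matching the published design of 25 scored cells per
image. Everything is reproducible bit-for-bit from `rng_seed`; panels
derive per-replicate seeds deterministically from a base seed.

What the generator does **not** emulate: nuclei or any second channel,
optics (PSF, depth of field), photobleaching, autofluorescence texture,
or cell-size heterogeneity beyond Voronoi variation. Passing the
recovery tests therefore shows the operator chain measures what it
claims on images with this structure — it does not certify performance
on any particular microscope's output.

## Numerical choices

* Images are 8-bit end to end, re-quantized after every operator, as in
  the original tool chain; the fixed 21–255 threshold only makes sense
  on that scale. Inputs that are not 8-bit are rejected unless min–max
  rescaling is explicitly requested (and then logged).
* Huang's threshold minimizes the membership-entropy fuzziness over the
  256-bin histogram; exact ties break toward the smaller threshold.
  Binarization is strictly-greater-than, fixed for bit-reproducibility.
* The rolling ball is the classic non-flat ball (grayscale opening with
  a spherical structuring element of the stated pixel radius), which is
  reproducible from the printed radius alone.
* Gaussian blur is separable with reflective boundaries; two passes at
  $\sigma$ match one pass at $\sigma\sqrt{2}$ within one intensity unit.
* Quartile summaries use linear interpolation (R type 7); box plots
  whisker at min/max, matching the reported summaries.
* Coordinates are 1-based (row, column) pixel centres; outline length is
  the count of path pixels.

## Validation strategy and what the tests show

The `validate_recovery()` loop closes the circle: panels at true gap
fractions 0, 0.1, 0.2 and 0.4 (eight images each, 25 cells per image)
are generated, run through the full pipeline from TIFF files, and the
per-image mean measured ratio is compared with the realized truth.
Condition means increase strictly with the truth, and the per-image
Spearman correlation exceeds 0.9. The measured ratio *understates* the
true gap fraction by roughly half, for two reasons that the vignette
reader should expect rather than be surprised by: the Gaussian tails of
the remaining junction bleed ≥21-intensity signal a few pixels into each
gap, and cells whose walls were too destroyed to close are excluded by
the border/closure rules (a mild survivor bias shared with the manual
protocol). The statistic is therefore a monotone index of junction
disruption, not an unbiased estimator of gap length.

The Kruskal–Wallis wrapper is checked against hand rank arithmetic, its
empirical size at $\alpha = 0.05$ over 1000 null simulations, and the
exact permutation null for groups of up to eight values. For the latter
the chi-squared p is compared with the permutation **mid-p** (half the
probability atom at the observed H): at these sample sizes the
permutation distribution is discrete with atoms larger than 0.1, the
inclusive p is systematically larger than any continuous approximation,
and the mid-p is the standard comparator; agreement is within 0.05
(observed ≲ 0.035).

Test problem sizes — 256–320 px module fixtures and one full-scale
512 px, 32-image panel — were chosen so the whole suite completes in a
few minutes on one core while still exercising the pipeline at the
published design size.

## Known limitations

* **Vertex resolution.** Blur at $\sigma = 2$ twice plus double dilation
  makes binarized walls ~8–11 px thick; where three walls meet, the
  fused blob displaces the skeleton branch point from the true vertex by
  up to about half the wall thickness. Extracted outlines agree with
  truth boundaries to 1–2 px along walls but can deviate 3–5 px at
  vertices. This is a property of the published operator chain, not of
  the implementation; distance-ordered thinning and Lloyd-relaxed
  tessellations were adopted specifically to keep it near the low end.
* **Survivor bias at high disruption.** Above a true gap fraction of
  ~0.4, an increasing share of cells cannot be closed even by bridging
  and drops out of scoring; group comparisons remain valid as rank
  comparisons but per-cell means compress.
* **Cells are the unit of analysis**, pooled across images as in the
  published design. Cells within an image share acquisition conditions;
  the per-image summary (`summarize_by_image()`) is exported alongside,
  and a mixed-effects treatment is deliberately out of scope.
* Physical calibration (µm per pixel) is the user's responsibility; all
  lengths are in pixels.
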