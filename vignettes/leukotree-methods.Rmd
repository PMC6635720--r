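---
title: "Staging myeloid cells from smear images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging myeloid cells from smear images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukotree)
```

## The problem

In chronic myeloid leukemia (CML) the marrow floods the blood with
myeloid-series white cells at every maturation stage: myeloblast (MB),
promyelocyte (PM), myelocyte (M), metamyelocyte (MM), band (B) and
segmented neutrophil (N). Staging each white cell on a stained smear is
routine but slow microscope work, and the visual cues are largely
morphometric: as the cell matures its nucleus shrinks relative to the
cell (the N:C ratio falls from above 80 % in myeloblasts to 20–30 % in
neutrophils), the nucleus deforms from a smooth round/oval shape through
a kidney-shaped notch and a curved band to separate lobes, and the
cytoplasm colour shifts from basophilic blue to pink. `leukotree`
implements an automated version of this reading: segmentation of cell
and nucleus masks, six morphometric features, and a fixed-threshold
decision tree over them. Because no public image set accompanies the
method, the package also contains a seeded synthetic-scene generator
that renders class-conditioned cells with ground-truth masks, so the
entire chain is testable end to end.

## Segmentation model

Whole cells are found in the yellow (Y) channel of the naive CMYK
transform: stained leukocytes are blue/purple dominated and carry
essentially no yellow, so they are the darkest structures there, while
the faintly warm background and the orange-pink red cells stay bright.
The channel is contrast-enhanced as the mean of a linear stretch `L` and
a 256-bin histogram equalization `H` (rescaled to [0, 1]); the exact
combination of the two operators is not fixed by the method's
description, and the arithmetic mean was chosen because it preserves
both operators' contributions and stays bounded (`sum-clipped`,
`L-only` and `H-only` are available through `seg_options()`). A 3×3
minimum filter applied three times suppresses bright speckle, Otsu's
threshold (dark side) yields the cell mask, and opening, closing and
hole filling regularise it.

Nuclei are extracted inside the cell regions from the a* channel of
CIELAB, where the magenta chromatin stain stands out from any cytoplasm
colour. The channel is smoothed with a Gaussian of σ = 33 px, min–max
normalised over the cell region, Otsu-thresholded there (bright side —
nuclei have *high* a*), regularised by a 10-px-diameter closing and a
2-px-diameter opening, hole-filled, and filtered by area: components
below 25 % of the largest one are treated as stain debris. The 25 %
fraction interprets a qualitative "smaller than a nucleus" rule for
which no absolute cutoff exists; it is configurable
(`area_fraction`). Touching cells are separated by a watershed of the
Euclidean distance transform with h-maxima suppression (h = 5 px), the
standard marker-controlled realisation of gradient-based watershed
splitting; the implementation is `EBImage::watershed()` over
`EBImage::distmap()`. Finally the cytoplasm mask is the set difference
of cell and nucleus masks, pixel-exactly.

All length parameters above are quoted at the reference acquisition
geometry (2592 × 3872 px at ×1000 magnification) and scale linearly
with the `scale` option; areas scale quadratically.

## The six features

For each cell record with a non-empty nucleus, `extract_features()`
computes:

* **Num** — nucleus lobe count, the number of 8-connected components of
  the nucleus mask.
* **AoN** — nucleus area in pixels (all lobes).
* **ACoC** — mean cytoplasm colour on the CIELAB b* (blue–yellow) axis.
  The feature is stored with a +128 offset, i.e. on the 8-bit-encoded
  b* axis with neutral at 128 that common imaging toolchains use. The
  tree's colour thresholds (24, 27, 30) are only attainable by
  blue-series cytoplasm on this encoded axis — on the signed axis a
  basophilic cytoplasm can never exceed +27 — so the encoded axis is
  the one reading under which all three printed cut points are
  reachable. The offset is configurable (`acoc_offset`).
* **T1** — minimum nucleus thickness, from the bottleneck search below.
* **T2** — minimum convex thickness: the width of the convex hull of
  the nucleus (smallest distance between parallel supporting lines),
  computed by rotating calipers over the hull edges.
* **HD** — Hausdorff distance between the nucleus border and the cell
  border, `max(h(U,V), h(V,U))` with `h(U,V) = max_u min_v ||u − v||`.
  The symmetric form was chosen (the directed variant is available via
  `hd_directed`); for a nucleus inside its cell the two differ only
  when the nucleus is strongly off-centre.
* **P1** — perimeter (border-pixel count) of the smaller nucleus part
  after a validated bottleneck split; 0 when no split happens.

Thickness convention: distances between boundary pixel centres are
converted to material thickness by adding one pixel (a w-pixel-wide
rectangle spans w − 1 between centres). The perimeter convention is the
count of foreground pixels with at least one 4-neighbour in the
background; this matters because the band/neutrophil cut at 475 px is
expressed in it.

### The modified bottleneck search

The bottleneck of a concave shape is the closest pair of boundary
points that pinches it. Candidates are ordered contour point pairs at
least 10 contour steps apart whose Euclidean distance is less than
0.55× the shorter boundary arc between them; pairs are visited by
increasing distance and the first pair whose straight (Bresenham)
segment contains no background pixel is accepted — the interior test is
the modification that stops the search from picking a pair whose
connecting segment leaves the shape, as happens on horseshoe-like
nuclei. The 0.55 pinch ratio separates genuine waists from convex
curvature: on a circle the chord/arc ratio never falls below 2/π ≈
0.64, while a kidney notch of classifier-relevant depth pinches at
about 0.4–0.5. Convex nuclei therefore produce no candidate pair; for
them T1 falls back to T2 so that T1/T2 = 1 exactly, which is what the
tree's "regular nucleus" branch expects.

A split along the accepted segment is then screened by the area rule:
it is accepted when the bigger part exceeds 3.8× the smaller **and**
the summed area exceeds 74 000 px² (both at reference scale, both
configurable). On rejection the smaller part is removed — it is treated
as an attached artifact — and the search repeats on the remainder; the
loop terminates because every retry removes a part. The direction of
the 3.8× comparison is implemented exactly as stated
(`big > 3.8 × small` accepts), although the surrounding artifact-removal
narrative could be read the other way; `split_comparator` flips it if
needed. A consequence worth knowing: a band nucleus split into two
similar halves fails the ratio clause, so a band's P1 is only non-zero
when its bottleneck sits well off-centre — the synthetic band generator
therefore places a thinner head segment with a marked waist at about
one fifth of the band length, and neutrophil-sized nuclei (area below
74 000 px²) can never yield an accepted split, which is consistent with
the tree using P1 only to separate bands from neutrophils.

## The decision tree

With `r` = T1/T2, `q` = T1/HD:

| Stage | Condition | Outcome |
|---|---|---|
| 1 | Num > 1 | **N** |
| 2 | r > 0.92 | go to 5 |
| 3–4 | 0.86 < r ≤ 0.92 and ACoC < 30 | notch ignored: r := 1, T2 stands in for T1, go to 5 |
| 5 | q > 3.7 | **MB** |
| 6–8 | 2.1 < q ≤ 3.7 | ACoC < 24 → **MB**; ACoC > 27 → **PM**; else **MB\|PM** |
| 9–10 | q ≤ 2.1 | AoN < 110000 → **M**; AoN > 115000 → **PM**; else **PM\|M** |
| 11 | 0.53 ≤ r | **MM** |
| 12 | r < 0.1 | **N** |
| 13 | 0.1 ≤ r < 0.53 | P1 > 475 → **B**; else **N** |

Boundary semantics are not specified by the stage descriptions
("upper than", "lower than"); the package resolves exact equality by
strict comparisons that route borderline cells toward the later, more
ambiguous outcome: r = 0.92 goes to the irregular branch, ACoC of
exactly 24 or 27 gives MB|PM, AoN of exactly 110 000 or 115 000 gives
PM|M, and P1 = 475 stays N. The overlap classes exist precisely to
absorb borderline cells, which makes this the conservative convention.
Two further interpretation points: cells with 0.86 < r ≤ 0.92 whose
cytoplasm is *not* basophilic (ACoC ≥ 30) fall through to the irregular
branch, and stage 11's metamyelocyte range is treated as extending up
to the regular cut (0.53 ≤ r ≤ 0.92) so that such cells have a leaf —
otherwise the tree would be partial. Totality over the whole feature
space, including every printed boundary value, is fuzz-tested. A cell
missing a feature on a branch that reads it gets the distinct
`unclassifiable` outcome rather than a forced guess.

The T2-for-T1 substitution in stages 3–4 is implemented as a rewrite of
the feature vector (effective `q` becomes `q/r`), recorded in the
returned trace, because the substituted T1 is reused by all later
stages.

## The synthetic generator

`synthetic_cell_spec()` and `render_cell()` draw one cell per scene on
a slightly warm background with red-cell-like distractor disks and
additive Gaussian noise (default σ = 2 intensity units, a mild
sensor-noise level; the renders are otherwise clean). Geometry is
calibrated to the reference resolution so the tree's absolute pixel
thresholds apply as printed: cell radii span roughly 185–355 px and
nucleus areas roughly 8 000–140 000 px² across classes. Per class:

* **MB** — near-concentric nucleus disk, N:C sampled in 0.82–0.88.
  With a compact cytoplasm rim, T1/HD lands far above 3.7.
* **PM / M** — nucleus disk plus a tapering cytoplasmic pseudopod
  (wedge) that stretches the cell border away from the nucleus. The
  pseudopod is the geometric device that realises intermediate and low
  T1/HD at high N:C: with plain concentric disks, an N:C above 0.6
  forces the cell border close to the nucleus everywhere and T1/HD
  cannot drop below ≈ 4. Tail lengths of 0.40 and 0.78 cell radii give
  PM T1/HD ≈ 2.6–3.4 and M ≈ 1.4–1.9; M cell sizes keep AoN below
  110 000 px². The wedge tapers monotonically so the distance transform
  has no separate maximum in it and the watershed never cuts it off.
* **MM** — kidney: a disk with a deep, blunt circular bite
  (bite radius 0.75 R, centre at 0.95–1.05 R), tips rounded by a
  morphological opening. Bite depth sets T1/T2 ≈ 0.70–0.81; blunt
  ~110° arms avoid spurious tip pinches.
* **B** — curved band along a circular arc (sweep 3.5–3.9 rad) with a
  thinner head segment (55 % thickness) and a distinct waist at 25 % of
  the length. The head is the intended split: it holds ~14 % of the
  area (ratio clause ≈ 6× > 3.8) yet, being elongated, its perimeter
  clears the 475 px band cut with margin.
* **N** — 2–4 separate lobes on a ring (5 possible via `lobes=`; it is
  not sampled by default because at the mandated σ = 33 a* smoothing,
  five tightly packed lobes merge after thresholding). Lobe gaps are
  kept ≥ 85 px so blurred lobes stay separate. N nuclei are small
  enough that the split rule's total-area clause always rejects, so
  P1 = 0 on every neutrophil path.

Achieved N:C is enforced by construction (the dependent radius is
derived from the rasterised partner mask), so ground-truth ratios sit
within ~0.01 of target. The cytoplasm palette steps from deep blue (MB)
through lighter blues (PM, M) to pinkish lavender (MM/B/N); saturation
of the blues is deliberately moderate because a fully saturated blue
has a* ≈ +78, which would outshine the nucleus in the very channel the
nucleus segmentation relies on. On the encoded b* axis all cytoplasm
colours exceed 27, so PM is separated from MB by geometry plus colour
as the tree intends.

The generator does **not** emulate chromatin texture, granules,
nucleoli, staining variability, illumination gradients, cell clumping
or out-of-focus blur, and each scene holds a single white cell. Passing
end-to-end tests therefore demonstrate that the implementation realises
the intended geometry–feature–tree chain under the stated phenomenology,
not that the method reaches its published headline agreement on real
smears — that claim depends on the authors' private 1730-cell dataset.

## Evaluation module

`confusion()` builds one-vs-rest TP/FP/FN/TN counts per class;
`metrics()` reports per-class sensitivity, specificity and accuracy in
percent with unweighted macro averages, marking zero-denominator ratios
as undefined and excluding them (with a warning) from the averages.
The observed agreement p0 is reported as `overall_accuracy`; note that
for more than two classes the *mean* of one-vs-rest accuracies is not
p0 (it equals 1 − 2(1 − p0)/K), so the "agreement = accuracy" identity
is deliberately exposed through the overall figure, not the macro one.
`cohen_kappa()` implements κ = (p0 − pe)/(1 − pe) with pe from the
raters' marginal frequencies, returning κ = 1 by convention when both
raters assign a single identical label (pe = 1). When two expert label
sets are supplied, their consensus is the cells on which they agree;
disagreements are excluded and counted, which is the conservative
reading of a "joint" reference.

## Numerical choices and degenerate inputs

* Otsu runs on an explicit 256-bin histogram so it can be restricted to
  region samples (the nucleus threshold is computed from within-cell
  pixels only); a constant sample is an error, and a constant image
  passes through contrast enhancement unchanged with a warning.
* Contours come from `EBImage::ocontour()`; contours longer than 2 600
  points are subsampled before the all-pairs bottleneck search, and at
  most 600 candidate segments are interior-tested before the search
  concludes no usable pinch exists.
* The split cut line is one pixel thick but dilated by one pixel so it
  actually disconnects 8-connected parts; slivers beyond the two
  largest parts are attached to the nearer part.
* Empty cytoplasm (nucleus fills the cell) flags ACoC as missing; the
  record is still classified on branches that never read colour.
* Label masks are written as 16-bit TIFF (the available PNG writer
  quantizes to 8 bits).
* Images are 8-bit per channel, 0-based row-major coordinates,
  half-open bounding boxes.

## Problem sizes used by the test suite

The package's own tests render end-to-end datasets at `scale = 0.4`
(40 cells per class, 240 scenes) and smaller unit fixtures at scales
0.25–0.35; scaling the geometry and every absolute threshold together
leaves all dimensionless quantities invariant, and 0.4 keeps each
scene's heavy operations (σ-scaled Gaussian smoothing, contour
all-pairs work) comfortably small while individual features stay many
pixels wide. The acceptance script's myeloblast N:C batch renders at
the full reference scale.

## Known limitations

* The pinch criterion is a geometric proxy; extremely elongated convex
  shapes (axis ratio beyond ~2) do generate a candidate pair, but their
  accepted "waist" equals the minor width so T1/T2 still evaluates to 1
  within a pixel.
* T1 is computed on the largest lobe of a multi-lobed nucleus; the tree
  short-circuits on Num > 1, so this only affects reported raw values.
* The printed split-validation rule makes P1 unreliable for bands whose
  bottleneck is central; real band nuclei with symmetric waists would
  need the comparator flipped (`split_comparator = "small_over_big"`).
* Headline real-data performance is out of reach without the original
  dataset; the synthetic recovery rate is a property of the generator's
  stated phenomenology.
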