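---
title: "Splitting overlapping cells: the model behind ClumpSplit"
author: "ClumpSplit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting overlapping cells: the model behind ClumpSplit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClumpSplit)
```

## The problem

Counting nuclei in H&E-stained tumour tissue — the basis of cellular
quantitative grading in small round blue cell tumours such as
neuroblastoma — fails wherever two or more cells touch or overlap in the
2-D section and merge into a single connected *clump* in the segmented
binary mask. Intensity cues are unreliable at H&E overlap borders, so
ClumpSplit works purely on binary morphology: it decides which connected
components are clumps, and cuts each clump into its constituent cells so
the count, not the shapes, comes out right.

The input is any binary foreground mask (nonzero = cellular), typically
512×512 at 20× magnification where nuclei have radii of roughly 8–14
pixels. Upstream colour segmentation is out of scope; `binarizeHE()` is
only a convenience thresholder.

## Stage 1 — discriminating clumps from single cells

After preprocessing (hole filling, opening, closing), each 8-connected
component *i* is measured:

* area $A_i$ (pixel count), and the image mean $\bar A$;
* diameter equality $DE_i = d_{minor}/d_{major} \in (0,1]$, where
  $d_{major}$ is the longest straight line inside the object (maximum
  Feret diameter of the pixel set) and $d_{minor}$ is the object width
  (minimum Feret diameter). A disc scores ≈ 1, elongated clumps score low.
  Feret diameters are measured between pixel centres plus one pixel of
  footprint; the width definition reproduces the intuitive answers for a
  square (≈ $1/\sqrt2$, diagonal vs. side) and a 2:1 rectangle (≈ 0.5);
* concavity $CX_i = (A^{CH}_i - A_i)/A^{CH}_i$, the normalized convex-hull
  deficit, with $\overline{CX}$ its image mean.

Three sequential rules label each object: $A_i > \bar A$ makes it
*potentially overlapping* (PO), else *potentially single* (PS); a PO
object with $DE_i > \gamma$ is a round *single cell* (SC); a surviving PO
object with $CX_i > \overline{CX}$ is an *overlapping cell* (OC). All
comparisons are strict, so ties fall to the non-overlapping side: a
missed split costs one count, an invented split corrupts two cells.
Residual PO objects (large, elongated, but not unusually concave) are
counted as single and keep the PO label for auditing.

The area rule presumes within-image size homogeneity — appropriate for
neuroblast populations, which are morphologically monomorphic. The
`gamma = 0.9` default is the threshold the method was designed around.

## Stage 2 — splitting each clump

For every OC object with region $R$ and filled convex hull $CH(R)$, the
deficit $CH(R)\setminus R$ decomposes into 8-connected components; those
of at least `minSTArea` pixels are the *splitting triangles* (STs), the
markers of concave pinches between overlapped cells. Each ST's boundary
splits into the **chord** — its intersection with the hull's inner
boundary (exact, since both live on one raster) — and the **arc**, which
follows the cell contour.

All distances are the chessboard (Chebyshev) metric
$\max(|\Delta r|, |\Delta c|)$, grown from seed sets
(`chebyshevField()`); it is cheap and, for this morphology, serves as
well as Euclidean distance. The *initial splitting point* of an ST is the
arc pixel set farthest from the chord (`criticalPoint()`); points are
paired nearest-first and the geodesic corridor between a pair — the
pixels on which the sum of the two point fields attains its minimum — is
thinned to a one-pixel cut path with the two-subcycle thinning operator
(neighbours indexed from the east counter-clockwise), endpoints
protected. Clearing the cuts fragments the clump; fragments are counted,
never restored ("the aim is counting, not shape recovery").

### Refinements the raster forces

Working at nucleus radii of 8–14 px puts several steps at the resolution
limit; the following choices are part of the package's design and were
made from the geometry, with synthetic scenes as verification:

* **Dominance threshold** (`minSTArea = 4`). The analytic pinch deficit of
  two discs of radius $r$ at centre distance $f\,r$ is
  $r^2\!\left(f - \tfrac f2\sqrt{1-f^2/4} - \arcsin(f/2)\right)$ per side
  — only 5–10 px for $r \le 10,\ f \le 1.4$. Noise slivers of rasterized
  round contours measure ≤ 2–3 px, so 4 px separates signal from noise.
  Pinches whose deficit rasterizes below that (e.g. $r=8, f=1.2$, deficit
  ≈ 1 px) are below the sampling limit and cannot be split at this scale.
* **Closing radius 1** (opening stays at radius 2). A radius-2 closing
  fills the very 2–3 px deficits stage 2 detects; radius 1 repairs
  single-pixel contour defects without erasing them.
* **Counterpart pairing.** A splitting line joins a concave region to its
  *counterpart* — the dent on the opposite flank. Each point carries the
  local inward normal (foreground minus background centroid in a 5-px
  disc); pairs whose normals agree in sign are inadmissible. Because the
  chessboard unit ball is a square, an across-pinch pair and a diagonal
  pair can tie up to rasterization (±2 px); ties resolve toward the most
  mutually facing pair.
* **Merged STs.** When the hull's tangent edge clears the middle cell of
  a bent chain, adjacent concave regions merge into one ST. Its arc then
  carries one chord-distance peak per pinch; peaks are separated by
  topological persistence (prominence ≥ 2 px), and peaks whose
  neighbourhood is mostly background — convex bumps of the merged arc,
  not concavities — are discarded.
* **Lone points.** A cell with a single concave region (or a leftover
  after pairing) is routed to the cell contour: candidate pixels exclude
  the point's own arc, are filtered to a cone about the concavity
  direction, and the most aligned nearest candidate becomes the virtual
  partner. Plain nearest-in-chessboard instead picks corner nicks.
* **Cut realization.** A width-1 8-connected path does not disconnect an
  8-connected foreground at diagonal steps, and a rasterized endpoint can
  stop one pixel shy of the contour. `applyCuts()` therefore clears one
  bridge pixel per diagonal step and prolongs each cut end along its own
  direction until background is reached. The `CutPath` object itself
  remains a clean one-pixel route from one splitting point to the other.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `gamma` | 0.9 | – | diameter-equality threshold; above it a PO object is a round single cell |
| `openRadius` | 2 | px | disc element of the opening; removes sub-element artifacts |
| `closeRadius` | 1 | px | disc element of the closing; repairs 1-px defects, preserves pinches |
| `minSTArea` | 4 | px | dominance threshold for concave deficit regions |
| `edgeMethod` | boundary | – | ST edge extraction; `gradient` (Sobel) is equivalent on binary regions |
| `clipCorridor` | FALSE | – | intersect corridors with the cell before thinning |
| `globalFields` | FALSE | – | grow DA/DC on the full image from pooled label matrices instead of per ST |
| `iouThreshold` | 0.5 | – | overlap needed to score a predicted cell as a true positive |

## The synthetic scene generator

`makeScene()` emulates what the splitter sees after segmentation of one
20× field: round single cells and chains of 2–5 partially overlapping
round-to-elliptical cells (axis ratio capped at 2:1), no contact between
distinct entities (≥ 3 px separation), optional isolated noise pixels and
single-pixel holes injected *after* ground truth capture so preprocessing
is tested against a known clean reference. Cell radii are drawn around a
per-scene base radius (±10 % jitter, base uniform on 8–14 px): one field
of a monomorphic tumour shows nearly uniform nuclei, and the stage-1 area
rule presumes that homogeneity. Clump centre distances are 1.1–1.6 radii
— overlapping but not engulfing.

What the generator does **not** emulate: staining variation and
segmentation errors other than salt noise and pin holes; irregular,
non-convex nucleus outlines; clusters overlapping in more than pairwise
chains; variable magnification. Passing the synthetic suite therefore
demonstrates the geometry engine and the counting logic under controlled
morphology, not robustness to real staining artifacts — on real slides
the quality of the upstream segmentation dominates.

## Worked example

```{r example}
scn <- makeScene(shape = c(256, 256), nSingle = 6, nClump = 2, seed = 3)
df <- suppressWarnings(runCount(scn))
df[, c("n_objects", "n_clumps", "n_cuts", "count_pred", "count_true",
       "precision", "recall", "fmeasure")]
```

The two clumps are labelled OC, each is cut once per pinch, and the
count recovers the ground truth up to pinches below the raster limit.

## Numerical conventions

Coordinates are 1-based (row, col), origin top-left. Foreground
components use 8-connectivity throughout, matching the diagonal-tolerant
chessboard metric. The convex hull is rasterized by keeping every pixel
of the bounding box whose centre lies inside (or on) the polygon of the
object's pixel centres; integer cross products make the test exact, so
hull-area conservation ($|CH| = A + \sum_k|ST_k| + |\text{slivers}|$)
holds exactly, not approximately. Deterministic tie-breaks (lexicographic
by row, then column) make every run reproducible; all randomness lives in
the generator and is seed-controlled.

Degenerate inputs: a single-pixel object has DE defined as 1 (warning); a
convex OC object yields no STs and is counted as one cell; an ST whose
arc or chord rasterizes empty is discarded with a warning; a cell whose
every concave region degenerates is flagged `unsplittable` and counted as
one.

## Problem sizes in the test suite

The unit suite runs on small windows (clump fixtures of 30–80 px,
scenes of 128–384 px). The end-to-end property check uses 100 scenes at
the full 512×512 study conditions (12 singles, 5 clumps of 2–3 cells),
the size at which the whole suite completes in a couple of minutes on a
single core.

## Known limitations

* Pinches whose hull deficit rasterizes below ~4 px (deep overlaps,
  $f \lesssim 1.2$ at $r \lesssim 10$) are undetectable; the affected
  clump is counted as one cell fewer. This mirrors the method's inherent
  blind spot for highly overlapped cells with few contour convexities.
* Splitting assigns pixels by cut geometry only; fragment shapes are not
  biological and are scored by IoU ≥ 0.5 with a centroid fallback.
* Stage 1's area rule degrades if an image mixes widely different cell
  sizes; `gamma` and the concavity rule then carry the discrimination.
* The chessboard metric quantizes distances; all pairing logic treats
  ±2 px as ties for that reason.
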