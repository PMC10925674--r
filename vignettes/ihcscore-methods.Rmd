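---
title: "ihcscore: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ihcscore: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The package scores nuclear DAB staining (e.g.
ki67) in epithelial tissue: it detects nuclei as points inside a user-drawn
region, classifies each into highly stained / low stained / unstained, splits
the region into basal, medial and superior thirds of the epithelium, and
reports counts and positivity per stratum.

## The detection model

### Region-based detector

The region-based chain assumes three things about the image: (1) DAB gives
*nuclear* staining in brown on a pale background with a bluish counterstain;
(2) in CIELAB, stained nuclei are simultaneously dark (low L) and yellow-brown
(high b among tissue pixels), so the product `L·b`, min–max normalized over
the image, places strong stain at the bottom of the scale and background at
the top; (3) nuclei are blob-like, with diameters the user can bracket.

Given that, the chain is: multi-level Otsu on the normalized product image
(three thresholds, four classes over the 256-bin histogram, exhaustive scan
of all ~2.7M ordered triples, lexicographically smallest maximizer for
determinism); binarization *below* the lowest threshold (strict `<`, matching
the convention that only clearly stained pixels seed the next stage); then a
seeded 4-cluster k-means on the Lab pixels. The k-means is deliberately
deterministic: batch updates, squared Euclidean distance, initial centroids
at the mean colours of the binary image's two sides plus their 1/3 and 2/3
interpolants, convergence when every centroid moves less than 1 Lab unit, 20
iterations at most, empty clusters frozen. Because the converged centroids
need not keep their seed order, cluster indices are re-anchored afterwards by
proximity to the seed extremes: the cluster nearest the stained seed is
index 1, nearest the background seed index 0, and of the remaining two the
one nearer index 1 is index 2. Strongly stained regions (cluster 1) are split
with the Euclidean distance transform, normalized to `[0, 255]` and
thresholded at the highest Otsu level of the histogram of its *nonzero*
values — including the background zeros would let the empty class dominate
the statistics on sparse masks. Low/unstained masks (clusters 2, 3) instead
get a 3×3 morphological closing to remove pinholes.

Cells are extracted from any of these masks as the centroids of 8-connected
components (holes filled first; only external contours matter) whose
equivalent-circle diameter `d = 2·sqrt(A/π)` lies strictly between the user's
`d_min` and `d_max`. The equivalent-circle definition is rotation-invariant
and robust for blob-like nuclei.

Degenerate inputs short-circuit: an image whose grey projection has fewer
than four distinct values (e.g. a blank field) returns *no cells* rather than
an error, and a constant-product image normalizes to all zeros.

**A consequence worth knowing:** the distance-transform split thresholds all
strongly stained blobs against a single global level. When strongly stained
nuclei are mostly isolated and vary in size, small nuclei shrink to cores
below a tight `d_min`, so the lower diameter bound should be set permissively
for this channel. The package's own recall test for this channel uses nuclei
of near-uniform size and `d_min = 3` px; in the merged pipeline the edge
detector covers isolated nuclei, which is why the two detectors are
complementary.

### Edge-based detector

Canny filtering on the L plane with derivative-of-Gaussian gradients at
σ = 4 px (single scale), non-maximum suppression over four quantized
directions, hysteresis linking over 8-connected weak edges anchored at strong
pixels. The two hysteresis thresholds are `low_rate` (0.3) and `high_rate`
(0.7) times a reference gradient computed from the image itself.

The choice of reference was a genuinely open design point. Reading the rates
as straight quantiles of the gradient-magnitude distribution fails on images
where structure is sparse: with mostly flat, noisy background the 70th
percentile sits in the noise floor and hysteresis floods the image with
closed noise contours. Reading them as fractions of the *maximum* gradient
fails the other way: weakly contrasted (unstained) nuclei fall below
0.7·max. The package therefore anchors the rates to the Otsu separation
point of the gradient-magnitude distribution (256-bin histogram of the
max-normalized magnitudes, mapped back): it adapts to content density, is
exactly covariant under affine rescaling of the luminance, and degrades
gracefully between the two extremes. Two guards make the degenerate cases
explicit: a constant image (gradient range numerically zero relative to the
luminance range) has no edges, and when the reference does not stand clear of
the noise floor — less than 4× the median gradient magnitude, which a
Rayleigh-distributed pure-noise magnitude essentially never exceeds
(its 99.9th percentile is ≈3.2 medians) — the image is treated as
structureless and no edges are returned.

Closed contours become cells by 3×3 closing, filling fully enclosed
interiors, and dropping connected components that enclose no interior at all
(open arcs, dangling fragments); nested rings resolve to the external contour
only. The same diameter filter applies.

### Merging and the region

Channels are merged in fixed precedence RDA-HIGH, RDA-LOW, RDA-WS, EDA with
greedy suppression: a candidate survives only if it is farther than `d_min`
from every already-kept cell (strict `>`; two points at exactly the minimum
cell diameter are one cell). Greedy is deterministic and `O(n·k)`; it is not
a maximum-cardinality selection, and the collinear triple `0, 0.9·d_min,
1.8·d_min` deliberately keeps points 1 and 3. Merging is idempotent.
Containment in the analysis polygon is even–odd with the boundary counted
inside: a user-drawn outline should not silently drop cells it touches.

## The classifier

Features are the means of the 8-bit L, a, b planes over a square window of
side `max(3, round(d_min))` centred on the rounded cell position, clipped at
image borders. Features are standardized by the training mean and standard
deviation before the RBF kernel — without this the fixed σ grid would be
scale-sensitive — and the constants travel with the model.

Training balances classes under a cap: classes with fewer than 10 labelled
cells are excluded; the cap (default 1,000) is split equally (remainder to
the earlier classes in HIGH, LOW, NONE order); classes short of their quota
contribute everything and the shortfall is redistributed equally among
classes with members to spare. Sampling is without replacement under a fixed
seed. Balancing-then-capping versus capping-then-balancing was an open
choice; quota-then-redistribute was chosen because it keeps the realized
class ratios as close to uniform as the data allow.

The grid is λ = 2^(2i−7), i = 1…10 and σ = 2^(−(i+1)/2), i = −15…0 (i.e.
2⁷ … 2⁻⁰·⁵; the index range of the σ grid is configurable since reasonable
conventions differ). Model selection maximizes the mean Cohen kappa over a
*stratified* 4-fold cross-validation with a fixed seed — plain rotation can
produce folds missing a class at small n, which stratification prevents —
and ties prefer the smaller λ, then the smaller σ (the less complex model,
deterministically). The final model is refit on the whole training set.
Kappa is the standard chance-corrected agreement in percent; a matrix with
chance agreement 1 (a single occupied category) returns 0 by convention.
Models serialize to a portable text file holding the standardization
constants, the winning hyper-parameters and the training table; reading
refits the SVM, which is deterministic, so round trips reproduce identical
predictions without serializing libsvm internals.

## Strata geometry

The minimum enclosing rectangle is the minimum-*area rotated* rectangle
(rotating calipers over convex-hull edges): epithelium bands are generally
oblique in the image, and the sweep construction presumes rectangle sides
aligned with the tissue, not the image axes. The rectangle side nearest the
user's basal point (point-to-segment distance, ties to the lowest index) is
the basal side. `n_lines` sweep lines perpendicular to the basal side are
stationed evenly along it, inset by 1/(10·n_lines) of its length at each end
so end stations still cross the contour transversally; each line's two
contour crossings are split at 1/3 and 2/3 of the chord, and chaining the
crossings and split points yields the three stratum polygons directly. A line
crossing the contour in any number of points other than two (a non-convex
fold) is skipped; if more than 20% of lines are skipped the region is
rejected as not epithelium-like so the user re-draws the ROI — guessing a
chord through a folded contour would silently misassign cells.

`n_lines` defaults to 100: on rectangular, triangular and random convex
fixtures this keeps every band within 1% of a third of the region area and
the three-band union within 2% of the region (0.2% in practice), while the
partition polygons stay small. Chord thirds are measured by Euclidean length
along the chord. Cells are assigned by boundary-inclusive containment tested
basal-first (shared-boundary ties resolve basal-most, matching how
pathologists err toward the basal compartment); a cell falling in a numeric
gap between sampled polygons is assigned to the nearest boundary and counted
in a warning attribute.

## Quantification and evaluation

Counts and percentages are reported per stratum plus a global `all` row;
positivity defaults to HIGH + LOW (stained vs unstained) and can be
restricted to HIGH for a strong-staining definition. Detection evaluation
matches detections to ground truth greedily in increasing distance order,
one-to-one, within radius `d_min`. The reported `Sp` is mathematically the
positive predictive value — point detection has no true negatives — and the
name follows the reporting convention of the quantification protocol this
package implements; the documentation says so explicitly. Ratios with zero
denominators are reported as missing, never coerced to 0 or 100.

## The synthetic generator

Scenes emulate the features the pipeline actually keys on: brown nuclei at
two intensities (dark ≈ RGB (90,60,30), light ≈ (170,130,90)), bluish
unstained nuclei (≈ (150,150,200)) on a pale background (≈ (235,230,238)),
per-pixel Gaussian noise (sd 8), elliptical nuclei (axis ratio 0.8–1, random
orientation — ellipses rather than discs so centroid and diameter code is
exercised off the symmetric case), diameters 14–26 px, and a minimum
centre spacing of 1.2·d_max. The palette keeps the `L·b` ordering the
region detector assumes (strong stain lowest, background highest — verified
by an explicit test). Scenes are bit-identical for a fixed seed. The band
variant places nuclei in known thirds of a rotated rectangular "epithelium"
with centres at least 3 px from the third boundaries, recording the
generating layer.

What the generator does *not* emulate: overlapping/occluding nuclei, chromatic
background staining gradients, tissue texture, out-of-focus blur, or the
~1,000-cell density of real fields. Passing the synthetic end-to-end tests
therefore demonstrates the pipeline's correctness and internal consistency,
not its accuracy on real slides; on real material the detectors are explicitly
designed to be supervised and corrected by an expert before quantification.

## Problem sizes and numeric conventions

Tests and the acceptance script use 512×512 scenes with 30 nuclei (10 per
category), training grids over the full 160-point (λ, σ) lattice at n ≤ 180
features or 30 scene cells, 100 sweep lines, and 20 random 64×64 images for
the threshold-oracle comparison — sizes chosen so the full suite runs in a
few minutes on one CPU while still exercising every code path. Coordinates
are 0-based with pixel centres at integers, origin top-left, y downward;
polygons are open vertex lists closed implicitly; overlay XML is versioned
(`version="1"`) and coordinates serialize with 17 significant digits so write
∘ read is the identity; CSV uses comma separator, "." decimal point, UTF-8,
header row, percentages with 2 decimals. L is rescaled to `[0, 255]` and a, b
offset by +128 and clipped, so the grey projection operates on non-negative
channels; all 8-bit re-encodings round half to even (R's `round`).

## Known limitations

* The region detector's LOW/WS channels depend on the seeded clustering
  carving the intermediate colours into meaningful clusters; on sparse or
  low-variety images one intermediate cluster often absorbs background and
  contributes nothing — the merged pipeline then relies on the edge detector.
* The distance-transform split uses one global threshold; heterogeneously
  sized, isolated strongly stained nuclei shrink to small cores (see above).
* ROIs with holes, multi-part regions, and more than three strata are out of
  scope; heavily folded contours are rejected rather than guessed.
* No colour deconvolution: stain separation rides on CIELAB geometry, which
  is adequate for DAB-vs-hematoxylin but not for arbitrary chromogen pairs.
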