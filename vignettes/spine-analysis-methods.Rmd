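---
title: "Dendritic spine morphometry, validation and tracking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic spine morphometry, validation and tracking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## Scope and model of the data

`spinemorph` is the analysis back end of a spine-quantification workflow: it
assumes that restoration and semantic segmentation have already happened
outside the package (content-aware restoration models and nnU-Net-style
segmenters are consumed through their label-map outputs, never bundled). Its
inputs are

* a `volume_image`: an *n*-channel voxel grid with physical spacing
  `(z, y, x)` in µm, supplied by the user or a config file — never trusted
  from TIFF resolution tags, whose dialects are unreliable;
* a `semantic_labels` map on the same grid with classes background (0),
  dendrite (1), soma (2), spine head (3), spine neck (4).

Two acquisition geometries are used as presets throughout: spinning-disk
confocal at 0.150 × 0.065 × 0.065 µm and two-photon at 1.0 × 0.102 × 0.102 µm
(z, y, x). The axial step is 2–10× the lateral pixel, and this anisotropy is
the reason every metric in the package — distance transforms, geodesics,
Hausdorff distances, skeleton edge lengths — is computed with physical
spacings, never voxel counts.

## Spine instances

Spine instances are the connected components of the head ∪ neck classes.
The default connectivity is 26: thin necks sampled at 150 nm axial steps
fragment under 6-connectivity. Touching spines are *not* split — the upstream
segmenter is responsible for instance separation, and a watershed-style
splitter is a documented extension point. Instance ids are assigned in
descending component size with ties broken by the lexicographically smallest
`(z, y, x)` voxel, so numbering is deterministic.

Each instance is attached to the dendrite through an exact anisotropic
Euclidean distance transform (Felzenszwalb–Huttenlocher separable algorithm
with per-axis spacings, plus nearest-feature index propagation). The
attachment point is the dendrite voxel nearest any spine voxel, with exact
tie-breaking by smallest `(z, y, x)`; the spine-to-dendrite distance is that
minimum, in µm.

Filtering keeps an instance iff `min ≤ volume ≤ max` and
`distance ≤ max_distance`. The volume window defaults to 0.035–2 µm³, the
range used for spinning-disk spine analyses of cortical pyramidal neurons;
the distance default (1 µm) is deliberately permissive, as attached spines
sit essentially at one voxel step from the shaft. Rejected instances carry
the first violated rule (`min_volume`, `max_volume`, `max_distance`) so
filters can be audited; filtering is idempotent and re-labels survivors
1..K.

## Morphometry

All measurements are reported in µm/µm³ with the origin at the centre of
voxel (0,0,0). Missing values are explicit `NA`s and are written as empty CSV
fields, never as 0.

**Volumes.** `volume_um3` is the head ∪ neck voxel count × voxel volume;
`head_volume_um3` counts head voxels only and is missing for headless
instances (spines without a discernible neck/head split are retained, not
dropped).

**Spine length** is the maximum anisotropic distance from the attachment
point to any spine voxel centre (base → tip). The alternative — base to head
centroid — was rejected because it systematically underestimates long spines.

**Head width** is the diameter of the maximal inscribed sphere: twice the
maximum of the interior distance transform over head voxels, corrected by
half a lattice step along the direction of the nearest surface (the true
boundary lies about half-way between the last inside and the first outside
voxel centre). At 150 nm z-steps a head protruding axially is sampled by only
2–3 planes and its width can still be biased low by up to half an axial step;
widths are most reliable for laterally projecting heads with radii of at
least 3 lateral voxels.

**Neck length.** The naive measurement — length of the grid-shortest path
from the attachment voxel to the nearest head voxel — carries two
half-voxel-scale biases that are material for short necks at anisotropic
sampling: the attachment voxel centre can sit deep inside the shaft (up to
one axial step), and the first head voxel centre can sit beyond the true
head boundary. Both ends are therefore localized sub-voxel:

* the shaft is fitted locally around the attachment (PCA axis through the
  dendrite voxels in a 1.3 µm window; radius from the mean cross-section
  area), giving an axis and radius accurate to a few nm by averaging;
* the head tip is the head-voxel centroid pulled back by the volume-
  equivalent head radius `(3V/4π)^{1/3}` — the centroid likewise averages
  digitization away.

Neck length is then `distance(head centre, shaft axis) − r_shaft − r_head`.
When the voxel path is substantially longer than this chord (> 1.2×), the
neck is genuinely curved and the straightened voxel path (greedy
line-of-sight simplification with half-voxel tolerance) is used instead. On
phantoms this recovers planted neck lengths to ~2%, versus up to +30% for the
raw grid path.

**Soma distances.** The Euclidean distance is from the spine centroid to the
nearest soma voxel centre. The geodesic distance is computed by multi-source
Dijkstra propagation (26-neighbour, anisotropic step weights) seeded at the
soma over the *whole labelled foreground* — dendrite, soma and spines — and
read at the instance voxel nearest the centroid. Reading both distances at
the same point makes `geodesic ≥ euclid` hold by the path-length argument, up
to one voxel diagonal of discretization; reading the geodesic at the
attachment instead (a plausible alternative) breaks that ordering whenever
the spine body extends away from the soma, which is why it was not adopted.
Spines disconnected from the soma through the foreground get a missing
geodesic distance; maps without a soma get both distances missing, with a
notice.

## Dendrite skeleton and summaries

The centreline is extracted in the TEASAR style used by production neurite
skeletonizers rather than by voxel thinning. Homotopic thinning with endpoint
preservation, in both directional and distance-ordered sequential variants,
is unstable on digital tubes of even width: a 2×2 rod erodes end-first and
collapses to a point, because no voxel of such a rod is ever a protected line
interior. Path tracing avoids the problem entirely:

1. the root is the deepest soma voxel when a soma is present (SWC structure
   code 1), else the far endpoint of the longest geodesic;
2. a Dijkstra field whose step costs are scaled by
   `0.02 + (1 − D/D_max)^4` (D = interior depth) makes travel along the
   medial axis nearly free, so shortest paths hug the centreline;
3. paths are traced from the farthest unreached voxel back to the growing
   skeleton until every mask voxel lies within 1.5× the local tube radius
   (+2 voxel steps) of it;
4. root and tips are snapped to the locally deepest voxel, and the voxel
   paths become a rooted tree with anisotropic edge lengths; side branches
   shorter than `prune_um` (default 0.2 µm) sprouting from junctions are
   pruned.

The interior depth ignores the grid border as a surface (edge-replicated
padding), so a dendrite cut by the field of view keeps its centreline up to
the boundary. On phantoms, straight-tube lengths are recovered within 2–4%
and L-shaped tubes within ~5% (the corner is legitimately rounded by the
tube radius). Note that digital shortest paths are measured on the
26-neighbour metric, which can overestimate lengths of obliquely oriented
dendrites by a few percent.

Per-dendrite summaries report skeleton length, spine count, density =
count/length and averages of the per-spine measurements (missing values
excluded); a per-image row aggregates all dendrites. When a soma is present
its traversal to the root is part of the skeleton (the spec of the tree
places the root inside the soma), so shaft-length-based densities are best
computed on dendrite-only masks.

## Validation metrics

Dice `2|A∩B|/(|A|+|B|)` and IoU `|A∩B|/|A∪B|` are reported per class plus a
combined "spine" class (head ∪ neck). When both sets are empty the agreement
is vacuous and both metrics are 1 — this keeps per-class reports defined on
phantoms lacking a class; when exactly one is empty they are 0.

Object matching takes all (predicted, ground-truth) instance pairs with
pairwise IoU at or above the threshold and selects a one-to-one matching
greedily in descending IoU (ties: lower gt id, then lower pred id). At
thresholds ≥ 0.5 a voxel set can exceed the threshold with at most one
partner, so the greedy matching is provably optimal there; below 0.5 it can
differ from the optimal assignment when row/column maxima are not unique,
which the test suite checks explicitly against an exhaustive oracle.
TP/FP/FN give precision, recall and F1 (undefined ratios are missing, not 0),
and the F1 curve across IoU 0.1–0.9 is monotone non-increasing by
construction.

The Hausdorff distance is computed over 6-connectivity *surface* voxels (it
is a boundary metric), symmetric, under the anisotropic metric, via exact
EDTs of each surface sampled at the other; the full maximum is reported (the
"most extreme mismatched boundary point") with the robust 95th-percentile
variant alongside.

## Tracking

Rigid motion between sessions is estimated by 3-D phase correlation on one
reference channel — deterministic, global, and exact for translations — with
per-axis quadratic interpolation of the correlation peak for subvoxel
refinement (planted shifts are recovered within 0.25 voxel, also under shot
noise). Non-rigid correction is an adapter by design: an externally computed
displacement field can be applied upstream; no deformable registration engine
is included because none is specified by the workflow this package
implements.

Images are resampled linearly, label and instance maps by nearest neighbour
(no new codes), out-of-frame regions filled with background. Instances are
matched across sessions by the same greedy IoU procedure at a default
threshold of 0.3 — lower than the validation threshold because day-to-day
morphological change legitimately lowers overlap. Matched spines are
`stable` and share a track id; unmatched current-session instances are
`formed`, unmatched previous-session ones `eliminated`. Rates follow the
convention: stable% and eliminated% relative to the t0 count, formed%
relative to the t1 count. Longer series chain by successive pairwise
matching with forward-propagated track ids.

## The phantom generator and imaging model

`generate_scene()` voxelizes an analytic scene — a capsule shaft along a
polyline, an optional ball soma, and per-spine cylinder necks capped by ball
heads attached on the shaft surface — with painting precedence
head > neck > dendrite > soma, and returns the exact ground truth per spine:
analytic head volume `4/3πr³`, neck length, head width `2r`, spine length
(neck + head diameter) and the path-measured geodesic soma distance.
`random_scene_spec()` supplies a realistic stated world: shaft radius 0.4 µm,
head radii 0.25–0.45 µm, neck lengths 0.4–1.0 µm, neck radius 0.1 µm, and
densities below ~0.8 spines/µm — typical values for cortical pyramidal
neurons imaged at these resolutions. Two feasibility constraints are built
in: neighbouring spines rotate around the shaft so planted instances stay
disjoint (otherwise ground-truth identity is ill-defined), and under
two-photon anisotropy the shaft axis snaps to a z-plane with spines exactly
lateral, because a 0.1 µm neck pointing axially contains no voxel centres at
1 µm z-steps.

The degradation model is anisotropic Gaussian blur (axial σ ≥ lateral σ,
mimicking PSF elongation; defaults 0.09/0.25 µm), then Poisson shot noise at
`photon_scale` photons per intensity unit — the single SNR knob, with ~0.1
emulating low-excitation acquisitions and ~2.5 high-SNR ones — then additive
Gaussian read noise. The zero-σ, infinite-photon, zero-read-noise limit is
the identity, and degradation never touches label maps: ground truth is
generated, not re-derived. Augmentation supports right-angle z-rotations,
per-axis flips (applied identically to image and labels, labels never
interpolated) and image-only shot noise/blur; arbitrary-angle rotation is
refused because it would force label interpolation choices with no principled
default.

What a green phantom test does and does not establish: phantoms have
piecewise-constant intensity, perfectly tubular shafts and spherical heads,
no touching spines, no imaging artefacts in the *labels*. They validate the
geometry and bookkeeping of the analysis exactly, but say nothing about
segmentation quality on real tissue — that depends on the upstream model and
must be validated against annotated data with `validate_segmentation()`.

## Numerical choices and degenerate inputs

* Distance transforms are exact (no chamfer approximation); geodesics use
  26-neighbour Dijkstra, an upper-bounded metric overestimating oblique
  paths by ≤ ~8% in the worst direction.
* Component/id tie-breaks, greedy match tie-breaks and overlay colours are
  all deterministic given the seed; two runs of the driver on identical
  inputs are byte-identical.
* Empty instance lists, headless spines, missing soma, single-voxel masks
  and label files that fail to read all follow the documented missing-value
  or logged-skip paths rather than erroring the whole run.
* `rescale_volume()` maps voxel centres (`round(dim × spacing/target)` sizes,
  minimum 1); label maps always use nearest-neighbour so no class codes are
  invented.

## Known limitations

* TIFF support is uncompressed baseline (uint8/uint16/float32, single sample
  per pixel); compressed or exotic variants should be converted externally.
* Touching spines are not split; instance quality is bounded by the upstream
  segmenter.
* The greedy matcher can be suboptimal below IoU 0.5 in rare tie
  configurations (documented above).
* Head width for axially projecting heads at coarse z-steps is biased low by
  up to half an axial step; interpret absolute widths within the optical
  sampling limits.
* Only translations are estimated natively; rotation/deformation must be
  corrected upstream.
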