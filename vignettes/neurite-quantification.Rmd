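---
title: "Automated neurite outgrowth quantification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated neurite outgrowth quantification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuritracer)
```

# The measurement problem

Neurite outgrowth assays quantify the total length of processes that
neurons extend in culture, typically per cell and relative to a solvent
control, across a concentration series of a toxicant. The package
implements the full automated chain for calibrated two-channel 16-bit
micrographs — a nuclear stain (cell counting) and a neurite stain
(morphology) — from raw rasters to dose–response parameters. All physical
quantities go through one `Calibration` object; the reference geometry is
a 1376 × 1038 px frame imaging 884.89 µm × 667.52 µm, i.e. 0.64309 µm per
pixel, so 10 px correspond to 6.43 µm.

# Segmentation

**Brightness reduction.** Frames with more than `saturationFraction`
(default 0.5%) of pixels at full scale are linearly rescaled so that the
`clipPercentile` (default 99.9th) intensity value maps to full scale,
values above being clipped. This operationalizes "reduce brightness where
necessary" as an explicit, configurable rule; frames without saturation
pass through bit-identically.

**Phansalkar local thresholding.** On intensities normalized to [0, 1], a
pixel is foreground iff its value exceeds
\(T = m\,(1 + p\,e^{-q m} + k\,(s/R - 1))\), with \(m, s\) the mean and
standard deviation in a `windowPx` × `windowPx` neighbourhood (symmetric
reflective padding). The exponential term lowers the threshold in dark
regions, which suits fluorescence images: faint neurites on a dark
background still segment, while the \(s/R\) term suppresses pure noise.
Defaults are the canonical coefficients \(p=2, q=10, k=0.25, R=0.5\) with
a 25 px window (~16 µm — spanning a neurite cross-section plus local
background). The method itself is prescribed; the coefficients and window
are package defaults, exposed in the configuration.

**Closing and plausibility.** Morphological closing (disk radius 2 px)
bridges 1–2 px binarization gaps. Components whose physical area does not
exceed `maxImplausibleAreaUm2` (default 82.71 µm²) are removed. The
criterion is stated to two decimals and equals exactly 200 px² at the
reference calibration (200 × 0.64309² = 82.7126… µm²); areas are therefore
compared at the criterion's printed precision (tolerance 0.005 µm²), so
the 200 px² boundary case is removed and 201 px² is kept. The filter is
applied to both channels, after closing; nuclei at realistic sizes
(≥ 10 µm across, ≥ ~100 µm²) are unaffected. Connectivity is 8-connected
throughout (own union–find labelling; the area filter and orphan removal
depend on it).

# Nuclei separation

Markers for the watershed are regional maxima of the Euclidean distance
transform after suppression of maxima shallower than `hDepth` (default
0.2) times the global maximum distance and closer than
`minPeakSeparationPx` (default 10 px); flooding the negated distance
transform restricted to the mask assigns every foreground pixel to exactly
one label, so region areas always sum to the mask's foreground area. The
maxima-detection neighbourhood is a box of radius
`minPeakSeparationPx / 2`, which is what enforces the stated separation.
Two equal touching disks split whenever the saddle between them is deeper
than the suppression depth — at the default parameters this holds down to
centre distances of 1.5 radii. There is no apoptotic/healthy classifier;
per-region area and eccentricity columns are emitted so downstream tools
can apply their own rule.

# The pruned skeleton

The neurite mask is upscaled 3× by nearest-neighbour replication before
skeletonization so that the thinnest structures are at least 3 px wide.
The skeleton is computed per 8-connected component and satisfies three
contracts: every skeleton point carries its maximal-disk radius (its
Euclidean distance to the boundary); the union of maximal disks
reconstructs the shape to within the precision parameter ε; and boundary
protrusions of extent below 2ε generate no branch.

Internally, a feature transform (exact nearest-background point per
pixel) drives two stages. *Anchoring*: a pixel is marked when its feature
point and a neighbour's subtend ≥ 75° and lie > 2.9 px apart — features on
opposing boundary walls, the signature of a medial ridge — and only the
larger-disk side of each such pair is marked, keeping the zone thin.
This rejects boundary-staircase and distance-transform-facet artefacts,
whose features cluster on one wall. *Thinning*: homotopic erosion in
increasing distance-transform order removes simple non-anchor pixels
(8-connected foreground, 4-connected background), preserving endpoints;
a final parallel thinning pass reduces residual two-pixel bands to
one-pixel curves without retracting band ends.

*Pruning* then shortens terminal branches under witnessed maximal-disk
containment: a tail point may be removed only while some surviving point
with a strictly larger maximal disk ε-contains its disk
(\(|p-q| + r_p - r_q < \varepsilon\)), and previously removed points must
stay within the 2ε-inflation of some surviving disk. The strict
radius requirement protects constant-radius structures — a bar's central
segment, a neurite's centreline — from creeping erosion, while blob
interiors collapse onto their largest disk. For a square protrusion of
extent *e* on a wide bar, the disks of the stub just below the junction
cover *e*/2 of the protrusion, so a branch is first forced into the
protrusion at *e* = 2ε exactly — the stated protrusion rule. Passes repeat
until no tail shortens; finally, near-coincident residues of at most four
points collapse to their largest disk, so a discrete disk's skeleton is a
single point.

Two consequences are worth stating precisely. First, the ε-reconstruction
bound is certified (by an independent checker in the test suite) on shapes
whose boundary features are either finer than ε or coarser than 2ε —
crossing bars with long arms, large disks. Features *between* ε and 2ε in
extent are deliberately dropped by the protrusion rule, leaving a residual
bounded by their own extent (< 2ε) rather than by ε; this is inherent to
the rule, not an implementation defect, and the certified and
feature-scale regimes cannot be satisfied simultaneously on the same
boundary feature. Second, branch lengths are measured on lightly smoothed
polylines (moving average, window 5, endpoints pinned), which removes the
pixel-staircase bias of 8-connected chains; a 30°-rotated bar measures
within a few percent of its axis-aligned twin.

ε defaults to 10 px in upscaled space (6.43 µm at 1× at the reference
calibration) and is configurable per cell type: larger ε suppresses more
boundary detail (total length is non-increasing in ε), smaller ε traces
finer arborization at the cost of noise branches.

# Soma combination and metrics

Somata are seeded at mask pixels whose distance-transform value reaches
`somaRadiusPx` (default 8 px ≈ 5.1 µm, the half-width separating somata
from neurites at the reference scale) and grown back by a single geodesic
dilation of the same size — equivalent to a morphological opening
restricted to the mask. Iterating the dilation to stability would flood
the entire connected component, somata *and* attached neurites, so the
single-step form is the one that matches the intended geometry: thin
structures contribute nothing, and only components overlapping a nucleus
are retained. A nucleus is a neuron iff at least one of its pixels
overlaps the neurite mask (the automated analogue of counting
stain-positive cells); neurite components containing no neuron nucleus
are removed as staining artifacts; the skeleton is clipped per-vertex at
the soma boundary (whole-branch deletion would also delete legitimate
neurites passing near a soma); and neurite area is the mask area after
soma subtraction.

Reported total neurite length extends each free terminal by its
endpoint's maximal-disk radius (bounded by twice the skeleton's median
radius): the medial axis of a round-capped tube ends one cap radius short
of the tip, and the extension restores the tube's full extent. Endpoints
at the soma boundary are not extended — their truncation is deliberate.
Per-cell quantities divide by the nucleus count (default) or by the
neuron count (the stain-positive mode for mixed cultures); a zero
denominator flags the frame excluded rather than erroring.

# Statistics

Within each experiment, per-cell metrics are divided by the mean over the
non-excluded control frames and expressed as percent (control mean =
100%). Dose–response curves use the variable-slope four-parameter
logistic with the upper asymptote fixed to the solvent-control value, the
lower asymptote constrained non-negative and the slope free (negative
slopes describe lesions, i.e. responses declining with dose);
concentration 0 cannot enter the fit (log scale) and contributes only
through the fixed top. The least-squares problem is multi-started over
seven log-spaced LD50 seeds × three slope seeds and the lowest residual
sum of squares wins; a fit on responses with no dose effect reports
`converged = FALSE` with an undefined LD50 rather than a spurious number.
Method comparison uses closed-form ordinary least squares with
\(R^2 = 1 - SSE/SST\). Analysis-of-variance and multiple-testing
procedures are intentionally out of scope; the per-image and per-condition
tables are designed for export to any statistics tool.

# The synthetic-frame generator

`generateFrame()` draws somata (disks, radius 13–18 px) with 2–4 neurites
each, grown as smooth random-walk polylines in physical units (step
1.5 µm, heading diffusion 0.1 rad) and rasterized at the calibration's
pixel size, so ground-truth lengths are resolution-independent and exact
by construction. Walks carry their own collision field with delayed
self-stamping: structures from different cells keep a closing-proof gap,
a blocked walk terminates (truth records the consumed length) and
unconsumed budget re-spawns at a fresh angle, so realized tree lengths
track their targets. Side branches spawn beside the parent tube
(touching, not co-linear) so the child's drawn length is not swallowed by
the parent's stamp. Nuclei are bright ellipses (semi-axes 9–12 px,
≈ 100–150 µm² — realistic for SH-SY5Y-like cells and safely above the
plausibility criterion), one per soma plus configurable non-neuron nuclei,
optionally with touching partners (`clumpFraction`) to exercise the
watershed. Artifacts are isolated blobs drawn in two size classes, small
speckles (50–150 px²) below and large smears (300–500 px²) above the
plausibility criterion; knife-edge areas at the 200 px² boundary are
avoided deliberately, because behaviour exactly at the boundary is
already covered by the deterministic integer-area sweep, and rasterization
noise would otherwise dominate the artifact-survival property. Intensities
are two levels (background 2000, foreground 28000–30000) times a per-frame
exposure gain (0.85–1.2) plus Gaussian noise (σ = 800) clipped to 16 bits.

The generator emulates arborized morphology, clumped nuclei, artifacts,
exposure variation and sensor noise; it does **not** emulate point-spread
blur, uneven illumination, intensity gradients along neurites, or neurite
crossings (collision avoidance keeps structures separate — the
"non-crossing regime"). Passing the recovery suites therefore shows the
chain is correct and well calibrated on clean, separable structures;
real micrographs with dense crossing networks will measure less
faithfully, which is exactly why the per-cell, control-normalized readout
is the assay's endpoint.

`generateDoseResponsePlate()` scales the neurite length range per
condition by a four-parameter-logistic lesion model (defaults: top 100,
bottom 10, LD50 500 nM, hill −1.2, six concentrations from 100 to
5000 nM, six frames per condition) with 5% lognormal inter-frame
variability, and records exact truths per frame.

# Problem sizes and numerical choices

The validation suites run on a 360 × 270 px field at the reference pixel
size (`standardTestSpec()`: 3 neurons, 2–3 neurites of 45–90 µm, 3
non-neuron nuclei, 4 artifacts) — large enough to exercise every stage,
small enough to process whole plates in seconds. Reconstruction
certificates use 100 random bar-cross/disk shapes at ε = 10; the
medial-axis equivalence suite compares against a brute-force oracle on 25
random 3 × 3-block polyominoes within 40 × 40 px at ε = 1.5 (cells of a
few pixels keep every feature wider than a single pixel, where any two
discrete medial-axis definitions legitimately disagree); pruning itself is
probed separately by the protrusion sweep at ε = 10. Determinism is by
construction: parallel thinning and fixed tie-breaks (priority by distance
then linear index; watershed ridge handling is delegated to the flooding
implementation, which assigns every foreground pixel), seeded generation
restoring the caller's RNG state, and batch results merged in a canonical
frame order so worker count and manifest order cannot change any number.

# Known limitations

* Reconstruction error for boundary features between ε and 2ε in extent
  is bounded by the feature extent, not by ε (see above).
* Skeleton tips recede by up to the tube cap radius plus discretization;
  the endpoint extension compensates the systematic part only.
* The watershed separates touching nucleus *pairs* reliably; larger dense
  clumps can undercount by design of the marker suppression.
* Per-cell attribution of individual branches to individual neurons is
  out of scope, as is any learning-based segmentation.
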