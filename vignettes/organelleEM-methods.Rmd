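---
title: "Reconstructing mitochondria and ER from serial EM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing mitochondria and ER from serial EM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Serial-section scanning electron microscopy produces aligned grayscale
image stacks with strongly anisotropic voxels (here 3 × 3 nm in plane,
~50 nm between sections).  Mitochondria appear as dark-rimmed elliptical or
elongated profiles spanning many sections; the endoplasmic reticulum (ER)
appears as thin curvilinear membrane profiles, and the nuclear envelope as
a closed membrane shell around the nucleus.  Manual contouring of these
organelles cannot keep pace with acquisition, so OrganelleEM implements an
automated pipeline: per-slice instance segmentation of mitochondria by a
detection network plus a recursive, movable-field-of-view (FoV) mask
refinement network; joint semantic segmentation of ER and nuclear membrane
with a relabeling rule that separates the two; 2D→3D linking with
morphological rectification and a z-length filter; and morphometric
measurements (skeletons, cross sections, volume/surface, mitochondria–ER
contact distances) in physical units.

# Mitochondrion instance segmentation

## Detection subnetwork

A residual backbone feeds a feature pyramid (levels P2–P6 at strides
4–64).  A region proposal head predicts, for three anchors per feature-map
location (areas 32²–512² px², one per level; aspect ratios 1:1, 1:2, 2:1
under the area-preserving convention w·h = area), a 2-class score and a
4-vector box regression in the standard parameterisation.  Proposals are
decoded, clipped, and filtered by non-maximum suppression (IoU 0.7), and a
refinement head — RoIAlign-extracted features through a small
fully-connected trunk — rescoring and re-regressing each proposal (final
NMS 0.5).  P6 exists only for proposal generation.  The training loss is
the four-term multitask sum: cross-entropy and smooth-L1 for both the
proposal and refinement stages, box terms on positives only.

The refinement head is trained on jittered ground-truth boxes (guaranteed
positives) *and* on the network's own current proposals labeled by IoU
(≥ 0.5 positive, < 0.3 negative), plus random background boxes of varied
size.  Training on the model's own proposals supplies hard negatives —
without them, off-object or image-sized boxes receive confident foreground
scores because nothing similar was ever labeled background.

## Tiny configuration

All widths, anchor areas and thresholds are configuration, so a narrow
variant (`tinyDetectorConfig()`: 8 channels, anchor areas 16²–256²) trains
on one CPU.  Because phantom objects are 10–30 px rather than hundreds,
the tiny configuration extends the pyramid downwards with RoI-only levels
P1 and P0 (strides 2 and 1, laterals from the stem stages): at the
full-scale stride-4 floor, a 16 px object spans only 4 feature pixels,
too coarse for mask refinement.  This mirrors the full-scale design's use
of P6 "only in the RPN": the extra fine levels are used only for RoI
feature extraction (`roiMinLevel = 0`).

Optimisation is SGD with momentum 0.9 and weight decay 1e-4 (learning rate
0.001 full-scale; 0.01 tiny), with gradients clipped to a global L2 norm
of 5 — batch-of-one updates on summed detection losses otherwise diverge.
Prediction heads are initialised near zero, as is customary for detection
heads.  Batch-norm layers in the backbone use the current input's
per-channel spatial statistics in both phases (batch-of-one training);
the segmentation head additionally tracks running statistics during
training and uses them at inference — the standard batch-norm semantics.
This matters: normalising each window by its own statistics makes the
head contrast-invariant, so an empty background window has its noise
amplified until it looks like structure and the moving field of view
floods the image.  With population statistics an empty window stays flat
and is predicted empty.  Outputs remain deterministic functions of the
input and weights.

## Recursive FoV segmentation subnetwork

For each detected box the segmenter receives a 33 × 33 RoIAlign feature
window and a 33 × 33 object-mask channel, concatenated, through four 3 × 3
convolutions with batch normalisation and ReLU and a final 1 × 1
convolution with sigmoid.  The mask channel is initialised to zero except
an active value at the window centre (`seedValue = 0.95` in probability
space — the mask channel carries probabilities between iterations, so the
output probability map can be fed back directly).  The loss is the
*summed* pixelwise binary cross-entropy, with predictions clamped at 1e-7.

After each forward pass the eight positions at (±Δx, ±Δy, and the four
axis-aligned offsets), with (Δx, Δy) = (8, 8) in mask units, are checked
in the canonical order; every position whose probability is at least
T_move = 0.9 becomes a new FoV centre.  During inference a priority queue
holds pending centres in descending probability; the movement step is
scaled to image pixels as (Δx·w/s, Δy·h/s) for a w × h box, rounded half
away from zero, so larger objects take larger steps.  Each visit writes
the predicted probabilities into a slice-coordinate canvas under pixelwise
maximum, which makes the binarized coverage monotone non-decreasing, and
traversal ends when the queue empties (a hard cap of 512 visited centres
guards against degenerate runaway).  The FoV window keeps the detection
box's size; the union of visited windows is the object's effective extent
— the window-evolution rule is genuinely open in this design, and this is
the interpretation implemented here.

Training simulates detection output by jittering ground-truth boxes by up
to ±25% in shift and scale, with a four-mode curriculum: 40% of steps
shift the window by the scaled step in a random direction — one simulated
FoV move, with the mask channel carrying the object as already segmented
(the pre-move state seen from the new window, resampled bilinearly; the
ground-truth target is resampled nearest-neighbour so it stays binary);
15% are background-only windows of the same box scale with an all-zero
target (a spurious or overshot FoV must predict empty); 20% feed the
head's own seed-pass prediction back as the mask channel (the recursion);
the rest are seed-initialised object windows.  Without moved and
background samples the head only ever sees object-centred windows and
paints everything else confidently, which floods the traversal.  The
learning rate decays tenfold for the final third of the steps, the
configured decay-on-plateau schedule at this problem size.

## Canvas merging and binarization

Canvases binarize at the 8-bit threshold 127 interpreted on probabilities
as 127/255, strictly: a pixel exactly at threshold is background.
Overlapping binarized instances are resolved in favour of the higher
detection score.

# ER and nuclear-membrane segmentation

A fully convolutional residual encoder–decoder over six resolution steps
(additive skip merges, upsample → 3 × 3 convolution → batch norm → add →
ReLU per decoder step; 1 × 1 head to 3 classes) classifies every pixel as
background-or-nucleus-interior, ER, or nuclear membrane.  Inference takes
the per-pixel argmax (ties to the lowest class index).  Because ER and
nuclear membrane are locally indistinguishable membrane profiles, the
split is done by geometry: 8-connected components of the foreground that
touch the nucleus interior (sharing an edge or corner) are relabeled
nuclear membrane, the rest ER.  The relabeling never changes the
foreground/background partition and is idempotent.  The interior may be
supplied as a mask; by default it is derived from the prediction as the
class-0 components that touch no image border.  Relabeling runs per slice
in 2D, matching how the classes are annotated; a 3D variant over
26-connected components can be composed from `labelComponents3D()`.
Training uses mean 3-class cross-entropy with SGD (learning rate 0.01,
momentum 0.9).

# 3D reconstruction

Per-slice instances are linked across z: regions on consecutive slices
join when IoU ≥ 0.3 *or* containment overlap (intersection over the
smaller region) ≥ 0.5, matched greedily by descending IoU, one-to-one per
slice pair; unmatched regions may link across one missing slice (gap
tolerance g = 1).  Connected components of the link graph become 3D
objects.  The published multilayer-fusion algorithm this stage stands in
for is not specified in detail anywhere accessible; the overlap/greedy/gap
scheme is this package's concrete, testable realisation, and linking is
deterministic and invariant to instance-id permutation.

Rectification applies three local rules: (a) per-region hole filling plus
opening-by-reconstruction (erosion with a small disc, then geodesic
reconstruction under the region) — this removes detached debris and fills
enclosed holes while leaving clean regions *bit-exact*, which plain
closing-then-opening cannot do on discrete boundaries and which keeps the
operation idempotent on clean input; (b) one-slice gaps bridged by the
linker are filled with the eroded intersection of the dilated neighbouring
regions (a discrete shape interpolation); (c) regions whose area deviates
from the object median by more than 5× in either direction are replaced by
the same neighbour interpolation.  Finally, objects occupying fewer than
L = 15 sections are discarded — at 50 nm sections this removes everything
shorter than ~750 nm in z, which suppresses spurious short chains while
keeping genuine mitochondria, whose z extents are far larger.

# Morphometry

All outputs are in physical units (nm, µm², µm³) under the stack's voxel
spacing.

**Skeletons.**  The main skeleton is a distance-transform-guided geodesic
medial path: the two geodesically farthest voxels are connected by a
shortest path whose edge costs are down-weighted by the Euclidean distance
transform, so the path hugs the medial axis; each vertex is then recentred
to the deepest point of its perpendicular cross-section, the boundary-
corner end runs (one inscribed-ball radius of arc) are trimmed, and the
endpoints are rebuilt by marching along the interior direction to the
object boundary.  Objects whose longest internal path does not exceed the
inscribed-ball diameter by more than ~10% are blob-like and collapse to a
point skeleton (the degenerate skeleton of a sphere).  A voxel-thinning
skeletonizer would serve the same role; the geodesic construction needs no
topology-preservation lookup tables and returns the branch-free main path
directly, which is what the downstream cross-section sampling consumes.
Masks larger than 20k voxels are subsampled in plane first — the skeleton
is a centreline, so in-plane detail beyond a few voxels does not affect
it.  Smoothing fits per-axis least-squares polynomials (default cubic) in
the normalised arc-length parameter, resampled uniformly; with too few
points the degree reduces automatically.

**Cross sections.**  At n uniformly spaced arc positions the plane normal
to the local tangent is rasterised at the finest voxel spacing; the
trilinearly interpolated indicator is thresholded at 0.5 for the area
(cell counting) and contoured at 0.5 for the perimeter
(`grDevices::contourLines`, i.e. marching squares with linear
interpolation).  Planes that miss the object are skipped and flagged.

**Volume and surface.**  Volume is the voxel count times the voxel
volume.  Surface area is, by default, the co-area integral ∫|∇χ_σ| dV of a
Gaussian-smoothed indicator on an isotropically resampled grid — an
iso-surface estimator that avoids the systematic overestimate of raw
voxel-face counting on anisotropic voxels (face counting is available as
`method = "faces"`).

**Contact distances.**  Boundary voxels (mask minus its 6-neighbourhood
erosion) are reduced on a coarse grid of (2, 4, 4) voxels in (z, y, x):
every occupied coarse cell keeps one representative boundary voxel's
*true* coordinate.  The minimum distance over representative pairs is then
never below the full-resolution minimum and at most one coarse-cell
diagonal above it — reducing points by cell-centre snapping would lose the
lower bound.  Direct contact means a face-adjacent voxel pair at full
resolution, in which case the distance is reported as 0; records fall into
the bands direct / < 30 nm / ≥ 30 nm, a conventional cutoff for
membrane-contact-site proximity.

# The phantom generator

Real EM volumes for this problem are not redistributable, so the package
generates seeded phantoms with paired ground truth: dark-rimmed rotated
ellipses following an ellipsoidal z-profile with slow in-plane drift
(mitochondria, one instance id each, z spans drawn from a configured
range), thin random-walk tubules (ER), a disk-stack nucleus whose 2-voxel
shell is the nuclear-membrane class, smooth background texture and
additive Gaussian noise.  The four truth classes are pairwise disjoint by
construction; distinct mitochondria are kept from overlapping in plane
within a ±2-slice window so ground-truth 3D linking is unambiguous, and ER
keeps a 2-voxel clearance from the nuclear classes so the
membrane-vs-ER relabeling split is well defined.  Default conditions:
20 × 128 × 128 voxels at 50 × 3 × 3 nm, 4 mitochondria with in-plane
semi-axes 6–12 voxels (18–36 nm-scale profiles scaled to the tiny image
regime) spanning 15–20 sections, 3 ER tubules, rim contrast 0.4, noise
σ = 0.035.  Augmentation applies one shared geometric transform
(right-angle rotations and flips by default, so labels need no
interpolation; arbitrary angles with nearest-neighbour labels behind a
flag) and adds Gaussian noise to the image only.

What the phantoms do *not* emulate: vesicles, Golgi, membranous texture
inside mitochondria, registration artefacts, and section-to-section
intensity drift (histogram matching is exercised on synthetic drift in the
tests).  Passing the test suite therefore demonstrates the machinery —
learnability, traversal, reconstruction, measurement — not performance on
real tissue.

# Numerical and design choices

- Coordinates are (z, y, x), 0-based, half-open; boxes are
  (x1, y1, x2, y2) with exclusive upper edges.
- Histogram matching is per-slice against one fixed reference slice (the
  first slice by default).
- 8-bit intensities map to [0, 1]; the 8-bit threshold constant 127 is
  127/255 on probabilities, strict.
- RoIAlign samples 2 × 2 points per output bin, averaged, at unquantized
  coordinates; even-sized windows take the floor-centre convention.
- The pyramid-level assignment rule is k = clamp(floor(4 +
  log2(sqrt(wh)/224)), min, 5).
- Zero-denominator metrics report 0 and are flagged rather than NaN.
- The training problem sizes used by the tests and the acceptance script
  (64–96 px patches, ~200 training patches, hundreds of SGD steps, tiny
  widths) were chosen as the smallest sizes at which the learning
  behaviour is demonstrable and stable.

# Known limitations

- The tiny networks are demonstration-scale: they learn the phantom
  appearance, not EM tissue; no claim is made about full-scale accuracy.
- Through-plane merges (two true objects touching in xy across slices)
  are not split by the linker.
- The FoV window-extent rule beyond the detection box is an
  interpretation (running union of visited windows, fixed window size).
- The derived nucleus interior (enclosed background components) is a
  heuristic; supplying an interior mask is preferred when available.
- HDF5 containers are not supported in this build; multi-page TIFF and
  numbered PNG/TIFF series are.
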