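---
title: "foliakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foliakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

foliakit implements the computational chain that turns a closed, labeled
cortical surface mesh into a mutually consistent surface + volume atlas,
subdivides the surface into approximately equal-area patches, and fits the
atlas into individual subject space by diffeomorphic registration. This
vignette explains each model, the parameters that matter, the numerical
choices, and what the synthetic phantoms do and do not establish.

## Coordinate conventions

Voxel indices are 0-based; a volume's 4x4 affine maps voxel *centers* to
world millimetres (the NIfTI convention), and all distances are reported in
mm. Faces are 1-based index triples in R and converted to the 0-based
on-disk conventions of FreeSurfer, GIFTI and PLY by the readers/writers.
Displacement fields store world-mm vectors on their own grid; as point maps
they send `x` to `x + d(x)` with trilinear interpolation.

## Winding-number voxelization

A point is inside a closed, consistently oriented surface when the sum of
the signed solid angles of all triangles at that point is (numerically) 4π;
we use the Van Oosterom two-argument arctangent form per triangle and the
0.5 threshold on the normalized sum. Closedness is checked structurally
first: every undirected edge must be shared by exactly two faces and every
directed edge must be unique.

Evaluating the exact sum at every voxel center costs
O(voxels × triangles). Below a size threshold we simply do that. Above it,
the package exploits the fact that the winding number is constant on each
connected component of the complement of the surface: triangles are
supersampled at sub-half-voxel spacing to find every voxel the surface
crosses, the winding number is evaluated exactly at those voxels, and each
remaining 6-connected component inherits one exact evaluation (verified at
three representatives; a disagreement, which would indicate an
under-sampled barrier, is surfaced as a warning). This is an evaluation
strategy for the same quantity, not an approximation: the test suite checks
bit-identical agreement with the exhaustive evaluation on a folded phantom.

Shell voxels (those containing at least one vertex) take the modal label of
their vertices, with ties going to the smallest id for determinism. The
interior sentinel id defaults to `max(labels) + 1`. The default voxel size
is 1 mm — the resolution of the standard MRI data the reconstruction
pipeline targets — and is configurable down to the native resolution of
high-resolution meshes.

## The volumetric atlas pipeline

`run_atlas_volume_pipeline()` executes, in order: voxelize + interior fill;
7 synchronized sweeps of competitive cortical expansion into the interior;
white-matter assignment of the remaining core; 3 iterations of volumetric
mode smoothing; 4 sweeps of white-matter expansion back into cortical
labels; shell re-assignment from the surface; one final sweep of cortical
expansion into white matter; label pull-back to the vertices; surface mode
smoothing (radius 3, 3 iterations); and a final consistency pass. The
iteration counts are the recipe's fixed values; connectivity defaults are 6
(face-adjacent) for expansions — which keeps the expansion isotropic in
voxel steps — and 26 for mode smoothing, where the larger stencil gives
stabler modes. Expansions are synchronized sweeps in which ties at equal
distance go to the smallest label id; the suite proves each sweep equal to
a depth-truncated multi-source BFS with the same tie rule.

Two choices deserve justification:

* **Background handling during mode smoothing.** Freezing only the
  vertex-containing shell voxels lets background (id 0) votes erode thin
  interior voxels at deep fissures and, symmetrically, lets labels dilate
  outward into background — after which background voxels remain inside the
  winding interior, which the pipeline treats as a hard error. The pipeline
  therefore runs the mode filter with `ignore_background = TRUE`: background
  voxels neither vote nor change, so the smoothing acts strictly within the
  segmentation's support. The generic `mode_filter_volume()` keeps the plain
  semantics by default and both variants are oracle-tested.
* **The consistency pass is bidirectional.** Re-labeling each
  vertex-containing voxel with the mode of its vertices, alone, cannot give
  100% vertex/voxel agreement whenever a voxel contains vertices of mixed
  labels. The pass therefore assigns the voxel mode first and then pulls the
  voxel label back onto the vertices; afterwards every vertex matches its
  voxel and a second application changes nothing (idempotence is tested).

## Equal-area parcellation

The patch budget (800 by default, sized so patches land near the scale of
fine cortical parcellations) is apportioned to regions by
largest-remainder rounding of `budget x area fraction`, with a minimum of
one patch per region. Area fractions attribute one third of each face's
area to each corner vertex; the fraction denominator excludes designated
non-cortical labels such as the white-matter-tract patch.

Seeds are drawn uniformly without replacement within each region and then
repelled for 100 sweeps: sequentially in ascending patch id, each pointer
moves to the same-region neighboring vertex that maximizes its minimum
distance to the other pointers of the region, staying put when no neighbor
strictly improves it. Distance is the Euclidean chord length in the
spherical surface representation — a monotone equivalent of arc length and
the stated approximation of geodesic distance. Because a pointer only moves
when its own minimum distance strictly increases, the region's minimum
pairwise seed distance is non-decreasing sweep by sweep; the acceptance
suite asserts this over all 100 sweeps. The "move away from the others"
rule admits several readings; max–min repulsion was chosen because it is
deterministic given the draw, local, and directly yields the monotonicity
property. Sequential (rather than simultaneous) pointer updates were chosen
so a sweep is well-defined without conflict resolution.

Patches grow by multi-source BFS confined to regions, with a single FIFO
frontier seeded in ascending patch id; the suite checks equality with an
independent BFS oracle. Mode smoothing (radius 3, 3 iterations,
region-confined) rounds patch outlines; since a mode filter can split a
patch into fragments, fragments are reassigned to the adjacent same-region
patch with the longest shared border (largest component keeps the id) — an
addition the original recipe does not discuss but which the connectivity
invariant requires.

Balancing splits patches above twice the current mean area (two seeds at
the patch's mutually farthest vertex pair by chord distance — a split
recipe of our choosing, as none is stated — then two-way BFS inside the
patch) and merges patches below half the mean into the same-region neighbor
sharing the most boundary edges, recomputing the mean after each batch, with
at most 5 operations per patch and a final forced pass. Split halves
inherit the parent's operation count plus one; a merged patch's count is the
maximum of the pair plus one. Merging is the reason final patch counts come
out 15–25% below the budget, an expected consequence of the recipe, not a defect;
patch-area CV and max/min range ratio are reported in the `parcellation`
object rather than asserted against any fixed figure, since they are mesh- and
seed-specific.

## Registration and subject reconstruction

The builtin backend is multi-resolution diffeomorphic demons. Per
iteration: symmetric demons forces (difference image times the average of
the fixed and warped-moving gradients, normalized per voxel), capped at
`step_size` voxels; fluid Gaussian smoothing of the update; exponentiation
by scaling-and-squaring so the update is itself a small diffeomorphism;
composition with the running field; diffusion Gaussian smoothing of the
total field. With `metric = "lncc"` both images are locally normalized
(window mean removed, divided by window SD, 5³ window) before the force
computation, making the SSD force insensitive to intensity scaling — a
local-correlation drive in the spirit of symmetric-normalization
registration, feasible at desk scale. Images are brought to unit scale
internally for the plain SSD path so the force behaves identically for
images in [0, 1] and in scanner units.

Defaults (3 levels; 100/60/30 iterations; fluid 2 mm, diffusion 2 mm; step
1 voxel) were set on synthetic recovery problems. Because diffusion
smoothing of the *total* field at every iteration systematically attenuates
the recovered displacement, a short refinement pass (25 iterations, fluid
2 mm, diffusion 0.5 mm) runs at full resolution after the pyramid: starting
from the converged field it only corrects the residual, recovering the
attenuated detail without destabilizing the warp. Every returned field is
checked testably via `jacobian_determinant_range()` (finite differences at
interior grid points).

Subject reconstruction (`arcus_reconstruct`) follows the two-stage design:
stage 1 registers the atlas labels to the subject segmentation with each
label rendered as a 1 mm-blurred one-hot channel and a summed multi-channel
force (labels are categorical; one-hot channels give every boundary its own
gradient). The stage-1 field resamples the atlas virtual MRI into subject
space; stage 2 registers that image to the mask-multiplied subject MRI with
the LNCC drive. Demons fields are resampling pull-backs living on the
subject grid, so "applying the two fields to the vertices" is realized by
composing the pull-backs and numerically inverting the composition
(fixed-point iteration `inv(x) <- -d(x + inv(x))`, which converges for
fields with displacement-gradient norm below 1) into the forward point map
applied to the atlas vertices. Virtual MRI intensities default to cortex
110, white matter 250, background 0 (arbitrary units), blurred 0.5 mm.

The external-adapter backend writes fixed/moving as NIfTI, invokes a
user-supplied command or function, and reads back a displacement-field
NIfTI — the hook for plugging in a full symmetric-normalization
implementation; its contract is tested with a mock.

## Evaluation

DICE is `2|A∩B| / (|A|+|B|)` with empty-vs-empty defined as 1 (agreement on
absence) and empty-vs-nonempty as 0. Hierarchies are named groups of fine
label ids; groups within one hierarchy must be disjoint, so the
coarse-level evaluation ships as separate editable JSON files
(`hierarchy_coarse.json` with cortex/white-matter, `hierarchy_vermis.json`
with the whole-vermis group, which overlaps the cortex group and therefore
cannot live in the same hierarchy object). Groups absent from both volumes
are reported as missing, never as 0. Score tables are summarized the way
multi-subject evaluations are reported: median across subjects per group,
then the unweighted median and mean over the group medians; spread
statistics use the median-unbiased quantile definition (type 8). The
surface-to-volume Hausdorff distance voxelizes the surface vertices of a
group onto the volume grid and takes the classic symmetric max–min distance
in mm against the group's filled voxels — deliberately a surface-volume
discrepancy, which is inflated relative to a boundary-only comparison.

## Synthetic phantoms: what they do and do not show

`make_folded_phantom` applies the radial map
`r(θ, φ) = R (1 + a sin(kθ) sin(kφ))` to a subdivided icosphere. Because
`a < 0.5` keeps the radius positive, the surface is star-shaped and cannot
self-intersect (an optional winding test at offset face centroids verifies
this). Defaults — R = 25 mm, k = 6, a = 0.2, subdivision 5 (10,242
vertices), 8 latitude-band regions — give a closed genus-0 surface whose
folds are several voxels deep at 1 mm resolution: large enough to exercise
interior filling, label competition and patch growth, small enough that the
full pipeline runs in seconds. The bands are balanced in vertex count, so
apportionment, seeding and growth see realistic region structure; an
optional midline strip exercises cross-band groups in evaluation.

The phantoms establish algorithmic correctness (oracle equivalence,
postconditions, recovery of known deformations). They do not emulate real
cerebellar geometry: no branching folia, no peduncle cuts, no contact
between adjacent folial walls, no MRI physics beyond additive Gaussian
noise, and deformations are band-limited sinusoid mixtures rather than
anatomical variability. Passing tests therefore demonstrate that the
machinery is implemented as specified, not that reconstruction accuracy on
real subjects matches any cohort-level figure.

`make_smooth_deformation` mixes random sinusoids per component, rescales to
the requested peak amplitude, and enforces finite-difference displacement
gradients below 0.9, guaranteeing a positive Jacobian determinant; fields
are bit-reproducible from the seed.

## Problem sizes and tolerances

The test and acceptance runs use: the default subdivision-5 phantom on a
~61³ 1 mm grid for the pipeline-consistency check; a subdivision-4,
4-region phantom with a 100-patch budget for the parcellation checks; a
subdivision-3 phantom on a ~37³ 1 mm grid, warped by a 3.5 mm-amplitude
deformation with 5-unit MRI noise, for registration recovery (vertex RMS
asserted below 2 voxels, per-label DICE strictly improved). These sizes are
the package's choices for fast, deterministic verification; every stage
accepts larger inputs. Float comparisons in IO round-trips use 1e-6
relative tolerance (float32 storage); integer data round-trips exactly.

## Known limitations

- The builtin demons backend approximates, but does not reproduce, full
  symmetric-normalization registration; users needing it should use the
  external adapter.
- The supersampled-barrier interior classification assumes the triangle
  sampling is dense enough to separate inside from outside components; the
  three-representative check warns when it is not, and `exact = TRUE` is
  always available.
- Mean boundary distances between nearest-neighbor-warped label masks have a
  discretization floor of a few tenths of a voxel; recovery assertions are
  phrased against that reality (ratios, RMS in voxels) rather than absolute
  zero.
- `.annot` support is limited to the version-2 color table; other versions
  are rejected rather than guessed, and GIFTI support covers the pointset /
  triangle / label arrays the toolkit itself writes.
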