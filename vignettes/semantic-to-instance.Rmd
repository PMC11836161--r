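---
title: "From semantic to instance spine masks: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From semantic to instance spine masks: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemask)
```

## The problem

Whole-spine segmentation of sagittal T2-weighted MR images is naturally
posed in two steps. A per-voxel *semantic* labelling — which of 14 spinal
structures does this voxel belong to (ten vertebral substructures
including the endplate, the intervertebral disc, spinal canal, spinal
cord, sacrum) — is a job that patch-wise segmentation networks do well.
What they do poorly is *instance* separation: telling one vertebra from
the next, because all vertebrae look alike locally, and pathologies such
as fused vertebral bodies break any naive rule that slices the column at
disc levels.

`spinemask` implements the second step as a self-contained, testable
procedure: given a validated semantic mask, produce a mask in which each
vertebra (and each disc and endplate) carries its own identifier, counted
from top to bottom. The defining idea is that instance identity is only
ever predicted *relatively* — "the vertebra at the center of this window,
the one above it, the one below it" — never globally, so a model trained
on such windows does not need to know where in the spine it is looking,
and an error in one window cannot corrupt distant vertebrae.

## The two-phase procedure

**Phase 1 (semantic)** is a pluggable contract, not a model: any function
mapping an image volume to a same-grid mask of scheme codes can serve as
the backend (`segment_semantic()` validates grid congruence and codes
before anything downstream runs). The package ships phantom-backed oracle
and noisy backends; a trained patch-wise network would plug into the same
contract. Training and weights are explicitly out of scope.

**Phase 2 (instance)** runs entirely on the semantic mask — image
intensities are never consulted, and `predict_cutout()` enforces this:

1. *Centers.* 26-connected component analysis of the vertebral-body
   (corpus) label yields one center of mass per body, sorted top to
   bottom. Fused bodies form one component and hence one center.
2. *Cutouts.* Around each center a fixed-size, fixed-spacing window is
   resampled (nearest neighbour) from the mask. The default geometry is
   248 × 304 × 64 voxels at 0.75 × 0.75 × 1.65 mm in P-I-R orientation —
   large enough to hold a vertebra and both neighbours at human scale.
3. *Relative prediction.* A per-cutout predictor labels every voxel of
   the window as background, *above*, *center* or *below*. The predictor
   is again a contract; the oracle reads the phantom's ground truth
   through the placement transform, the noisy variant corrupts it.
4. *Appearances and consistency.* Vertebra *k* appears in up to three
   windows: as "below" of window *k*−1, "center" of window *k*, "above"
   of window *k*+1 — three appearances for inner vertebrae, two for the
   outer ones. Each appearance is mapped back to the canonical grid, and
   the vertebra's *consistency score* is the mean pairwise Dice across
   its appearances.
5. *Ordered fusion.* Vertebrae are written into the output from the
   highest to the lowest score, and a voxel once written is never
   overwritten, so the least trustworthy predictions are handled last
   and cannot steal voxels from corroborated neighbours. Within one
   vertebra, a voxel is kept if the majority of its appearances contain
   it. Surviving instances are renumbered 1..N from the top.
6. *Discs and endplates.* Each 26-connected IVD and endplate component
   inherits the id of the nearest vertebra strictly above it (by body
   center of mass, in mm), offset into disjoint id blocks: disc = 100 +
   v, endplate = 200 + v.

### Why majority voting, and what the ties do

The fusion rule had to be chosen (union, majority, or a designated
appearance would all be consistent with "integrated from highest to
lowest score"). Majority voting is what gives the method its
self-correcting behaviour: for an inner vertebra, a corruption confined
to one window is simply out-voted by the two intact appearances — the
acceptance suite demonstrates that corrupting a single interior window
often changes *nothing* in the fused mask. Exact ties (possible only
with an even number of appearances) are resolved in favour of the
center-role appearance, i.e. the window that was aimed at this very
vertebra; if no center-role appearance exists the tied voxel is dropped,
the conservative choice. A single uncorroborated appearance scores 0 so
it integrates last. Score ties between vertebrae break top-to-bottom,
for determinism.

## Post-processing

Four optional rules reconcile the two masks (each independently
toggleable, applied in this order by `postprocess_pair()`):

1. **Unsupported-voxel removal.** Instance voxels without semantic
   support are cleared. This package applies the rule *group-aware*: a
   vertebra id must sit on a vertebra-group semantic voxel, a disc id on
   an IVD voxel, an endplate id on an endplate voxel. The plain
   "semantic background" reading is implied by this stronger one; the
   stronger one is what makes rule 2 sufficient for exact foreground
   agreement.
2. **Missing-component rescue.** Connected components of vertebra-group
   semantic foreground still lacking an instance id — a wholly dropped
   spinous process, or holes left by inconsistent predictions — are
   assigned to the instance holding the plurality of their 26-neighbour
   shell, filling inward pass by pass. Components touching no instance
   at all are left with a warning. After rules 1–2, instance and
   semantic foregrounds agree voxel-exactly per group; this invariant is
   tested on every phantom run, noisy ones included.
3. **Isolated-element removal.** The largest 26-connected foreground
   component is the target spine; components whose bounding boxes miss
   its bounding box even after a 5-voxel dilation are deleted. In the
   chained form the analysis runs on the semantic mask and the same
   voxels are removed from both masks, so the foreground agreement
   survives. The margin is a package choice; no published value exists.
4. **Articular relabelling.** Predictions mix neighbouring vertebra ids
   at the articular processes by a few voxels; per connected component
   of each articular label, all instance voxels are set to the majority
   id.

All plurality/majority ties resolve toward the more superior (smaller)
id, for determinism.

## Reference-annotation merging

`merge_annotations()` reproduces the priority fusion used to build
training references from three automated sources: a base annotation
(body, disc, canal, sacrum), translation-derived posterior substructures,
and a cord mask — lower-priority sources only ever write onto background.
`fill_corpus_ivd_gaps()` then turns thin body–disc seams into endplate:
background runs of at most 2 voxels along the inferior axis directly
sandwiched between corpus and IVD are filled (the bound is a package
choice — unbounded filling would bridge unrelated structures; only axial
runs are considered, not diagonal ones), and where corpus touches disc
directly, the corpus-side transition voxel is relabelled, endplates being
anatomically part of the vertebral body.

## Evaluation suite

* **Dice** with the both-empty = 1 convention; **IoU** likewise.
* **ASSD** (mm): surface voxels are foreground voxels with a 6-connected
  background neighbour (a choice — no standard definition exists); the
  pooled mean over both surfaces of each voxel's distance to the other
  surface, computed with an exact anisotropic Euclidean distance
  transform and verified against an O(n²) brute-force oracle to 1e-9.
* **Instance matching** is greedy on descending IoU with threshold 0.5;
  a pair at *exactly* 0.5 is a true positive. At thresholds ≥ 0.5
  matches are provably unique (two pred instances cannot each cover
  half of the same ref), so greediness cannot change the result.
* **RQ / SQ / PQ** with RQ = TP/(TP + FP/2 + FN/2), SQ = mean matched
  IoU, PQ = RQ·SQ.
* Instance-wise Dice and ASSD average over *matched* pairs only;
  unmatched instances are reported through RQ/FP/FN instead of being
  folded into the overlap average. Structures empty in both masks are
  excluded from averages, mirroring how evaluations omit structures
  absent from a reference.
* `paired_signed_rank()` wraps the two-sided Wilcoxon signed-rank test
  for paired per-subject scores, reporting against α = 0.05; all-zero
  differences are degenerate and reported as p = 1.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds sagittal whole-spine label maps from
axis-aligned blocks in P-I-R orientation: 1–99 vertebra-like bodies with
nine posterior/peripheral substructures each, junction endplates and
interleaved discs, a continuous canal with embedded cord, a sacrum block,
optional fused pairs (continuous body across the junction, still two
ground-truth ids) and optional truncation of the outermost slices. The
default spacing (0.8, 0.8, 3.3) mm mimics thick-slice sagittal
acquisitions — high in-plane resolution, few left-right slices — which is
exactly the anisotropy that motivates 26-connectivity throughout.
Defaults place ~20 mm bodies with 4 mm discs and one-voxel endplates.

The phantom is deliberately schematic. It exercises connectivity,
top-to-bottom ordering, windowing, fusion, tie-breaks and the
post-processing rules deterministically; it does not emulate MR
intensities, curved spines, partial-volume boundaries or pathologies
beyond fusion and truncation. A green phantom suite therefore certifies
the *conversion and evaluation machinery*, not the segmentation quality
of any trained backend on real data.

`corrupt_mask()` provides the error model for robustness tests: random
foreground deletions and boundary-adjacent accretions at a given rate,
the same restricted to the one-voxel surface shell (emulating ragged
model boundaries and missed outermost voxels), and wholesale removal of
chosen labels — all reproducible under a seed.

## Numerical and geometry choices

* Canonical orientation is P-I-R; every pipeline entry point reorients
  first. "Superior" always means a smaller inferior-axis index.
* Arrays use R's native 1-based indexing; affines use the NIfTI 0-based
  voxel convention. Reorientation is exact (permutation + flips, affine
  updated consistently; round-trips are identity).
* Label maps are resampled with nearest neighbour only — labels must
  stay categorical and nearest interpolation can never invent a label;
  images may use trilinear.
* Affines must be orthogonal within 1e-4 after normalization; sheared
  geometry is rejected rather than silently resampled.
* Phantom-scale work uses `phantom_cutout_config()`: windows at the
  phantom's own spacing (extraction is then an exact crop with
  background padding) spanning ~3.5 vertebral pitches and the full
  volume slab in the two other axes. With unit grid ratio the placement
  transform is exactly invertible, which is what makes the voxel-exact
  recovery property provable; pushing labels through a non-integer grid
  ratio shifts boundaries by up to one voxel, which is acceptable at
  human scale (the mm-geometry default) but would make bit-exact tests
  meaningless. The test and acceptance problem sizes — phantoms of 3–24
  vertebrae, grids around 70 × 800 × 15 voxels at the largest — were
  chosen so the full property suite runs in minutes on one CPU.

## Known limitations

* No anatomical naming: ids count from the top of the field of view;
  C2 in one scan and T5 in another may both be "1". A labelling step
  would sit downstream.
* The sacrum stays semantic-only; whether it should receive an instance
  id is left open, and none of the evaluation paths require one.
* A corpus component whose prediction returns an empty center class is
  skipped with a warning rather than recovered.
* The rescue rule cannot assign a semantic component that touches no
  instance anywhere; it warns and leaves it unlabelled.
* `paired_signed_rank()` defers to `stats::wilcox.test`; with heavy ties
  the normal approximation applies.
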