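---
title: "Building C-alpha backbone models from cryo-EM density maps"
author: "cryotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building C-alpha backbone models from cryo-EM density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryotrace)
```

## The problem

A cryo-EM density map is a 3-D voxel grid of scattering potential; building
an atomic model into it means deciding where the protein backbone runs,
where each residue's C-alpha atom sits, and which sequence position each
traced position corresponds to (sequence registration). Experimental maps
are locally ambiguous — resolution varies across the volume and some
regions carry little signal — while structure predictors are accurate for
individual domains but unreliable for domain packing and chain-chain
interfaces in large complexes. cryotrace fuses the two sources: the map is
the experimental modality, and a predicted per-chain structure, already
placed (docked) in the map coordinate frame, is the prior modality.

The pipeline has three stages:

1. **Voxel prediction.** A multimodal 3-D convolutional network reads a
   normalized density window plus a 24-channel binary encoding of the
   placed predicted structure and emits, per voxel, class scores for three
   cascaded tasks: backbone-atom labels (4 classes), C-alpha labels
   (4 classes), and amino-acid type (21 classes, including "no amino
   acid").
2. **Candidate extraction.** Per-voxel C-alpha probabilities are
   thresholded, clustered with DBSCAN, filtered by backbone support,
   reduced by non-maximum suppression, and refined to sub-voxel
   coordinates.
3. **Tracing and registration.** Candidates are linked into a 2-6 Å
   connectivity graph, pruned to chain-like (degree <= 2) topology, and
   aligned to the chain sequences through a candidate-by-residue scoring
   matrix enhanced by N-hop connectivity propagation; fragments are grown
   bidirectionally, merged, greedily assigned to chain copies, optionally
   register-refined against the predicted structure, and gaps are filled.

The result is a C-alpha backbone model with per-residue identities, ready
for external full-atom reconstruction and real-space refinement (both are
deliberately out of scope here, as are docking and domain segmentation —
the package consumes structures already placed in the map frame).

## Input standardization and labels

Maps are resampled to 1 Å voxels (trilinear interpolation; the resampled
dimension is `round(extent) + 1` per axis, preserving physical extent) and
normalized by median subtraction, clipping above the 99.9th percentile,
flooring negatives at zero, and min-max scaling to [0, 1]. An all-constant
map normalizes to all zeros rather than erroring. The order — subtract,
clip, floor, scale — follows the textual order of the source procedure;
normalization is idempotent up to floating tolerance unless the max was
clipped.

Voxel indices relate to coordinates by `index = round((coord - origin) /
voxel)` per axis, with i taken from z, j from y, k from x. Rounding is
half-up (`floor(x + 0.5)`): nearest-integer rounding centers atoms in
voxels on a 1 Å grid, whereas flooring would bias every index by half a
voxel. Base R's `round()` is half-to-even and is deliberately not used.

Training labels are three integer masks shaped like the map. Backbone:
3 at voxels holding backbone atoms (N, CA, C, O), 2 at voxels holding other
atoms, 1 at voxels adjacent to any atom, 0 elsewhere. C-alpha: the same
with 3 reserved for CA voxels. Amino-acid: the residue type code (1-20,
one-letter codes in alphabetical order, A = 1 ... Y = 20 — one table used
everywhere) at each CA voxel and its neighbors. "Adjacent" means the
26-connected neighborhood, the smallest standard 3-D adjacency; the source
procedure does not fix the connectivity. Higher labels always win voxel
collisions; amino-mask collisions go to the residue whose CA is nearest
the voxel center.

Maps are processed in 64³ windows: non-overlapping 48³ cores tiled from
the origin corner, each wrapped with 8 voxels of context (zero-filled
outside the map). Only the 48³ core of each output window is written back,
which makes stitch-after-partition exactly the identity — a property the
tests exercise over arbitrary shapes.

## The network

Two branches learn modality-specific representations before fusion. The
density branch applies parallel 3-D convolutions with kernels 3, 5, 7 and
9, concatenates them (128 channels at full size), and applies channel
self-attention (global average pooling, a two-layer bottleneck, sigmoid
gates multiplied back). The prediction branch convolves the 24-channel
encoding to 64 channels and multiplies it by learned feature gates. The
concatenated branches pass through a fusion convolution to 64 channels.
When no predicted structure covers a window the same pipeline runs with
the 24 channels zeroed — the fallback is architectural, not a separate
code path.

Three encoder blocks (128, 256, 512 filters) each consist of a residual
dense block (three 3³ convolutions with dense connections and a
squeeze-and-excitation gate, plus a 1×1 projection shortcut), a dual
attention block (a local 3³ convolution in parallel with global channel
attention, concatenated), and a 3³ transition convolution. By default the
encoders keep full 64³ resolution, following the stated output shapes; a
`downsample_encoders` flag enables stride-2 pooling per block, in which
case the FPN's trilinear upsampling becomes active rather than a no-op.
The FPN harmonizes the three encoder outputs with 1×1 lateral convolutions
to 64 channels each, smooths each scale with three 3³ convolutions,
weights the scales with softmax-normalized learnable scalars, and
concatenates to 192 channels. Three cascaded decoders consume the FPN
output: the backbone decoder (4 channels); the C-alpha decoder, whose
input concatenates the FPN features with the backbone logits (4 channels);
and the amino-acid decoder, fed the FPN features plus both earlier logit
sets (21 channels). The cascade mirrors the biological hierarchy: backbone
geometry constrains C-alpha placement, and both constrain residue
identity.

No deep-learning framework ships with this package's dependency set, so
the network is implemented on a small reverse-mode autodiff tape with
Rcpp kernels for the 3-D convolutions; analytic gradients are verified
against numerical differentiation in the test suite.

### Loss, schedule, training

Each task contributes a weighted cross-entropy (mean over voxels of
`-w_k log softmax` at the true class); the total is the lambda-weighted
sum with weights constrained to sum to 1. The schedule starts at
(0.6, 0.3, 0.1) — backbone first — and reaches (0.25, 0.4, 0.35) at epoch
25; the transition is a linear ramp over epochs 20-25 (the two endpoint
triples are the binding contract; any smooth ramp between them would do).
Training uses Adam from 1e-4 with halving on validation plateau,
global-norm gradient clipping at 1.0, dropout 0.01, optional augmentation
(noise, blur and intensity scaling on the density only; joint 90-degree
rotations, flips and integer translations on density, encoding and masks),
and keeps the checkpoint with the lowest validation loss. Class weights
default to inverse class frequency over the training masks (capped at
100), since background voxels dominate by orders of magnitude.

At inference, per-window logits are stitched to map shape and softmaxed
per task. "Probability" outputs are the class-3 softmax probability for
the backbone and C-alpha tasks, and, for the amino task, the 21-class
softmax with the "no amino acid" class dropped and the 20 type
probabilities renormalized.

### Reduced configurations

The default `model_config()` mirrors the published channel sizes, which
target GPU training at scale — out of scope here. All experiments in the
tests use `model_config_tiny()`: the same topology with 8/12/16-channel
encoders, kernels 3 and 5 in the density branch, and small windows. The
overfitting check trains this reduced model on five 12³ windows cut from
one synthetic fixture, with uniform class weights and Adam at 5e-3 for 30
epochs; training loss falls to about 10% of its initial value, and the
outcome is stable across a factor-2 change in learning rate. Uniform
weights and the larger step are appropriate for a from-scratch overfit
probe on a handful of windows; the inverse-frequency default and 1e-4
remain the right settings for real training. Problem sizes throughout the
tests (40-100 residue toys, 12³-16³ training windows, single-window
inference maps) were chosen so every stage is exercised end to end on one
CPU.

## Candidates, tracing, registration

Voxels with C-alpha probability strictly above 0.3 become candidate
voxels. DBSCAN groups them with eps = 1.9 Å and min_samples = 1: half the
3.8 Å consecutive C-alpha spacing, so two adjacent residues can never
merge into one cluster, while the sub-voxel cloud around one true C-alpha
does. Noise points are kept as singletons rather than discarded — at
min_samples = 1 every point is core, and downstream filtering is the
intended gate. Clusters are scored by mean backbone probability and kept
only above 50% of the best cluster's score (the best cluster therefore
always survives). Non-maximum suppression (radius 2.0 Å, descending
C-alpha probability) leaves one candidate per local maximum; coordinates
are refined to the probability-weighted mean of same-cluster voxels
within 2.0 Å. Because refinement can pull two accepted candidates
slightly together, a final suppression sweep on the refined coordinates
restores the minimum-distance contract. Each candidate carries the
20-type probability vector read at its refined voxel.

The connectivity graph joins candidates 2-6 Å apart with edge weight
`exp(-(d - 3.8)² / (2 · 0.5²)) · min(p_i, p_j)` — peaked at the ideal
consecutive spacing; the window alone is given by the source protocol,
the weight form is this package's choice. Pruning removes edges in
ascending weight wherever an endpoint exceeds degree 2; connected
components of the result are simple paths or cycles, and cycles are cut
at their weakest edge.

The scoring matrix sets `S[i][j, k]` to candidate k's probability of
residue j's type in chain i (unknown letters score uniform 1/20). N-hop
propagation (default N = 2) replaces each entry with the average over
sequence offsets h in [-N, N] of the best score among candidates exactly
|h| graph hops away at residue j + h, dividing by 2N + 1 with
out-of-range offsets contributing zero. A candidate on a well-connected
stretch whose neighbors also match the flanking sequence is boosted; an
isolated candidate is damped to a third of its score (N = 1). Sequence
ends lose terms under this normalization; seeds there still clear the
0.5 seed threshold for one-hot scores, so the behavior is accepted rather
than special-cased.

Fragments seed at matrix maxima above 0.5 and extend bidirectionally —
one residue and one graph-adjacent candidate per step, taking the highest
enhanced score above the 0.2 extension floor. With predicted structures
available, a step is rejected when the last five fragment candidates
deviate from the corresponding predicted segment by more than 2.0 Å RMSD
after rigid superposition. Overlapping fragments that agree on every
shared assignment are unioned; conflicting overlaps keep the higher
score. Greedy assignment consumes fragments best-first into the first
chain copy where neither residues nor candidates are claimed — identical
sequences fill copies in order, with no symmetry-aware scoring (a known
limitation). Register refinement tries shifts up to ±2 residues per
fragment, keeping the shift that lowers RMSD to the predicted chain, and
iterates to a fixed point; the RMSD sequence is non-increasing by
construction. Gap filling searches depth-limited paths through unassigned
candidates between anchor endpoints (each step 2-6 Å, geometry screened
against the prediction when present); when no candidate path exists, the
predicted segment is rigidly fitted onto placed flanking residues and
inserted with a `gap-filled` provenance flag (occupancy 0.50 in PDB
output). Residues neither source can place stay unmodeled.

All thresholds above (0.3 extraction, 50% cluster filter, 2-6 Å window,
0.5/0.2 seed/extension, ±2 shifts, 2.0 Å geometry tolerance, N = 2) are
exposed as function arguments; the extraction threshold, filter fraction
and distance window come from the source protocol, the rest are this
package's documented defaults.

## Evaluation metrics

Model quality against a reference structure is reported as: TM-score
(optimal rigid superposition over a supplied C-alpha correspondence, sum
of `1/(1 + (d_i/d0)²)` normalized by reference length, with
`d0 = 1.24 (L_ref - 15)^{1/3} - 1.8` floored at 0.5); C-alpha match (% of
model C-alphas paired within 3.0 Å — map-frame comparison with no
superposition, because model and reference share the map frame and
agreement there is the meaningful map-to-model criterion); C-alpha quality
score (match × model length / reference length — precision times
coverage, exceeding 100 when the model over-builds); aligned C-alpha
length; sequence identity; and sequence match (% identical types among
paired atoms). The correspondence is greedy globally-closest-first,
one-to-one, ties broken lexicographically. A full structural alignment
search is not reimplemented: results from an external alignment tool can
be supplied as a text file and parsed instead.

## The synthetic generator

Every stage is testable without downloads through synthetic fixtures. Toy
proteins are self-avoiding C-alpha walks (consecutive spacing 3.8 ± 0.1 Å,
non-consecutive separation >= 4.0 Å) with N, C and O at fixed ideal
offsets and uniformly random sequences. Density maps are sums of per-atom
isotropic Gaussians with sigma = 0.425 × resolution on a 1 Å grid with a
5 Å margin, plus optional peak-scaled Gaussian noise — enough to exercise
normalization, labeling and extraction; image formation, CTF and solvent
are deliberately not modeled, so passing tests say nothing about detector
physics or experimental artifacts. Predicted-structure surrogates jitter
coordinates (optionally displacing one contiguous segment rigidly, the
domain-error case). Oracle prediction volumes place `sharpness` mass
(default 0.99) on the true class directly from the label masks — a
perfectly trained network stand-in that isolates the clustering/tracing
stages from network quality; degraded sharpness (e.g. 0.2, below the 0.3
threshold) provides the hard cases. What the oracle pipeline does
demonstrate: on 100-residue fixtures, candidate extraction plus tracing
recovers >= 95% of residues within 1 Å with >= 95% correct registration
and TM-score >= 0.9. What it cannot demonstrate: performance on real maps
with non-Gaussian noise, varying local resolution, or sequence repeats
longer than the propagation window.

## Numerical and degenerate-input choices

Constant maps normalize to zero; empty structures yield all-zero masks
and encodings with warnings, not errors. Ties in half-up rounding go away
from minus infinity. DBSCAN, pruning and NMS iterate in deterministic
(index or descending-probability) order, so results are reproducible;
trace extraction is invariant under candidate relabeling. Cycles are cut
at the weakest edge; equal-weight ties resolve by edge index. The TM-score
with fewer than 3 pairs is reported as 0 with an `undefined` flag rather
than erroring. All generator and training randomness flows from explicit
seeds.
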