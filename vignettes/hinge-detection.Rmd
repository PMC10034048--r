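---
title: "Detecting 3-hinge gyral folding patterns: models, parameters and design"
author: "hinge3 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 3-hinge gyral folding patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The cerebral cortex folds into gyri and sulci; where three gyral crests
meet, the folding forms a *3-hinge* — a junction landmark with thicker
cortex, strong axonal connectivity and consistent cross-subject function.
Classical extraction builds a gyral-crest graph per hemisphere (watershed
plus tree marching) and reads hinges off its nodes, which takes over an
hour per brain. `hinge3` implements the learning-based alternative: segment
3-hinge *regions* from per-vertex morphometry with a convolutional network,
then condense each region to *centroids* with weighted mean shift. This
vignette records the models, every tunable that matters, and the design
decisions that were genuinely open.

## Stage 1 — labels and features

**Region labels.** The label source is a list of 2-hinge (crest) and
3-hinge (junction) vertices — from a gyral-net extraction on real data, or
planted ground truth on synthetic data. `expand_regions()` marks a vertex 1
iff it lies within `R1` of a 3-hinge vertex or `R2` of a 2-hinge vertex.
`R1 = 6` mm and `R2 = 2` mm are the empirical radii for human cortex.
"Spherical neighbourhood" is interpreted as the ambient Euclidean ball, not
a geodesic patch: the target regions are compact spherical caps, and the
ball is what a sphere of radius R encloses. The kd-tree implementation is
pinned to a brute-force all-pairs oracle in the tests. Expansion runs over
all surface vertices (not only crest vertices), and vertices satisfying
both radii are labeled once.

**KNN feature vectors.** Row `v` of the network input is
`[map(v), map(b1), ..., map(b15)]` over `v`'s `k = 15` nearest vertices by
ambient Euclidean distance, ascending. Ties at the k-th distance — which
occur systematically on lattice-like meshes — break to the lower vertex
index, making the output deterministic and permutation-equivariant.
Normalisation is min-max to [0, 1] per subject-hemisphere per feature,
computed before blocking and over real vertices only, so padding never
shapes the statistics and no information leaks across subjects.

**Blocking.** Vertices are kept in native file order, zero-padded to the
next multiple of 4096 and tiled into `64 x 64 x 16` blocks; 0-based row `i`
sits at block `i %/% 4096`, row `(i %% 4096) %/% 64`, column `i %% 64`. The
index map makes the layout a bijection on real slots, so `unblock()` is an
exact inverse and the (arbitrary) ordering cannot affect any downstream
metric. A ~330k-vertex hemisphere pads to 331,776 rows = 81 blocks; a
~365k-vertex one to 90 blocks. Whether such an array represents one
hemisphere or a whole brain is left to the cohort manifest; the package
processes hemispheres independently and assembles whole-brain numbers only
in evaluation.

**Indexing.** In memory every vertex index is 1-based, as in all R mesh
tooling. On-disk plain-text index lists are 0-based by default and carry an
explicit `index_base=` header, so files interoperate with 0-based tools.

## Stage 2 — the SE-Unet segmenter

The segmenter is a symmetric U-shaped encoder/decoder over single blocks.
Each encoder level applies two 3x3 convolutions, each followed by batch
normalisation and ReLU, with one dropout layer (p = 0.2) between the paired
convolutions; a squeeze-and-excitation block; then 2x2 max pooling with
channel doubling. The decoder mirrors it: a learned 2x2 transposed
convolution halving the channels, concatenation with the matching encoder
map, paired convolutions, SE. A 1x1 two-channel head with softmax yields
per-position class probabilities. The SE block pools each channel globally,
squeezes `C -> floor(C/r) -> C` (ReLU then sigmoid) and rescales channels
by the resulting gates; the plain U-net baseline simply omits SE, and the
audit `params(se_unet) - params(unet) = sum over blocks of
2*C*floor(C/r) + C + floor(C/r)` is asserted in the tests. The
multi-feature variant scales each input tensor with its own conv/BN/ReLU
stem and concatenates the stem outputs before the encoder.

Reference hyper-parameters (`preset = "reference"`): 5 levels, 64 base
channels, `r = 24`, RMSprop with initial learning rate 0.05, batch size 40,
150 epochs, batch-norm momentum 0.6 (Keras convention:
`running <- 0.6*running + 0.4*batch`), soft Dice loss with smoothing
`eps = 1`. The per-epoch exponential decay factor is not pinned by the
reference design; 0.96 is the package default and is exposed in the
config. Padding slots are masked out of the loss — the zero-padding rows
carry no anatomy and letting them vote would bias the foreground sums.

**Desk preset.** The networks in this package run on plain CPU BLAS
(im2col convolutions; forward and backward passes are hand-derived and
verified against numerical gradients). Tests and the synthetic pipeline
use `preset = "desk"`: depth 4, 8 base channels, `r = 4`, 30 epochs, batch
10, initial learning rate 0.01. The smaller rate follows from the smaller
batches: with ~10-sample batches the Dice gradient is noisy and RMSprop
steps of 0.05 overshoot, while 0.01 converges smoothly across seeds. The
full-scale preset remains available and uses the reference values
unchanged.

**Dice loss.** `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)` on the
foreground probability; `eps = 1` keeps empty-empty comparisons defined
and bounds the loss in [0, 1].

## Stage 3 — weighted mean shift

A predicted region is a point set $X \in R^{n \times 3}$. The centroid
update iterates $X_m \leftarrow X_m + M_h(X_m)$ with

$$M_h(X_m) = \frac{\sum_i G_H((X_i - X_m)/h)\, w(X_i)\,(X_i - X_m)}
                  {\sum_i G_H((X_i - X_m)/h)\, w(X_i)}.$$

Design choices, in order of consequence:

- **Kernel reading.** The kernel is the (magnitude of the) derivative of a
  1-D Gaussian. Applied literally to a 3-vector it is dimensionally
  ill-defined, so the package evaluates the radially symmetric profile on
  the scalar scaled distance `u = ||Xi - Xm||/h` — the standard reading
  under an isotropic bandwidth `H = h^2 I`, which is chosen precisely so
  that a single hyper-parameter `h` (6 mm, the 3-hinge region radius)
  remains. `s` defaults to `h/2`.
- **Weights.** The weighting is specified only as "closer to the centre,
  more important"; the package uses `w(Xi) = exp(-||Xi - Xm||^2 / (2 h^2))`
  recomputed against the current centre each iteration, with
  `weight_fn = "uniform"` recovering the classical algorithm. With uniform
  weights and a flat (indicator) kernel one step reduces to the
  sample-mean offset over the spherical window, which the tests assert
  against a literal implementation.
- **Seeding.** Labeled vertices are split into mesh-edge connected
  components (components below `min_region_size = 5` are noise and are
  dropped). A component is *not* given a single seed: ground-truth-like
  label sets are one connected web along the entire crest network, and a
  single seed can only ever return one mode. Instead each component is
  seeded at a deterministic `h`-spaced grid subsample of its vertices (one
  seed per bandwidth cell) and all seeds are iterated in one batched
  matrix computation.
- **Stability filter.** The derivative-of-Gaussian profile admits unstable
  equilibria halfway along symmetric crest segments (offsets vanish there
  by symmetry). After merging, each mode is therefore restarted from six
  axis displacements of `merge_radius`; a mode whose restarts do not all
  return is an unstable fixed point and is discarded — its restarts flow
  into the neighbouring stable modes and merge there. Genuine junction
  modes pass this test because a junction ball is an attractor of radius
  roughly half the crest spacing.
- **Merging and membership.** Modes within `merge_radius = h/2` are merged
  by single-linkage with weight-averaged positions (cluster count is
  monotone non-increasing in the radius); labeled vertices join their
  nearest surviving mode.
- **Convergence.** In offset norm (`tol = 1e-3` mm, `max_iter = 200`), not
  in density value — the quantity of interest is the position.

## Evaluation

Region metrics are precision, recall and F1 in percent over valid (non-pad)
vertices; undefined ratios (empty prediction or empty truth) report 0 with
an explicit flag. Centroid error PreE is the mean Euclidean distance from
each reference centroid to its nearest prediction — penalising missed
hinges, the costly failure — with the reverse direction and the symmetric
mean available, since excess predictions are otherwise free and no
standard fixes the matching rule. Subject aggregation defaults to macro
(per-subject means, F1 averaged as F1), the common reporting convention
for per-subject studies; micro pooling of confusion counts is also
implemented and the two are asserted to agree on identical confusion
tables. The accuracy–sex analysis is a Pearson point-biserial correlation
with the two-sided t-based p-value; when many feature combinations are
scanned the p-values are raw (no multiplicity correction), and the report
labels them as such.

## The synthetic test bed

`generate_subject()` builds a 2.5-D triangulated height-field sheet: a
planar ridge skeleton (honeycomb hexagons by default; triangular lattice
and random Voronoi cells are alternatives) raised to Gaussian-profile
ridges of amplitude `ridge_height = 8` mm and cross-section
`ridge_sigma = 2.5` mm, with vertex jitter `noise_sd = 0.3` mm. Junctions
of the noiseless skeleton (degree >= 3 nodes) are the exact ground-truth
3-hinge centroids; crest-line samples every `spacing` become 2-hinge
vertices. Morph maps copy the couplings seen in real data: `sulc` is
anticorrelated with ridge height, `curv` is the signed mean curvature of
the height field (negative on crests, positive on flanks), `thick` is
~0.75 mm larger on crowns than in fossae around a 2.5 mm baseline, `area`
comes from incident triangle areas and `vol = area * thick`. Defaults were
chosen once to mimic human-scale folding (ridge cells a few centimetres
across, millimetre-scale noise) and are the package's study conditions.

A flat sheet is used deliberately: every pipeline operation depends only on
local geometry, and on a sheet the ground truth is analytic. What the sheet
does *not* emulate — closed brain topology, long-range curvature, the
spectral statistics and inter-subject variability of real cortex, partial
voluming of the morph maps — bounds what passing tests show: they
demonstrate that the implementation is correct and that the method recovers
planted structure under realistic local geometry, not that any particular
accuracy transfers to clinical data.

Cohorts alternate a binary label and shift gender-1 ridge heights by a
configurable effect, with per-subject seeds fanned out from the base seed
by a fixed counter scheme; the manifest is lazy, so 100-subject cohorts
cost nothing until a subject is realised.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale configurations
chosen as the package's own study sizes: 96 x 96 mm sheets (9,216 vertices,
3 blocks per hemisphere) for the end-to-end pipeline with 3 subjects
(2 train / 1 test); 128 x 128 sheets for the 20-block segmentation
learnability study; one 256 x 256 sheet (65,536 vertices, 26 planted
junctions) for junction-recovery and oracle-equivalence checks. A
`grid_shape = c(576, 576)` sheet reproduces the 331,776-vertex / 81-block
geometry of a full hemisphere when full-scale behaviour is wanted.

Other numerical conventions: FreeSurfer binary I/O is big-endian float32
(round trips are exact to format precision); GIfTI is read in ASCII,
Base64Binary and GZipBase64Binary encodings and written as ASCII;
degenerate inputs (empty annotations, all-zero labels, constant features,
coincident mean-shift points) return typed empty results or flagged
warnings rather than errors wherever the pipeline can proceed; every
stochastic step draws from a seed derived deterministically from the
global seed, and the desk pipeline is byte-reproducible across reruns.

## Known limitations

- The SE-Unet runs on CPU BLAS; the desk preset trains in about two
  minutes, but full-scale training (81 blocks x 1000 subjects x 150
  epochs) is out of reach of this implementation and is not attempted.
- Mean shift on a connected crest web reports modes at sharp junction-free
  bends of the label density (they are genuine stable modes); the
  stability filter removes straight-segment artefacts but a bent
  degree-2 arc far from any junction will still contribute a centroid.
  PreE, which matches truth to nearest prediction, is insensitive to
  these; precision of centroid counts is not.
- Geodesic distances are never used; on heavily folded real cortex the
  ambient-ball reading of `R1`/`R2` can bridge opposing sulcal banks.
- The gender analysis is a correlation on per-subject summary accuracy; it
  makes no causal or morphometric claim beyond the planted effect it is
  tested on.
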