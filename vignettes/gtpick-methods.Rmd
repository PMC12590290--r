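---
title: "Set-prediction particle picking: model, training objective, and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-prediction particle picking: model, training objective, and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gtpick)
```

## The problem

Single-particle cryo-electron microscopy determines macromolecular
structures by averaging hundreds of thousands of individual particle
projections extracted from micrographs. The extraction step — particle
picking — has to find the (x, y) centers of particles in images whose
per-pixel signal-to-noise ratio is below one, where particles are densely
packed and easily confused with ice contamination and carbon edges.
Missed particles (low recall) directly reduce the information available to
3D reconstruction, and spurious picks (low precision) contaminate the 2D
class averages downstream.

`gtpick` treats picking as *set prediction*: a fixed set of learned object
queries decodes an image into at most Q detections, trained end-to-end with
bipartite (Hungarian) assignment between predictions and ground truth, so
no hand-tuned anchor matching or non-maximum-suppression heuristics enter
the training objective. Three ideas define the detector:

1. **Reference-point cross-attention.** Each object query owns a normalized
   2D reference point. Its sinusoidal positional embedding conditions the
   decoder's cross-attention and anchors the query's box regression, giving
   every query an explicit spatial identity.
2. **Group-wise one-to-many assignment.** The Q queries are partitioned
   into G groups of Qg. Hungarian matching runs independently inside each
   group, so every ground-truth particle can supervise up to G queries
   (one per group) while assignment stays one-to-one within a group. In
   dense scenes this multiplies the positive supervision per particle and
   raises recall; at inference the duplicated detections the mechanism
   deliberately creates are merged by score-ordered center suppression.
3. **A composite Focal + L1 + GIoU objective.** Classification uses the
   focal loss `-sum alpha_t (1 - p_t)^gamma log p_t`, which down-weights
   the abundant easy background queries; box regression combines the L1
   distance in normalized center form with a generalized-IoU term
   `mean(1 - GIoU)` whose enclosing-box penalty keeps gradients informative
   even when prediction and target do not overlap. The total is the exact
   weighted sum `lambda_cls L_cls + lambda_l1 L_1 + lambda_giou L_GIoU`
   (defaults 2, 5, 2 — the conventional weighting in this detector
   family).

## Architecture and data flow

A convolutional backbone (`"resnet101"` bottleneck stacks at stride 32 by
default; a 4-block `"tiny"` network at stride 16 for CPU-scale work) maps
the standardized micrograph to a feature map, projected by a 1x1
convolution to the transformer width C and flattened to a token sequence.
A fixed sinusoidal 2D code P is added once at the encoder input; the
encoder applies post-norm self-attention + feed-forward layers. All
backbone normalization uses frozen statistics — fixed mean/variance and
affine — so no batch statistics are ever computed and small-batch training
cannot destabilize the feature distribution.

The decoder stacks N layers of (i) self-attention over the queries,
block-diagonal across groups, (ii) cross-attention whose query input is the
query state plus the reference-point embedding and whose keys/values come
from the encoder memory, and (iii) a feed-forward block; each sublayer is
wrapped in dropout, a residual connection, and LayerNorm. The grouped
self-attention mask is applied in both training and inference so that each
group behaves exactly like an independent single-group decoder with shared
weights — an equivalence the test suite asserts numerically; running it at
inference too avoids any train/test mismatch under the merged-group
inference mode.

Prediction heads are shared across layers: a linear + sigmoid head for the
single foreground class ("particle"), and a 3-layer MLP whose first two raw
outputs are *added to the reference point in logit space* before the
sigmoid, so boxes are anchored at their references; the last two outputs
give width/height through a sigmoid, with the bias initialized at a
configurable size prior (default 0.1 of the image side).

### Design choices where the design was genuinely open

The reference-point mechanism admits several implementations; the package
settled on the following, each exposed as a `model_config()` flag and
chosen after measuring desk-scale convergence (the minimal
static-learnable-point scheme trains so slowly at small scale that the
synthetic benchmark plateaus at F1 ~ 0.2 with near-uniform attention
maps):

* **Positional keys** (`pos_memory_keys`): the grid code P is added to the
  cross-attention *keys* (values stay purely content-based), mirroring how
  the queries carry their reference code.
* **Shared query/key initialization** (`share_qk` inside the cross
  attention): Wq and Wk start identical, making the positional part of the
  attention logits a positive-semidefinite form that already peaks where
  the key position matches the query's reference; the matrices remain
  independent parameters afterwards.
* **Reference-point attention bias** (`pos_attention_bias`): the inner
  product between the query's reference code and each cell's grid code,
  scaled by 1/sqrt(C) and a trainable per-layer gain, is added to the
  cross-attention logits. This makes attention *sharply* local around the
  reference from the first optimizer step instead of requiring locality to
  emerge from random projections.
* **Dynamic reference refinement** (`refine_references`): decoder layer
  l + 1 anchors its regression and attention at layer l's predicted
  centers (treated as constants in the backward pass, the usual practice
  for iterative refinement).
* **Content-conditioned reference proposals** (`reference_mode =
  "proposal"`, the default): layer-1 reference points are the centers of
  the top-Qg cells of a per-image objectness map read off the encoder
  memory, so references sit on candidate particles before any decoding.
  Slot s of *every* group anchors at the rank-s cell: each candidate
  receives exactly one query per group — precisely the one-to-many
  supervision pattern the grouping is for — and no group is ever forced to
  chase a target its anchors do not cover (an earlier interleaved-rank
  variant had exactly that pathology and halved the achievable
  training-set fit). Top-k selection is non-differentiable and the
  proposals are detached, as usual for two-stage detectors. With
  `reference_mode = "learned"` each query instead owns a data-independent
  learnable 2D point.
* **Auxiliary dense objectness** (`train_config(objectness_aux = )`): during
  training a linear head on the encoder memory predicts per-cell "a
  particle center falls here", supervised with the same focal loss. This
  trains the backbone/encoder features directly and markedly accelerates
  convergence at desk scale; it adds no parameters to the prediction path
  and is reported separately (`l_obj`) so the detection loss breakdown
  remains the exact weighted sum of its three components.
* Auxiliary detection losses are applied at every decoder layer
  (`aux_loss`, default on), with re-matching per layer.
* The matching cost is `w_cls (-p) + w_l1 ||b - b'||_1 + w_giou (1 - GIoU)`
  with the loss weights; the classification term uses the foreground
  probability directly.
* `L_cls` is normalized by the number of matched queries so the
  classification and box terms stay commensurate; anyone comparing raw
  loss magnitudes against unnormalized sums should account for this.
* Focal parameters default to alpha = 0.25, gamma = 2, the reference
  values of the focal-loss literature.

## Training

`train_detector()` optimizes with AdamW. The full-size defaults are the
standard recipe — 640 px inputs, learning rate 1e-4 with 1e-5 for the
backbone, weight decay 1e-4, batch size 2, dropout 0.1 before each
LayerNorm, Xavier initialization of all non-backbone weights. The
CPU-scale configuration used throughout the tests (`tiny_config()`:
C = 64, 1 encoder + 2 decoder layers, G = 2, Qg = 10, tiny backbone,
dropout 0) trains from scratch, so it uses a single learning rate of 1e-3
— a conventional AdamW rate for a small model — and 128 px inputs matching
the synthetic micrographs. Seeding covers initialization, data order, and
augmentation, making loss histories bit-reproducible on CPU. Optional
augmentation is horizontal/vertical flipping with mirrored boxes; because
boxes are normalized, whole-image resizing needs no box adjustment.
Validation F1 at the default evaluation criterion selects the checkpoint.

Degenerate situations are defined rather than left to chance: an image
with no targets contributes only background classification; zero matched
pairs make the box terms 0; more targets than per-group queries matches
only Qg of them (with a warning); Hungarian ties resolve to the
lowest-index solution; probabilities are clamped to [1e-8, 1 - 1e-8]
before logs.

After training, the pick score threshold is calibrated by sweeping it on
the validation split and keeping the value that maximizes pooled F1 (ties
resolve toward higher recall); the calibrated value is stored in the
checkpoint and used by `pick()` unless an explicit threshold is
configured.

## Inference and export

`pick()` resizes the micrograph to the model input size, takes final-layer
predictions at or above the score threshold (default 0.5), optionally
restricts to the first query group, and suppresses duplicates greedily in
descending score order within a radius of 0.5 x the mean ground-truth box
side learned at training time — the counterpart of one-to-many training.
Centers are mapped back to original pixel coordinates (origin top-left,
0-based, box edges half-open), and `write_star()` emits a RELION-style
loop with `_rlnMicrographName`, `_rlnCoordinateX`, `_rlnCoordinateY`,
`_rlnAutopickFigureOfMerit` — the center-coordinate convention CryoSPARC's
extract-from-coordinates job expects. A detection-only picker has no pose,
so no rotation-angle columns are written.

## Evaluation

`evaluate_dataset()` matches picks to ground truth greedily in descending
score order; a pick claims the nearest unclaimed truth particle whose
center lies within half the truth box's mean side (an IoU >= 0.5 mode is
provided for comparability with the general detection literature — which
criterion a given published table used is often unstated, so both are
reported in the `criterion` field). Counts are pooled over micrographs
before computing P/R/F1 (micro-averaging); across datasets the arithmetic
mean of per-dataset metrics is the "average row" convention. F1 is the
harmonic mean; presentation rounding is half-up at 3 decimals and never
enters stored values.

## The synthetic benchmark

`sim_config()` emulates the regime that makes picking hard: dark
soft-edged disks (radius 8 +/- 2 px) on a slowly varying background, 5-15
per 128 px image at >= 12 px center separation, additive Gaussian noise
with sd 0.8 x the particle contrast (measured SNR ~ 1), plus 2 unannotated
irregular blobs emulating contamination that never intersect a particle
box — false-positive pressure without label noise. Ground truth is the
tight square of side 2 x radius. Everything is a pure function of
(seed, index); `synthetic_benchmark()` builds the 200/25/25
train/val/test corpus used by the acceptance checks.

What the simulator does *not* emulate: CTF oscillations, structured ice
gradients, particle shape variability, aggregation, and carbon edges. A
model that passes the synthetic benchmark has demonstrated that the
training loop, assignment, loss, and export machinery work end to end at a
realistic SNR — not that it matches hand-curated picking on real
micrographs, which additionally requires large-scale training on curated
data and a pretrained backbone.

Problem sizes throughout the tests are chosen for a single CPU: 128 px
images, the tiny configuration above, 20 training epochs at batch size 2
on 200 images. At this scale one training run takes a few minutes; the
full-size configuration is exercised structurally (shapes, frozen
statistics, determinism) rather than trained.

## Known limitations

* The backbone trains from scratch; pretrained weights, which the
  full-scale recipe assumes, are not distributed with the package (a
  checkpoint path can be supplied instead).
* Large micrographs are resized whole to the input size, not tiled; at
  4096 px this is a 6x downscale that blurs small particles. Tiling is a
  deliberate extension point, off by default.
* Single particle species only; no pose; no multi-scale attention.
* The engine is plain R matrix arithmetic: correct and reproducible, but
  two to three orders of magnitude slower than GPU tensor frameworks, so
  training beyond desk scale is out of reach here.
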