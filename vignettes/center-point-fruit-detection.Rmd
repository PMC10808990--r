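---
title: "Center-point fruit detection with double prediction layers and expanded sample allocation"
author: "fruitpoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-point fruit detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Training fruit detectors for orchard phenotyping requires bounding-box
labels that are expensive to draw by hand. A practical alternative is
auto-labeling: train a detector on cheap synthetic or source-derived
scenes, run it on unlabeled orchard images, and export its detections
as pseudo-labels. Two distribution mismatches limit this pipeline:

* a **foreground (scale) gap** — the training fruits occupy a narrow
  size range while application images contain fruits at widely varying
  scales, including small ones (pixel area below 32 × 32, or square
  root of the relative area ratio below 3%);
* a **background gap** — the training backgrounds do not resemble the
  orchard backgrounds the detector must operate in.

`fruitpoint` implements an anchor-free center-point detector with two
mechanisms aimed at these gaps, plus everything needed to exercise
them at desk scale: annotation I/O (COCO JSON, Pascal VOC XML), a
seeded synthetic-scene generator that reproduces both gap structures,
a self-contained training loop, decoding, pseudo-label export,
balance-point evaluation, and a four-way ablation harness.

## The model

An image `I` of size `W × H` is mapped to per-pixel predictions on
downsampled grids. The heatmap branch predicts `Ĥ ∈ [0,1]^(H/r × W/r)`,
the probability that each grid cell contains an object center; a size
branch predicts box width/height in input-image pixels; an offset
branch predicts the sub-pixel remainder of the center position in
heatmap-cell units. Detections are decoded from local maxima of `Ĥ`.

### Ground-truth heatmap encoding

Each annotated box writes an unnormalized 2-D Gaussian with peak 1 at
the integer heatmap cell containing its center. The Gaussian radius is
the largest corner perturbation that keeps IoU ≥ `min_overlap` (0.7)
with the original box — the minimum of the three standard
quadratic-root cases — and the width follows the center/corner-keypoint
convention `σ = (2r + 1)/6`. Overlapping objects combine by
elementwise maximum. Entries below `zero_threshold = 2⁻⁷` are set to
*exactly* zero, which makes "nonzero cell" a well-defined notion for
sample allocation. The alternative rule `σ = r/3` (the large-radius
limit of the same convention) is available as
`gaussianEncodingConfig(sigma_rule = "radius_over_3")`; at desk-scale
box sizes it collapses most footprints to a single cell and thereby
empties the expanded allocation, which is why it is not the default.

### Sample allocation: original vs expanded

The baseline supervision treats only exact centers (`H = 1`) as
positives, every other cell as negative — a few positives per image
against thousands of negatives, so foreground evidence is scarce.
The **expanded allocation** declares every nonzero-encoded cell a
positive sample and uses the Gaussian code itself as its label. On the
package's default 64 × 64 scenes this raises positives per image from
≈1.6 to ≈9.2 (the `positives_per_image_*` quantities recomputed by
`scripts/acceptance.R`).

### The two heatmap losses

The baseline pairing uses the modified focal loss (exponents α = 2,
β = 4):

```
L = -(1/N) Σ_xy  (1-Ĥ)^α log Ĥ              if H = 1
               (1-H)^β Ĥ^α log(1-Ĥ)          otherwise
```

Binary labels cannot express "positive, but off-center": supervising
the expanded positives with label 1 would make them indistinguishable
from true centers. The **continuous label value loss** (β = 2)
removes that restriction:

```
L = -(1/N) Σ_xy |H - Ĥ|^β [ (1-H) log(1-Ĥ) + H log Ĥ ]
```

Its label may be any value in [0,1], so each expanded positive is
supervised toward its own Gaussian code, with strength decreasing away
from the center. At binary labels (H ∈ {0,1}) the two losses coincide
pixel for pixel (asserted in the tests), so the continuous loss is a
strict generalization. The package rejects the incoherent pairing
(expanded allocation + focal loss) with an explanatory error.

**Normalizer.** `N` is read literally as the total number of heatmap
pixels — that is the default of `lossConfig()` and what the
loss-correctness tests pin down. `trainDetector()`, however, defaults
to the per-object normalization (`normalization = "objects"`, the
center-point lineage's training convention): with `N` = pixels the
heatmap gradient is roughly two orders of magnitude weaker than the
size/offset terms and the desk-scale model underfits centers. Both
normalizations are exposed; only the training default differs.

### The neck: deep-to-shallow iterative fusion, two prediction layers

The backbone emits feature maps at downsampling factors 2, 4, 8, 16
(the shallowest level added, the deepest removed relative to the
single-layer baseline). Fusion nodes follow

```
O(m, n) = DC( O(m, n-1) ) + DU( O(2m, n-1) )
```

with the valid index set m = 16: n = 0; m = 8: n ≤ 1; m = 4: n ≤ 2;
m = 2: n ≤ 3 — exactly six fusion nodes, no shallow-to-deep edge
(asserted by graph inspection). Prediction layer 1 is `O(2, 3)` at 2×
downsampling and detects small fruits; layer 2 is `O(4, 2)` at 4× and
detects the rest. The ablation baseline keeps the original
shallow-to-deep fusion `F(n) = DC(F(n-1)) + DU(O at 2^(n+2))`,
n = 1..3, producing a single 4× output.

`DC` is realized as a 3 × 3 convolution + ReLU and `DU` as the same
followed by 2× bilinear upsampling. Deformable convolution — the
operator of the reference design — has no implementation in this
package's dependency set, so the plain-convolution realization is the
only one offered and is recorded in checkpoints
(`fusion_op = "conv3x3"`). No batch normalization is used: the
desk-scale networks (≈10⁵ parameters) train stably without it, and it
keeps the hand-written backward pass small. `O(·, 0)` is a 1 × 1
projection of the backbone map to the shared neck width, so additive
fusion is well-typed.

### Layer routing

Every ground-truth object is routed to exactly one layer by the
small-object rule (area < 1024 px² **or** sqrt(area/(W·H)) < 3%):
small objects to layer 1, the rest to layer 2. Size and offset are
supervised at encoded center cells only — also under the expanded
allocation, which by design modifies the heatmap branch alone.

### Backbone

The reference design does not mandate a backbone; here it is a plain
strided-convolution pyramid with configurable channel widths
(`modelConfig()`), one stride-2 convolution plus `backbone_depth`
stride-1 refinements per level. `tinyModelConfig()` (channels
8/16/24/32, neck width 16) has ≈10⁵ parameters and runs a 64 × 64
forward pass in well under a second on one CPU. No claim of
architectural identity with any published network is made.

## Training

`trainConfig()` defaults follow the published recipe: batch size 4,
Adam, initial learning rate 0.000125, 100 epochs with a factor-10 drop
at epoch 90. `tinyTrainConfig()` scales the schedule down: 20 epochs
with the drop kept at 90% of the schedule (epoch 18) and learning rate
0.001 — the customary Adam rate for a few hundred from-scratch steps;
the full-scale rate is too conservative there. The total loss is

```
L = λ_heat Σ_ℓ L_H(ℓ) + λ_size Σ_ℓ L1_size(ℓ) + λ_off Σ_ℓ L1_off(ℓ)
```

with λ = (1, 0.1, 1) adopted from the center-point baseline (the
reference does not state head weights). Gradients flow through a small
reverse-mode tape over RcppArmadillo conv/upsample kernels; the
analytic gradients are verified against numeric differentiation in the
test suite. A fixed seed makes initialization, shuffling and hence the
loss trajectory bit-reproducible on one platform.

## Decoding and pseudo-label export

Peaks are cells equal to their 3 × 3 local maximum with score at or
above the floor; the top-k peaks per layer become boxes via the offset
and size maps and are clipped to the image. The two layers' detections
are merged by greedy IoU suppression (threshold 0.5, disableable),
keeping the higher score — the reference is silent on inference-time
combination, so this is the package's choice and is exposed in
`decodeConfig()`. Scores are raw heatmap values; no rescoring.
`exportPseudoLabels()` writes detections as COCO or VOC files (scores
carried along), drops zero-area boxes, and offers a hook where an
external pseudo-label refinement strategy can filter or rewrite labels
before export.

Two score floors appear deliberately: export keeps the 0.3 default (a
pseudo-label should be confident), while evaluation decodes at 0.05 so
AP integrates the full ranked list.

## Evaluation

Matching is greedy one-to-one in score order at IoU 0.5; AP is the
area under the all-point-interpolated precision-recall curve
(11-point interpolation available for cross-checking). Precision,
recall and F1 are reported at the **balance point**: the confidence
threshold minimizing |P − R|, ties broken by higher F1 then lower
threshold. All metric code is checked against brute-force oracles.

## The synthetic benchmark

Scenes are shaded ellipses over procedural backgrounds — the method's
mechanisms (center encoding, scale routing, sample allocation) depend
on geometry and scale statistics, not texture realism. Two regimes
emulate the foreground gap, with sizes in *absolute pixels* because
the small-object criterion mixes an absolute and a relative cutoff:

* `source_like`: box scale ~ Normal(40 px, 3 px), near-round; no
  fruit is small by the criterion;
* `target_like`: with probability `small_fraction` a small fruit
  (scale U(8, 20) px, always small), else a large one (U(34 px,
  0.35 × image side), never small); aspect ratios up to 1.8.

Two background styles emulate the background gap: style A (green
gradient, leaf-like ellipse distractors) vs style B (brown gradient,
branch-like strokes). Boxes are amodal (they cover the unoccluded
extent); fruits whose visible fraction falls below 0.25 are not
annotated. Placement draws each fruit's size once and retries only its
position, bounding pairwise IoU (< 0.35) and cover fraction (< 0.5 of
the smaller box) so annotations stay sound; infeasible placements are
skipped with a message. Identical (config, seed) pairs reproduce
scenes byte-identically.

What passing tests on these scenes show — and what they do not: they
demonstrate that the implementation is internally correct and that the
method's mechanisms behave as designed under controlled scale and
background structure; they say nothing about texture, lighting, or
real-orchard
clutter, and desk-scale ablation orderings are stochastic and are
reported, not asserted.

## The scaled-down study

`scripts/acceptance.R` (and the heaviest test) runs the study the
package is sized for: 64 × 64 scenes with 1-3 fruits, 200 training and
50 test images, 20 epochs. On the in-distribution split the improved
configuration (double prediction layers + expanded allocation with the
continuous loss) reaches AP@0.5 ≈ 0.98-1.00 at the balance point
P ≈ R ≈ 0.97. Under the domain gap (source-like/style A training,
target-like/style B testing) all four ablation configurations complete
and report P/R/F1/AP; absolute APs drop to ≈0.3-0.4 — the gap is
intentionally severe at this scale — and orderings vary by seed. These
problem sizes were chosen so a full run fits comfortably in a few
minutes on one CPU.

## Numerical choices and degenerate inputs

* Predictions are clamped to [1e-6, 1 − 1e-6] before logarithms;
  gradients vanish where the clamp is active.
* Cells exactly at `zero_threshold` are kept (treated as nonzero), so
  "H ≠ 0 ⇒ positive" is literally true after thresholding.
* Degenerate zero-area ground-truth boxes are dropped at read time
  with a warning; zero-area detections are dropped before export.
* Objects whose centers fall outside the heatmap after downsampling
  are skipped with a warning.
* Box coordinates are 0-based, half-open, continuous; VOC's 1-based
  inclusive corners are converted at the file boundary.
* Images are zero-padded to a multiple of 16 (32 for the single-layer
  baseline, which needs a 32× level); detections are clipped back to
  the original extent.
* Bilinear upsampling uses half-pixel centers with border clamping;
  on constant maps it is exactly the identity, which the structural
  tests exploit.

## Known limitations

* `DC` is a plain convolution; a true deformable operator may behave
  differently at full scale.
* The backbone is not the reference network; parameter/FLOP figures
  of the reference are out of scope.
* The pseudo-label refinement loop of the wider auto-labeling system
  is out of scope; only the hook where it would plug in is provided.
* Training is single-CPU, double-precision, one image at a time with
  gradient accumulation — correct and reproducible, not fast beyond
  desk scale.
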