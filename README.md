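# fruitpoint

Anchor-free center-point fruit detection in R, at desk scale — for
plant-phenotyping and auto-labeling workflows where bounding-box
labels are generated by a model rather than drawn by hand, and where
the training data differ from the application data in fruit scale
(the foreground gap) and in background appearance (the background
gap).

## The method

Fruits are localized as peaks of a center heatmap. An image
`I ∈ R^{W×H}` yields per-layer predictions `Ĥ ∈ [0,1]^{H/r × W/r}`
(center probability), a 2-channel size map (box width/height, pixels)
and a 2-channel offset map (sub-pixel center correction). Ground
truth encodes each box as an unnormalized Gaussian with peak 1 at its
center cell, radius tied to box size at IoU 0.7, entries below `2⁻⁷`
set to exactly zero. Two mechanisms address the two gaps:

* **Double prediction layers (DPL).** A deep-to-shallow iterative
  fusion neck, `O(m,n) = DC(O(m,n−1)) + DU(O(2m,n−1))` over factors
  m ∈ {2,4,8,16} (six fusion nodes, no shallow-to-deep edge), emits
  prediction layers at 2× and 4× downsampling. Small objects (area
  < 32², or √(area/WH) < 3%) route to the 2× layer, all others to the
  4× layer.
* **Expanded sample allocation (SA).** Every nonzero-encoded heatmap
  cell is a positive sample, supervised by its own Gaussian code
  under the continuous label value loss

  `L = −(1/N) Σ |H−Ĥ|^β [(1−H) log(1−Ĥ) + H log Ĥ]`,   β = 2,

  which coincides with the modified focal loss (α = 2, β = 4) at
  binary labels and generalizes it to fractional ones.

The package contains the full pipeline: COCO/VOC annotation I/O, a
seeded synthetic orchard-scene generator emulating both gaps, a
self-contained CNN training loop (RcppArmadillo kernels + reverse-mode
tape, Adam, the published schedule), heatmap decoding, cross-layer
merging, pseudo-label export with a refinement hook, and
precision/recall/F1/AP evaluation at the balance point (the threshold
where P ≈ R).

## A worked example

Train the improved configuration on 200 synthetic source-like scenes
(64 × 64 px, 1–3 fruits) and evaluate on 50 held-out scenes of the
same distribution:

```r
library(fruitpoint)

scene <- sceneConfig(width = 64, height = 64, fruits = c(1, 3),
                     scale_regime = "source_like",
                     background_style = "style_A")
train <- generateSamples(scene, 200, seed = 100)
test  <- generateSamples(scene,  50, seed = 900000)

fit <- trainDetector(train, tinyTrainConfig(epochs = 20, seed = 1))

dets <- lapply(test, function(s)
  detectImage(fit$detector, s$image, decodeConfig(score_threshold = 0.05)))
names(dets) <- sprintf("t%03d", seq_along(test))
gts <- lapply(test, function(s) s$annotation); names(gts) <- names(dets)
evaluateDetections(dets, gts)
#> EvalResult (balance point)
#>   precision: 0.9868  recall: 0.9868  F1: 0.9868  AP: 0.9868
#>   balance threshold: 0.1038  (IoU 0.50, 91 curve points)
```

Precision/recall/F1 are reported at the balance point — the
confidence threshold where precision approximately equals recall —
and AP is the area under the all-point interpolated precision–recall
curve at matching IoU 0.5. Here the detector recovers ~99% of fruits
at ~99% precision; AP 0.99 means the ranked detection list is nearly
perfectly ordered.

The four-way ablation (baseline / +DPL / +SA / +DPL+SA) on a
domain-gap benchmark — train source-like/style A, test target-like
(wide scales incl. small fruits)/style B:

```r
generateBenchmark("bench", n_train = 200, n_test = 50,
  trainConfig = scene,
  testConfig = sceneConfig(width = 64, height = 64, fruits = c(1, 3),
                           scale_regime = "target_like",
                           background_style = "style_B"),
  seed = 42)
rep <- ablate("bench", tinyTrainConfig(epochs = 20), seeds = 1L)
rep$means      # P/R/F1/AP per configuration
rep$positives  # mean positive samples per image:
#> baseline     +DPL      +SA  +DPL+SA
#>     1.63     1.63     9.01     9.01
```

A shell entry point wrapping the same functions is installed at
`system.file("scripts", "fruitpoint.R", package = "fruitpoint")` with
subcommands `generate`, `train`, `detect`, `label`, `eval`, `ablate`.

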