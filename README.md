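# ophiocount

Segment-and-count quantification of brittle stars (Ophiuroidea) in 2D
seabed mosaic imagery.

Underwater video transects are stitched into large seabed mosaics, and
marine ecologists need abundance estimates of benthic megafauna from
them. `ophiocount` implements the full workflow for brittle stars —
organisms with a central body disc and five slender arms, frequently
clipped, duplicated, or partly buried in mosaic imagery:

1. **Semantic segmentation.** A pyramid scene-parsing convolutional
   network maps each RGB patch to per-pixel organism probabilities: an
   encoder at output stride 8, pyramid pooling over 1×1/2×2/3×3/6×6
   context bins, 1×1 fusion with dropout, a sigmoid head, and bilinear
   upsampling. Mosaics are tiled by a 288 px sliding window with 144 px
   stride; overlapping predictions are averaged. Training minimizes an
   additive **Jaccard + Focal** loss
   (`L = 1 − (I+s)/(U+s)  +  mean[−α(1−p_t)^γ log p_t]`)
   with Adam at learning rate 0.00012, batch size 8, dropout 0.3. The
   network and its backward passes are implemented natively
   (Rcpp/RcppArmadillo GEMM convolutions); no deep-learning runtime is
   needed.
2. **Instance counting.** The thresholded mask (strict `> 0.5`) is
   cleaned by morphological opening (elliptical kernel (2,2) for disc
   masks, (4,4) for full shapes) and a minimal-area filter (40 px /
   120 px), then touching organisms are split by a watershed on the
   negated Euclidean distance transform, seeded at EDT peaks separated
   by at least 55 px (8-connectivity). The count is the number of
   watershed labels.
3. **Evaluation.** Pixel IOU `= TP/(TP+FN+FP)`, blob-count ratios
   truncated to three decimals, and instance-level strict/forgiving
   accounting (forgiving mode excludes false positives sitting on a
   real organism and false negatives whose central disc is not
   visibly present).

Both annotation variants used in benthic campaigns are supported:
*full shape* (disc + arms) and *disc* (body only). A synthetic scene
generator produces seabed mosaics with exact polygon ground truth in
both variants — including stitching artifacts (clipping, duplicated
instances, hidden discs) — so the entire pipeline is testable without
external data.

## Worked example

Train the desk-scale segmenter on synthetic scenes, predict a held-out
scene, and count:

```r
library(ophiocount)

# 300 training scenes of one 288 px patch each, 2-5 brittle stars per scene
scfg   <- scene_config(width = 288, height = 288, n_stars = c(2, 5),
                       min_center_separation = 60)
scenes <- generate_dataset(scfg, 300, seed = 11)
tp     <- make_training_patches(scenes, "disc", 288L, 288L)

model <- build_segmenter(train_config(seed = 42, epochs = 30L), "desk")
model <- train_segmenter(model, tp$images, tp$masks)
model
#> <seg_model> profile: desk  output stride: 8  parameters: 39,641 (trained)
#>   final loss: 0.1713 after 30 epochs

# held-out scene: predict, evaluate, count
test  <- generate_scene(scene_config(width = 576, height = 576,
                                     n_stars = c(10, 18),
                                     min_center_separation = 60), seed = 99)
prob  <- predict_mosaic(model, test$image)
report <- evaluate_prediction(prob, test$annotations_disc,
                              full_truth = test$annotations_full,
                              disc_truth = test$annotations_disc)
report
#> <eval_report> IOU: 0.79  blobs: 11 / 11  ratio: 1.000
#> <instance_match_report> strict: TP 11 FP 0 FN 0  | forgiving: FP 0 FN 0
```

The IOU is the pixel overlap between the thresholded prediction and
the rasterized disc annotations; `blobs / ground truth` compares the
watershed count with the number of annotated organisms (the ratio is
truncated to 3 decimals, so 337/361 would print as 0.933). On five
such held-out scenes this desk-scale run pools to IOU ≈ 0.83 with all
60 organisms counted (ratio 1.000); training takes about 6 minutes on
one CPU core.

Counting alone, on any binary mask — here the ground-truth disc mask of
a 20-star scene with 50 single-pixel noise dots added (the opening
removes them):

```r
scene <- generate_scene(scene_config(width = 640, height = 640, n_stars = 20,
                                     min_center_separation = 60), seed = 7)
mask  <- rasterize_annotations(scene$annotations_disc, 640, 640)
set.seed(1); mask[sample(length(mask), 50)] <- 1L
count_pipeline(mask, counting_config("disc"))
#> <count_report> 20 blobs ( 20 markers; 51 px removed by opening; 0 blobs under 40 px )
```

A thin CLI over the same functions lives at `inst/cli/ophiocount.R`
(subcommands `simulate`, `enhance`, `train`, `predict`, `count`,
`evaluate`, `run`), driven by the YAML experiment config
(`?experiment_config`).

## Package layout

- `R/synthetic_scenes.R` — scene generator with exact polygon ground truth
- `R/annotations.R` — polygon annotation I/O (JSON) and rasterization
- `R/patching.R` — sliding-window grid planning, slicing, mean reassembly
- `R/enhancement.R` — pluggable pre-processing registry (gamma, CLAHE, stretch)
- `R/losses.R`, `R/segmenter.R`, `src/convnet.cpp` — the segmentation model
- `R/quantify.R`, `src/imageops.cpp` — opening, EDT, peak seeding, watershed
- `R/evaluation.R` — IOU, count ratios, strict/forgiving instance matching
- `R/pipeline.R` — end-to-end experiment driver
- `vignettes/segment-and-count.Rmd` — the model, parameters, and design choices
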