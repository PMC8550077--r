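# ppaseg

Segmentation of **parapapillary atrophy (PPA)** in retinal fundus
photographs. PPA is the crescent- or ring-shaped chorioretinal thinning
adjacent to the optic disc; its extent tracks the severity of high myopia
and glaucomatous damage, so delineating it accurately matters for
screening and follow-up. Segmenting it automatically is hard: the lesion
hugs the much brighter optic disc, its outer boundary is blurred when the
atrophy is still progressing, and high-myopic eyes often show a
tessellated ("leopard") fundus and prominent vessels that confound
appearance cues.

`ppaseg` is an R toolkit for this task, built around an optimized
encoder–decoder network plus everything needed to
exercise it without clinical data: a synthetic fundus generator with exact
ground truth, the full loss stack, the six standard evaluation metrics,
and a training/prediction/evaluation pipeline with a CLI.

## The model

A five-level encoder produces the feature pyramid
{*f*<sub>i</sub>, i = 1..5} at strides /2 … /32, with three interchangeable
backbone families: VGG-style plain convolution blocks, bottleneck residual
blocks, and hierarchical multi-scale residual (Res2Net-style) blocks.
Three decoder-side modules enhance feature expression:

- **Edge attention** on *f*<sub>2</sub>: two 3×3 conv+BN+ReLU stages yield a
  contour feature *e*<sub>att</sub> and an edge logit map *S*<sub>e</sub>,
  supervised by BCE against the boundary truth map *G*<sub>e</sub>.
- **Parallel partial decoder**: *f*<sub>3</sub>–*f*<sub>5</sub> are reduced
  to 32 channels and fused by multiplicative top-down gating into a global
  map *S*<sub>g</sub> = *Pd*(*f*<sub>3</sub>, *f*<sub>4</sub>, *f*<sub>5</sub>);
  low-level fusion is skipped on purpose.
- **Cascaded reverse attention** at levels 5 → 4 → 3: each stage computes
  *A*<sub>i</sub> = 1 − σ(resize(*S*<sub>i+1</sub>)), gates the reduced
  *f*<sub>i</sub> with it (attending to what the coarser map currently
  misses), concatenates the downsampled edge feature
  (*R*<sub>i</sub> = C(*f*<sub>i</sub> ⊙ *A*<sub>i</sub>, Dow(*e*<sub>att</sub>))),
  and emits *S*<sub>i</sub> as a residual refinement of the coarser map.
  The final prediction is σ(up(*S*<sub>3</sub>)).

Training minimizes a deep-supervision total

  *L*<sub>total</sub> = *L*<sub>seg</sub>(*G*<sub>s</sub>, *S*<sub>g</sub><sup>up</sup>) + *L*<sub>edge</sub> + Σ<sub>i=3..5</sub> *L*<sub>seg</sub>(*G*<sub>s</sub>, *S*<sub>i</sub><sup>up</sup>),

where *L*<sub>seg</sub> = *L*<sup>w</sup><sub>IoU</sub> + *L*<sup>w</sup><sub>BCE</sub>
uses per-pixel weights *w* = 1 + 5·|AVG(*G*<sub>s</sub>) − *G*<sub>s</sub>|
(a sliding-window average), which up-weights the "complex" pixels in a band
around the lesion boundary.

There is no deep-learning framework dependency: the package carries its own
compact reverse-mode automatic-differentiation engine with C++
(RcppArmadillo) convolution kernels, so everything above is trainable on a
plain CPU.

## Worked example

Generate one synthetic sample, overfit a tiny network on it, and score the
prediction:

```r
library(ppaseg)

p <- synth_params(canvas_size = 64, disc_radius_range = c(10, 12),
                  ppa_width_fraction_range = c(0.5, 0.65),
                  crescent_angular_span = c(300, 340), vessel_count = 3,
                  blur_sigma = 0.8)
s <- generate_sample(p, seed = 2)
s$ppa_width          # 14.2 px, realized radial lesion extent
s$papilla_diameter   # 22.3 px  -> width > PD/3, i.e. a "large" lesion
s$size_class         # "large"

spec <- backbone_spec("res2net", channels = c(8, 8, 16, 16, 32),
                      res2net_scale = 4, res2net_width = 2)
cfg <- train_config(input_size = 96, backbone = spec, epochs = 200,
                    batch_size = 1, learning_rate = 8e-3, reduce = 8,
                    weight_kernel = 7, seed = 102)
fit <- train_model(cfg, list(s), steps = 200)
range(fit$log$total[c(1, 200)])   # total loss 6.26 -> 2.17

pred <- predict_model(fit, list(s$image))[[1]]
round(confusion_metrics(pred$bin, s$mask), 4)
#> precision sensitivity specificity       iou       dsc
#>    0.9827      0.9919      0.9954    0.9748    0.9873
```

A Dice coefficient of 0.987 on the training sample confirms the network,
loss and optimizer fit one image essentially perfectly — the standard
smoke test for a segmentation stack. Dataset-level training, stratified
evaluation (`evaluate_model` reports all/small/large lesion strata) and
prediction are available both as functions and through the CLI:

```sh
exec/ppa synth --n 40 --size 352 --seed 1 --out-dir data
exec/ppa train --config cfg.yaml
exec/ppa eval --checkpoint run/checkpoint.rds --manifest data/manifest.csv
exec/ppa predict --checkpoint run/checkpoint.rds --image data/img_001.png --out-dir preds
```

## Package layout

- `R/autodiff.R`, `R/nn-layers.R`, `src/conv_ops.cpp` — tensor engine
- `R/backbones.R`, `R/decoder.R` — encoder families and decoder modules
- `R/losses.R`, `R/metrics.R` — loss stack and evaluation statistics
- `R/synthetic.R`, `R/io.R` — synthetic fundus data, PNG/manifest I/O
- `R/train.R`, `exec/ppa` — pipeline and CLI
- `vignettes/ppa-segmentation.Rmd` — methods notes: model assumptions,
  parameter choices, and what the synthetic benchmark does and does not
  show
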