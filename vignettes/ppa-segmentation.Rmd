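---
title: "Methods: attention-enhanced segmentation of parapapillary atrophy"
author: "ppaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-enhanced segmentation of parapapillary atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the modelling choices behind `ppaseg`: the network
and its assumptions, the loss stack, the synthetic benchmark and its
limits, and the numerical decisions that were genuinely open.

## Problem and model

Parapapillary atrophy (PPA) appears as a crescent or ring of chorioretinal
thinning around the optic disc, brighter than the surrounding fundus but
darker than the disc itself. The segmentation difficulty is concentrated
at two places: the inner boundary, where lesion and disc intensities are
close, and the outer boundary, which is diffuse when the atrophy is
progressing. The network addresses both with an encoder–decoder in which a
pretrained-style encoder is augmented by three decoder-side modules.

**Encoder.** Five levels `f1..f5` at strides /2../32. Three families are
implemented behind one interface: a VGG-style stack (two 3×3 conv+BN+ReLU
per stage, 2×2 max-pool closing each stage, features tapped after the
pool), a residual family (stride-2 3×3 transition per stage followed by
bottleneck blocks at constant shape), and a hierarchical-residual family
in which the bottleneck's 3×3 stage is split into `s` width-`w` groups:
group 1 passes through; group *j* ≥ 2 is a 3×3 conv of (slice *j* + output
*j*−1), so the receptive field grows within a single block. With `s = 1`
the single group is convolved directly and the block degenerates exactly
to a plain bottleneck — this degenerate identity is tested. Stems are 3×3
stride-2 convolutions and the default depth is one block per stage: with
no ImageNet pretraining in this build there is no fidelity reason to
reproduce a specific published depth, and the channel counts (which fix
the decoder's interface) default to the canonical family values
64/128/256/512/512 and 64/256/512/1024/2048. Depth, widths, and the `s`,
`w` of the hierarchical block are all configurable. The `pretrained` flag
exists in the spec of a backbone but only `FALSE` is supported; all
results here start from seeded He initialization. Grayscale input is
replicated to three channels so the stem contract is the same for every
input.

**Edge attention** consumes `f2` (stride /4): resolution is high enough to
carry contour detail but half the cost of `f1`. Two 3×3 conv+BN+ReLU
stages produce the 32-channel contour feature `e_att`; a 1×1 projection
yields the edge logit map `S_e`, supervised with mean BCE against the
boundary truth `G_e`.

**Parallel partial decoder.** Only `f3..f5` are fused (low-level fusion
buys little and costs much). Each level is reduced to 32 channels (1×1
conv+BN); the gating is multiplicative and top-down:
`g4' = g4 ⊙ up2(conv(g5))`, `g3' = g3 ⊙ up2(conv(g4)) ⊙ up4(conv(g5))`;
the three maps are upsampled to /8, concatenated, and projected to the
global logit map `S_g`.

**Cascaded reverse attention.** Stages at levels 5, 4, 3. Each computes
`A_i = 1 − σ(resize(S_higher))` — attention on what the coarser prediction
has *not* yet claimed — multiplies it into the reduced `f_i`, concatenates
the average-pool-downsampled `e_att`, refines with two 3×3 conv+BN+ReLU
stages, and adds the 1×1 projection back onto the resized coarser map.
The residual addition is the minimal combination that preserves the global
map's guidance while letting each stage spend capacity only on
corrections; the identity `A_i + σ(resize(S_higher)) = 1` is asserted to
machine precision in the tests. The side-output indexing follows the
levels (`S_5`, `S_4`, `S_3`) so the total loss's sum over i = 3..5 reads
literally; the final prediction is `σ(up(S_3))`.

## Loss stack

Per-pixel weights `w = 1 + 5·|AVG(B) − B|` are computed with a
zero-padded, count-including sliding-window average of the ground-truth
mask (stride 1; the size-preservation condition
`floor((n + 2p − k)/s + 1) = n` is validated). Interior and far-background
pixels get weight 1; pixels whose neighbourhood disagrees with their label
— the boundary band — get up to 6. The default kernel is 31×31 at the
352-px working resolution (a band roughly one lesion-width wide); the
kernel and the gain 5 are configurable.

The weighted IoU loss is `1 − (Σ wPB + 1)/(Σ w(P+B) − Σ wPB + 1)`. The
denominator is the weighted *soft union* (total minus intersection): under
the alternative literal reading "union times weight minus intersection
times weight" a perfect binary prediction would make the denominator
collapse, so the structure-loss convention is the only bounded choice, and
the +1 smoothing keeps the empty-mask case finite. The weighted BCE is the
`w`-weighted *mean* of per-pixel cross-entropy (element-wise division by
the weight would cancel the weighting). BCE probabilities are clamped at
ε = 1e−7. Both BCE-type losses reduce by pixel mean rather than raw sum so
that the five deep-supervision terms stay commensurate across resolutions;
a `reduction = "sum"` flag restores the sum convention. The total loss is
the segmentation loss (weighted IoU + weighted BCE) of the upsampled
`S_g`, `S_5`, `S_4`, `S_3` plus the edge BCE. Every loss is checked
against an independent per-pixel double-loop oracle, and two exhaustive
small-grid properties are enforced: on all 256 pairs of 2×2 binary grids
the weighted IoU loss is zero iff prediction equals mask, and on all 512
3×3 masks flipping any single correct pixel never decreases the
segmentation loss.

## Tensor engine

No deep-learning framework is available to R here, and the network *is*
the contribution, so the package carries a small reverse-mode autodiff
engine: dynamic graphs over `[H, W, C]` arrays, with conv2d as C++
im2col+GEMM (forward, input/weight/bias backward), batch norm over the
spatial grid (one sample per step, so batch statistics are per-channel
spatial statistics; running stats serve eval mode), 2×2 max pooling,
and bilinear resizing/adaptive average pooling expressed as separable
linear maps `Y = A X Bᵀ` whose backward is the transposed map. Every
operator's gradient is verified against central finite differences in the
test suite. Optimization is Adam (default) or SGD; one CPU; everything is
seeded and bit-reproducible.

## Synthetic benchmark

The generator emulates the features that make PPA segmentation hard:
a bright, mildly elliptical disc; an adjacent crescent of intermediate
brightness whose radial width beyond the disc rim is drawn as a fraction
of the papilla diameter (PD), tapering with a cosine profile over a
configurable angular span; dark vessel curves leaving the disc;
low-frequency speckle mimicking a tessellated fundus; Gaussian blur and
pixel noise. Masks are exact by construction: the lesion is defined in
disc-centred polar coordinates strictly outside the disc boundary (so
lesion and disc masks never overlap), the edge truth is the 1-pixel inner
morphological boundary (cross-shaped structuring element) of the lesion
mask — a deterministic stand-in for the hand-drawn contours clinical
datasets use — and the realized radial width is measured on the rasterized
mask. Lesion-size stratification follows the one-third rule: a lesion is
*small* when its maximal radial extent beyond the rim is ≤ PD/3, with PD
the maximal disc-mask chord; the radial-extent reading is one admissible
operationalization of comparing "PPA" to PD, chosen because the
clinically described quantity is the crescent's width. The 4:1
train/test split is a seeded uniform permutation.

What passing tests on this benchmark shows: the architecture wiring, loss
stack, optimizer and evaluation are correct and can drive the network to
fit fundus-like geometry. What it does not show: performance on real
photographs — the generator has no camera model, no pathology variety, no
pigmentation or illumination artifacts, and its lesions are smooth
parametric shapes. Dataset-scale accuracy claims require clinical data.

## Problem sizes and defaults

The default working resolution is 352 px (divisible by 32, the stride of
level 5). The single-sample overfit check trains the tiny configuration
(channels 8/8/16/16/32, decoder width 8, hierarchical backbone s = 4,
w = 2) on one 64-px sample at a 96-px working resolution for 200 Adam
steps at learning rate 8e−3 with a 7-px weight kernel. The working
resolution exceeds the canvas because the final side output lives at /8:
12×12 logits place the 0.5-contour with sub-pixel accuracy after bilinear
upsampling, where an 8×8 grid visibly quantizes the boundary. Training
hyperparameters for real use (Adam, lr 1e−4, batch 8, 50 epochs) are
conventional defaults for this architecture family, not tuned values, and
all are configurable. Evaluation binarizes at 0.5 and macro-averages
per-image metrics within each stratum (a pixel-pooled mode is provided);
per-image AUC is the midrank Mann–Whitney statistic, and single-class
images are excluded from the AUC average and tallied.

## Known limitations

- Batch statistics come from one sample at a time (instance-style norm);
  with the default batch accumulation the gradient is exact but the
  normalizer is per-sample.
- The engine is CPU-only and dense; it is sized for method verification
  and small studies, not for 288-image training runs at 352 px, which
  would take days rather than hours.
- Pretrained encoder weights are not loadable in this build; accuracy
  benefits reported for pretrained stems elsewhere do not transfer.
- The generator's lesions are simply-connected smooth crescents; real PPA
  with irregular, multi-lobed geometry is outside its support.
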