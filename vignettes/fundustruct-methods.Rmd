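---
title: "Structure-aware glaucoma classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware glaucoma classification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundustruct)
```

## The problem and the approach

Glaucoma damages the optic nerve slowly and irreversibly; on a fundus
photograph its most reliable early sign is an enlarged optic cup relative to
the optic disc (a raised cup-to-disc ratio). Ophthalmologists therefore read
fundus images *structurally*: they look at the disc, the cup, and the retinal
vasculature, not at raw pixels. `fundustruct` reproduces that reading as a
pipeline:

1. **Preprocessing** — isolate the eye region from the black camera
   background, enhance local contrast on the luminance channel only, restore
   the black background.
2. **Structure extraction** — segment the retinal vessels with a residual
   U-Net applied patch-wise, and localise the optic disc with a brightness
   percentile mask plus a circular Hough transform.
3. **Classification** — feed the preprocessed image and the two extracted
   structures into a three-branch CNN whose structure branches are fused with
   the image branch by scaled dot-product attention, followed by a softmax
   over {glaucoma, normal}. An attention-free variant that simply
   concatenates the three branch outputs serves as the ablation control.

Everything runs on a small, fully deterministic CPU network engine built into
the package (no external deep-learning runtime, no downloaded weights), so
every number the package produces is reproducible from a seed.

## Preprocessing

* **Background mask.** The image is converted to grey with the standard luma
  weights (0.299, 0.587, 0.114) and thresholded: a pixel is eye-region
  foreground when its grey value is strictly above 40 (on 0..255). The
  threshold is exposed as `background_threshold`.
* **Mean fill.** Histogram equalisation across the hard black border would
  mostly stretch the border/eye contrast, so before enhancement the
  background is filled with the mean colour of the *foreground* pixels
  (including the background in the mean would darken it toward black, which
  is exactly the artefact the fill is meant to remove).
* **CLAHE on L.** The image is converted to CIELab (D65 white point, 8-bit
  sRGB scaling) and contrast-limited adaptive histogram equalisation is
  applied to the L channel only (`EBImage::clahe`; clip limit 2, 8 x 8
  tiles — the common defaults, both exposed), leaving chromaticity
  untouched. A flat field stays spatially flat under this operation; its
  level may shift by a few grey values, as with any clip-redistributed
  CLAHE.
* **Black background reapplied.** The mask from step 1 zeroes the background
  again, so downstream stages see the original composition.

Rotation augmentation (default step 10 degrees, giving 36 copies per image —
30 training images per class become 1080, 2 validation images become 72) is
implemented as inverse-mapped bilinear rotation about the image centre with
black fill. Rotations by multiples of 90 degrees are bit-exact on square
integer rasters; the train/validation split is drawn *before* augmentation so
no rotated copy of a validation image can leak into training.

## Optic-disc extraction

Only right-eye images are modelled, so the disc sits in the right (temporal)
image half, which is cropped first (columns `[W/2, W)`, half-open). The top
3.5% brightest pixels of the CIELab L channel form a binary mask: the
threshold is the k-th largest L value with `k = ceiling(0.035 * N)` and ties
are all kept, which makes the rule deterministic without an arbitrary pixel
order (a constant image selects every pixel). The circle is then found by a
circular Hough transform and its radius extended by 40 px so the disc is
never clipped; everything outside is blacked out and the crop resized to
64 x 64.

Two implementation details matter and were genuinely open choices:

* **The percentile mask is a quota, not a segmentation.** When the disc is
  larger than the 3.5% quota the mask keeps only a scattered subset of disc
  pixels (for strongly cupped discs, essentially the cup). The detector
  therefore closes the mask morphologically (5-px disc kernel) before
  extracting boundary pixels, so speckled regions become solid and only true
  outer contours vote.
* **Candidate selection.** The vote peaks of every candidate radius (top two
  per radius, non-max suppressed) are re-scored by *angular support* — the
  fraction of sampled directions in which the circle lands on a dilated
  boundary pixel, with out-of-frame directions counting as unsupported. Per
  centre the detected radius is the largest one within 90% of that centre's
  peak support, which resolves solid blobs to their outer envelope. If the
  vote peak is weak or the best circle's support is below 0.5, the detector
  falls back to the mask centroid with radius `sqrt(area / pi)` and records
  `source = "centroid-fallback"`, so the pipeline never aborts on an atypical
  disc. Radius bounds default to [15, 120] px at 512-pixel scale and scale
  with the input.

On seeded phantoms the detector recovers disc centres with sub-pixel median
error and radii within a few pixels; the residual failure modes are exactly
the two the quota predicts (a very bright central field competing with a
small disc, and large-cup discs where the mask contains no rim information),
and both are rare enough that the median stays within tolerance.

## Vessel segmentation

The segmenter is a residual U-Net: three encoder residual blocks (default
filters 16/32/64) with 2 x 2 max-pooling, a two-convolution bridge (128),
and three decoder residual blocks with nearest-neighbour upsampling and one
skip concatenation per level — six residual blocks and three skips, which
the test suite verifies by graph introspection rather than by trusting the
constructor. Each residual block is conv–BN–ReLU, conv–BN, an identity
shortcut (1 x 1 projection on channel mismatch), then ReLU; the head is a
1 x 1 convolution with a sigmoid.

Inference follows the tiling contract: grey conversion, bilinear resize to
256 x 256, sixteen non-overlapping 64 x 64 patches in row-major order,
per-patch inference, stitching (a bit-exact inverse of the tiling), and a
final resize to 64 x 64 for the classifier. No overlap blending is used
because the tiling is exact.

Training data are 64 x 64 crops of the synthetic phantoms at native
resolution, where vessels are 2–6 px wide; at least half the crops are
rejection-sampled to contain at least 1% vessel pixels. The loss is binary
cross-entropy with the vessel class up-weighted (`pos_weight = 8`, chosen
for the ~3–5% vessel pixel share; without it the optimiser converges to the
background class and thin-structure recovery stalls). Dice on held-out
patches is reported pooled over the whole held-out set, which keeps
near-empty crops from dominating the summary.

## The classifier and its ablation

Each of the three inputs (preprocessed image, vessel probability map, disc
crop; all 64 x 64 x 1, scaled to [0, 1]) passes through its own CNN branch:
four 3 x 3 ReLU convolutions with filters growing 64-128-256-512, with
BatchNorm + 2 x 2 max-pool after the second and fourth convolution, so the
branch output is 16 x 16 x 512.

**Fusion.** In attention mode, the vessel and disc branch outputs are each
fused with the *image* branch by scaled dot-product attention over the 256
flattened spatial positions: queries come from the image branch, keys and
values from the structure branch, weights are `softmax(q · k / sqrt(C))`
(no learned projections — the minimal form consistent with using one
attention layer per structure). The two attended maps are concatenated
(2 x 512 channels). The wiring of the image branch into the fusion was an
open design point; querying by the image branch is isolated behind the
`fusion` argument so alternatives can be added without touching the head.
In the concat ablation the three branch outputs are concatenated directly
(3 x 512 channels) with no attention; everything else is identical.

**Head.** BatchNorm, 2 x 2 max-pool, three convolutions with filters
2048/4096/4096 — the last with a 1 x 1 kernel — BatchNorm, flatten, a dense
ReLU layer (256), and a dense softmax over the two classes. "ReLU and
Softmax" as the final activations is read as ReLU on the penultimate dense
layer and softmax on the output, since a softmax stacked on a ReLU of the
same layer is not meaningful.

Training uses Adam (decoupled weight decay 1e-4 on weights only, learning
rate decaying smoothly to a third over the run) on categorical
cross-entropy with a seeded stratified validation split; the seed fixes
initialisation, the split, shuffling, and augmentation draws, so identical
configurations reproduce identical histories and weights bit-for-bit on the
same platform. Two regularisers matter at this data scale, where a handful
of base images make pixel-signature memorisation the path of least
resistance: Gaussian input jitter (sd 0.05 on the [0, 1] maps, training
batches only) and modality dropout with a warm-up schedule — for the first
40% of the epochs every training sample's image and vessel inputs are
dropped entirely, so the whole architecture first learns the disc pathway
(the branch that carries the diagnostic signal and converges reliably),
after which the dropout relaxes to 0.2 and the other modalities phase in.
Without the warm-up, whether a run discovers the cup-to-disc signal or
memorises pixel signatures is close to a coin flip; with it, held-out
accuracy is stable across seeds. A random per-sample zoom augmentation is
available (`zoom_range`) but off by default: it removes absolute-size
shortcuts, but slows convergence beyond what a 20-epoch budget repays.

The pipeline's desk-scale head uses `global_pool = TRUE` and 1 x 1 head
kernels: global average pooling turns the final feature map into
per-channel activation counts, and 1 x 1 head convolutions act as
per-position MLPs that preserve that count structure. Both choices encode
the right inductive bias for a count-ratio signal (the share of cup-bright
positions among disc-bright positions) and were what let the attention
model generalise from a few dozen phantoms; the flatten head
with 3 x 3 kernels remains the constructor default.

**Evaluation-mode statistics.** Batch-norm running averages accumulated with
momentum during training never quite match the population statistics of the
final weights; channels whose variance collapses toward zero then amplify
the train/eval activation mismatch by `1/sqrt(var)`, which can visibly
corrupt evaluation-mode predictions in small networks. The engine therefore
re-estimates every batch-norm layer's statistics under the final weights
(equal-weight averaging of batch statistics over the training set — the
"precise BN" recalibration used by large-scale vision frameworks) before
each validation evaluation and at the end of training.

## The phantom generator

The generator is the package's test bed, not an afterthought: every stage's
quantitative check runs against its ground truth. A phantom is a 512 x 512
RGB raster with a black background outside a circular eye field (radius
0.47 x size), an orange-toned field with radial shading (35% darker at the
rim), a bright disc blob placed in the temporal half (radius uniform in
[20, 60] px) with a brighter concentric cup, and a branching vessel tree
walked out from the disc centre (6–12 primary branches, widths 2–6 px,
random-walk curvature, one optional child branch each) rasterised into both
the image and a ground-truth binary mask. Gaussian noise (sd 4 grey levels)
is added inside the eye field only. The class signal is geometric: the
cup-to-disc ratio is drawn from [0.2, 0.4] for normals and [0.7, 0.9] for
glaucoma — disjoint by construction, mirroring the clinical sign, and
verifiably recoverable by a hand-written one-feature classifier before any
CNN is trained (the share of cup-bright pixels among disc-bright pixels
inside the detected circle tracks the squared ratio and separates the
classes at threshold 0.3).

What the phantoms deliberately do **not** model: camera vignetting and
colour variation across devices, glare and other quality defects, texture of
the neuroretinal rim, macula, and pathology beyond the cup/disc signal.
Passing tests on phantoms therefore demonstrate that the pipeline's
machinery — masking, enhancement, detection, segmentation, fusion,
optimisation — works end to end on data with a known answer; they say
nothing about accuracy on clinical photographs, which would require real
labelled data and realistic weights.

## Problem sizes and numerical choices

The constructors default to the full-scale architecture
(branch 64/128/256/512, head 2048/4096/4096, ResU-Net 16/32/64 + 128), and
the architecture checks introspect exactly those. For *training* runs the
pipeline defaults are deliberately desk-scale — branch 8/8/16/32, head
32/32/32 with 1 x 1 kernels and global average pooling, dense 32/2,
ResU-Net 8/16/32 + 64, 32 phantoms per class, 8 validation phantoms per
class, 90-degree augmentation for training and validation, 20 epochs,
batch 8, Adam at 0.01 with smooth decay — sized so a full end-to-end run
(two classifier trainings plus vessel training) completes in well under
half an hour on one CPU core. The phantom signal is coarse enough that
these widths saturate it; the full widths would add runtime, not
information, at this problem size.

Other numerical choices: He initialisation; BatchNorm with momentum 0.9 and
eps 1e-5, batch statistics in training and running statistics at inference;
max-pool ties broken by first-position priority; softmax and sigmoid output
layers are loss-fused (gradients taken at the pre-activation) for stability;
probabilities are clamped at 1e-12 (cross-entropy) and 1e-7 (BCE) before
logs; undefined evaluation metrics (zero denominators) are reported as `NaN`
with a warning rather than silently coerced to 0, because a silent 0 would
corrupt exactly the ablation comparisons the package exists to make. ROC
curves sweep every unique score as a threshold; the trapezoidal AUC equals
the Mann–Whitney concordance probability with ties counted 1/2, and the two
implementations are kept separate so one can check the other.

## Known limitations

* The network engine is single-threaded R + BLAS with compiled im2col
  kernels; it is meant for desk-scale reproducibility, not GPU-scale
  training.
* Gradient checking covers every layer type, but BatchNorm running
  statistics make train-mode and eval-mode outputs differ early in training;
  with very few batches per epoch the validation metrics are noisy.
* The Hough detector assumes one dominant circular structure in the right
  half; images with multiple comparably bright circular regions resolve to
  the best-supported one, which on a small minority of phantoms is the
  central field rather than a small disc.
* Only PNG roundtrips are guaranteed bit-exact; JPEG is accepted on input
  only.
* Left-eye images are out of scope (the crop convention is temporal-right).
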