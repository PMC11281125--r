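# fundustruct

Structure-aware glaucoma screening from retinal fundus photographs, as a
reproducible R package.

Glaucoma's earliest photographic sign is an enlarged optic cup relative to the
optic disc (a raised cup-to-disc ratio), read together with the retinal
vasculature. `fundustruct` implements a classification pipeline that mirrors
that clinical reading instead of feeding raw pixels to a network:

1. **Preprocessing** — the eye region is separated from the black camera
   background (grey threshold 40), the background is filled with the mean
   foreground colour so local histogram equalisation is not dominated by the
   border, CLAHE is applied to the CIELab luminance channel only, and the
   black background is reapplied.
2. **Retinal-vessel segmentation** — a residual U-Net (six residual blocks,
   three skip connections, a bridge) applied to sixteen 64 × 64 patches of the
   256 × 256 grey image, stitched back losslessly.
3. **Optic-disc extraction** — right-half crop, top 3.5 % brightest CIELab-L
   pixels, circular Hough transform with the radius extended by 40 px, and
   blackout outside the detected circle.
4. **Classification** — a three-branch CNN (preprocessed image, vessel map,
   disc crop; branch filters 64–128–256–512) fused by scaled dot-product
   attention with the image branch as query, head convolutions
   2048/4096/4096 (final kernel 1 × 1), and a softmax over
   {glaucoma, normal}; per-query attention weights are nonnegative and sum
   to one. A concatenation-only variant of the same model is the ablation
   control.
5. **Evaluation** — per-class sensitivity / precision / F1 and a
   threshold-sweep ROC with trapezoidal AUC (equal to the Mann–Whitney
   concordance probability, ties counted ½).

All networks run on a small deterministic CPU engine built into the package
(im2col + BLAS, with compiled C++ kernels for the hot loops), so there are no
external weights or deep-learning runtimes: every result is reproducible from
a seed. A seeded phantom-fundus generator — black background, shaded eye
field, bright disc with class-dependent cup, branching vessel tree with a
ground-truth mask — gives every stage a self-contained test bed.

## Worked example

```r
library(fundustruct)

# a labelled phantom: image + ground-truth vessel mask + disc geometry
ph <- generate_phantom("glaucoma", phantom_params(), seed = 7)
ph$image
#> <fundus_image 512 x 512 x 3, values 0..255>

pre <- preprocess_fundus(ph$image)          # threshold/fill/CLAHE/reapply
disc <- extract_disc_region(pre$image)      # 64 x 64 grey crop
attr(disc, "circle")
#> <disc_circle (hough) centre (217.0, 107.0), radius 68.0 (detected 28.0)>
```

The detected centre (217, 107) in right-half coordinates and pre-extension
radius 28 px sit within a few pixels of the phantom's constructed disc
(centre row 217, column 362 − 256 = 106, radius 24.6); the returned radius is
the detected one plus the fixed 40 px margin.

```r
# end-to-end: synthesis, preprocessing, vessel + disc extraction, training
# of the attention model and its concat ablation, evaluation (~17 min, 1 CPU)
res <- run_pipeline(pipeline_config(list(seed = 2024L)), out_dir = "run1")
res$reports$attention
#> <eval_report n=64 fusion=attention AUC=1.00>
#>   glaucoma sensitivity 1.00  precision 0.94  F1 0.97
#>   normal   sensitivity 0.94  precision 1.00  F1 0.97
```

The report shows per-class sensitivity, precision and F1 on the held-out
validation phantoms (8 per class, each in 4 rotations), plus the ROC AUC with
glaucoma as the positive class; the concat ablation's report
(`res$reports$concat`) lands far below it on the same data, which is the
expected signature of the attention fusion. `run1/` receives the resolved
`config.yaml`, training histories, detected disc circles, and the JSON
reports for both fusion modes.

A command-line wrapper with per-stage subcommands (`synth`, `preprocess`,
`extract-disc`, `train-vessels`, `segment-vessels`, `train`, `predict`,
`evaluate`, `run`) is installed at `exec/fundustruct`.

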