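# lesionkit

Multiclass skin-lesion analysis at desk scale, in R. `lesionkit`
implements a complete dermoscopy pipeline — contrast enhancement, deep
saliency segmentation, metaheuristic feature selection, correlation-based
feature fusion, and kernel extreme learning machine (KELM) classification
— together with a synthetic fixture generator, so every stage runs,
trains, and is testable with no external imaging data. It is aimed at
researchers who want a transparent, fully inspectable reference
implementation of this pipeline family for method study, ablation, and
teaching, rather than a clinical tool.

## The methods

**Enhancement (hybrid local contrast stretching).** On the luminance
channel: locate the dark lesion band [k1, kn] on the 256-level histogram
(k1 = lowest occupied level, kn = Otsu split), equalize inside the band
weighted by the normalized image variance w = sigma^2 / (255/2)^2, blend
50/50 with the original, then apply two gain-search passes that score
candidates `clip(mu + g (x - mu))`, g = 1..5, by Otsu between-class
variance and keep the arg-max.

**Deep saliency segmentation.** A ten-layer CNN (conv 3x3x64, conv
3x3x64, 2x2 max-pool, conv 3x3x128, FC softmax; SGD with momentum,
`v <- m v - r grad`) is trained on image-level labels. The saliency map
fuses all 128 third-convolution channels (per-channel min-max, mean,
bilinear upsample), is homogenized over SLIC superpixels of the enhanced
image, thresholded at its mean (`xi_seg = 1` where `xi_sal > tau`,
`tau = mean(xi_sal)`), hole-filled and reduced to the largest component;
boundaries come from Chan-Vese-refined contour tracing.

**IMFO feature selection.** Moths carry continuous positions; the fitness
of a gated subset is `r * Error + (1 - r) * |selected| / Dim` with a
cubic-SVM one-vs-all hold-out error and r = 0.9. Positions binarize
through a sigmoid mean-gate, spiral toward flames
(`d e^{bl} cos(2 pi l) + flame`, flame count annealing to 1), and an
entropy gate over the descending-sorted flames re-defines their
selections each iteration. A plain-MFO baseline and an exhaustive-search
oracle are included.

**Fusion and KELM.** Two selected streams are padded to equal width
(per-sample entropy padding), positionally Pearson-correlated, and every
pair with rho >= 0.5 contributes both columns to the fused matrix. KELM
solves `(I/C + Omega) beta = T` on the kernel Gram matrix and predicts by
arg-max score; reports follow the row-percentage confusion convention
with macro sensitivity and FNR = 100 - sensitivity.

## Worked example

```r
library(lesionkit)

# a 64x64 synthetic lesion with ground truth
im <- generate_lesion_image(lesion_image_spec(lesion_contrast = 0.4, seed = 7))
enh <- enhance(im$image)

# desk-scale segmentation experiment: 60 images, 50/50 split
ex <- run_segmentation_experiment(n_images = 60, seed = 1)
print(ex)
#> Segmentation experiment (with enhancement, 30 test images):
#>   mean accuracy 93.53% | mean error 6.47% | mean Dice 0.8239

# wrapper feature selection against the exhaustive optimum
fd <- generate_feature_dataset(feature_dataset_spec(
  n_samples_per_class = c(60, 60), n_features = 12, n_informative = 4,
  class_separation = 2, seed = 1))
cfg <- fitness_config(r_weight = 0.9, seed = 1)
sel <- select_features(fd$features, fd$labels, cfg, n_iter = 50, seed = 2)
print(sel)
#> IMFO feature selection: 3 of 12 features | fitness 0.0250 | 50 iterations
exhaustive_oracle(fd$features, fd$labels, cfg)$best_fitness
#> [1] 0.025

# KELM on the selected features
sp <- split_dataset(fd$features, fd$labels, 0.7, seed = 1)
m <- kelm(sp$train$x[, sel$selected_indices], sp$train$labels)
print(evaluate_classification(predict(m, sp$test$x[, sel$selected_indices]),
                              sp$test$labels))
#> Classification: accuracy 94.44% | sensitivity 94.44% | FNR 5.56%
```

The segmentation report reads: on the held-out half of the fixture set,
93.5% of pixels agree with the ground-truth masks and the mean Dice
overlap is 0.82. The selection block shows the optimizer reaching the exhaustive
optimum of the wrapper fitness (0.025 = 0.9 * 0 error + 0.1 * 3/12
features); the final block classifies the held-out samples with the
selected columns only.

A command-line interface wrapping the same functions is installed at
`exec/lesionkit` (verbs: `fixtures`, `enhance`, `segment`, `features`,
`select`, `fuse`, `classify`, `run-all`).

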