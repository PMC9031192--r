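# otospectra

Color-channel dependence analysis for CNN-based diagnosis of middle and
external ear conditions from otoscopy video.

Otoscopy videos show the ear canal and tympanic membrane, and the tissue
features that separate diagnoses live in different parts of the visible
spectrum: membrane vascularity (chronic otitis media, COM) absorbs strongly
in the green band where hemoglobin absorbs, middle-ear fluid (otitis media
with effusion, OME) is best seen through the red band's deeper penetration,
and an earwax plug is a broadband occlusion. `otospectra` implements, end to
end, a study design that quantifies this: train one convolutional network
per spectral rendering of the same image set, compare the classifiers, and
inspect where each network looks.

The pipeline, from raw video to comparison table:

1. **Domain filtering** — otoscopy recordings start before the specula enters
   the ear and end after it leaves. Assuming the central frame shows the
   membrane, every frame's per-channel intensity histogram `p` is compared to
   the central frame's `q` by the Kullback-Leibler divergence
   `D(q ‖ p) = Σ q log(q/p)`; frames diverging beyond a threshold are
   discarded.
2. **Blur rejection** — the variance of the response to the 3×3 Laplacian
   kernel scores sharpness; uniformly blurred frames score low and are
   discarded.
3. **Keyframe summarization** — usable frames are embedded with PCA
   (default 20 components) and clustered with k-means (`k = 100`); the frame
   nearest each centroid is kept, giving a balanced, non-redundant image set
   per video.
4. **Spectral rendering** — each image is rendered in seven channel modes:
   weighted grayscale `g = 0.2989 R + 0.5870 G + 0.1140 B`, single-channel
   grayscale R/G/B, and 3-channel images with two channels zeroed.
5. **Classification** — a VGG-16-style CNN (3×3 stride-1 same-padding
   convolutions, 2×2 stride-2 max pooling, ReLU, softmax; Adam, on-the-fly
   augmentation), trained from scratch per mode, plus a desk-scale `tiny`
   variant that trains on a CPU in seconds.
6. **Evaluation** — one-vs-all confusion-matrix reduction; macro-averaged
   accuracy, sensitivity, specificity, precision and F1
   (`F1 = 2pr/(p+r)` on the macro precision/recall); per-class ROC curves.
7. **Grad-CAM** — gradient-weighted class activation maps from the last
   convolutional block localize the image regions driving each prediction.

Because clinical otoscopy datasets are not openly deposited, the package
ships a seeded synthetic otoscopy-video generator (`synthetic_spec()`,
`generate_dataset()`) that emulates the acquisition artifacts above and
injects each class's discriminative feature predominantly into a configurable
color channel — so the whole pipeline is exercised against known ground
truth, including the headline property that the model trained on the signal
channel outperforms the others.

## Worked example

```r
library(otospectra)

spec <- synthetic_spec(n_videos_per_class = 3, frames_per_video = 40,
                       frame_shape = c(96, 128, 3), lead_frames = 6,
                       blur_fraction = 0.15, signal_channel = "G", seed = 11)
cfg <- study_config(
  spec = spec,
  kf_cfg = keyframe_config(n_components = 10, k = 20, downsample = 32, seed = 1),
  modes = c("gray_g", "gray_r", "gray_b"),
  train_cfg = train_config(learning_rate = 1e-3, batch_size = 16,
                           epochs = 20, n_trials = 3, seed = 1),
  test_n = 15, gradcam_n = 20, seed = 11)
bundle <- run_study(cfg)

sapply(bundle$reports, function(r) round(r$macro, 3))
#>             gray_g gray_r gray_b
#> accuracy     0.975  0.744  0.733
#> sensitivity  0.950  0.489  0.467
#> specificity  0.983  0.830  0.822
#> precision    0.968  0.372  0.363
#> f1           0.959  0.369  0.379
```

With the class signal injected into the green channel, the `gray_g` model
reaches macro-F1 0.96 while the red- and blue-channel models stay below
0.40 — the channel-dependence the study design is built to detect. The
bundle also carries the cross-mode comparison table (`bundle$comparison`),
per-trial reports, trained models, and Grad-CAM localization statistics
(`bundle$gradcam`: mean heatmap intensity inside the ground-truth feature
region was ~0.71 versus ~0.35 outside in this run).

```r
m <- build_vgg16(c(224, 224, 3), n_classes = 1000)
m$param_count
#> [1] 138357544
```

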