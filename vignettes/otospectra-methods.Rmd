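---
title: "Methods: spectral-channel analysis of CNN otoscopy diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-channel analysis of CNN otoscopy diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the pipeline answers

Four ear conditions — normal, chronic otitis media (COM), otitis media with
effusion (OME) and earwax plug — are diagnosed from the appearance of the
ear canal and tympanic membrane. Tissue optics make that appearance
wavelength-dependent: hemoglobin absorbs around 500–600 nm, so vascular
changes are most visible in the green channel; longer red wavelengths
penetrate the membrane and reveal the tympanic cavity behind it. The
pipeline quantifies this dependence operationally: the same image set is
rendered in seven channel modes, one CNN is trained per mode under an
identical protocol, and the classifiers are compared on held-out data.

## Preprocessing model and assumptions

**Domain filter.** The filter assumes the *central frame* of each video
shows the anatomical domain of interest (the recording starts before
insertion and ends after removal of the specula, so junk concentrates at the
ends). Each frame is scored against the central frame by the
Kullback-Leibler divergence of per-channel intensity histograms. Choices
that the method statement leaves open, fixed here once:

* **Direction**: the score is `D(central ‖ frame)`, summed over the three
  RGB channels. This penalizes frames that lack mass where the reference has
  it; any fixed convention works once the threshold is calibrated to it.
* **Histogram resolution**: 32 bins per channel over the 0–255 range, with
  `epsilon = 1e-8` added to every bin before normalization so the divergence
  is always finite.
* **Threshold semantics**: the discard rule is stated in the literature as a
  score "falling below a threshold", i.e. treating the score as a
  similarity. KL is a dissimilarity, so `kl_threshold` is exposed as the
  *maximum allowed divergence* (keep when `score <= kl_threshold`). The
  central frame is always kept. No universal default exists — the threshold
  depends on camera, lighting and compression — so it is a required
  parameter, with `calibrate_threshold()` providing a sweep against data
  with known flags (the midpoint between the two score populations, with
  the achieved agreement reported).

**Blur filter.** Sharpness is the sample variance of the frame's response to
the 3×3 Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]`. The channel feeding
the Laplacian is not fixed by the method statement; the default is the green
channel (the largest luminance contribution). Borders are reflect-padded.
Only uniform blur is modeled — motion blur is out of scope. The filter runs
*after* the domain filter, matching the stated stage order.

**Keyframe summarization.** Usable frames are converted to weighted
grayscale, downsampled to 64×64 (PCA on full-resolution frames would cost
far more and the frame-to-frame dissimilarity that drives the clustering is
low-frequency), flattened, and embedded with PCA. The default keeps 20
components — on otoscopy-like footage this captures roughly 80% of the
variance, and `variance_target = 0.8` is offered as the alternative
selection rule. k-means (k-means++ seeding, 10 restarts, Lloyd iterations,
seeded) partitions the embeddings into `k = 100` clusters; from each cluster
the frame nearest its centroid is selected, ties broken to the lowest
original frame index, output in temporal order. Videos with at most `k`
usable frames return all frames. Empty clusters — possible when `k`
approaches the frame count — are repaired by topping up with the frames
farthest from their assigned centroid, the points a re-seeded cluster would
capture.

## Spectral modes

Seven renderings: `gray_weighted` (`g = 0.2989R + 0.5870G + 0.1140B`),
`gray_r` / `gray_g` / `gray_b` (one channel as a single-plane image), and
`masked_r` / `masked_g` / `masked_b` (three channels with two zeroed — the
network input stays 3-channel but carries information in one). The weighted
output is kept in floating point; nothing is rounded to integers, so channel
comparisons are not confounded by quantization. Pixels are scaled by 1/255
at network input. The wavelength bands (red 618–780 nm, green 497–570 nm,
blue 427–476 nm) are carried as metadata only — no spectral physics is
computed.

## Network and training protocol

The classifier is a VGG-16 layout: five convolution blocks of
64/128/256/512/512 filters with 2-2-3-3-3 layers, all 3×3 stride-1
same-padding with ReLU, a 2×2 stride-2 max pool per block, two fully
connected layers (4096/4096 in the canonical form) and a softmax output.
For a 224×224 input the final feature map is 7×7×512, and the canonical
3-channel/1000-class instantiation counts 138,357,544 trainable parameters.
The convolution, pooling, dense, softmax, backpropagation and Adam steps are
implemented in the package (im2col patch extraction feeding BLAS matrix
multiplications), which also gives Grad-CAM direct access to internal
gradients. The backward pass is verified against central-difference
numerical gradients in the test suite.

Protocol defaults in `train_config()`: Adam at learning rate 1e-5, batch
size 32, 100 epochs, stratified 80/20 train/validation split, and 10 trials
with per-trial derived seeds (each trial re-splits and re-initializes);
reported metrics are trial means. Choices the protocol statement leaves
open: categorical cross-entropy loss (the standard pairing with softmax),
Glorot-uniform initialization, bilinear resizing to the input tensor, and
augmentation ranges of ±15° rotation, ±10% zoom and horizontal/vertical
flips at p = 0.5, applied on the fly to training batches only.

Full VGG-16 training is GPU-scale; desk-scale experiments use the `tiny`
variant, which obeys the same layout contract at reduced size — 32×32
input, three blocks of 8/16/32 filters, one hidden FC of 64 (~39k
parameters). The tiny study conditions used by the bundled experiments are
learning rate 1e-3, batch size 16, 20–30 epochs: a from-scratch net this
small on 32×32 inputs needs a larger step size than the full protocol's
1e-5, and these values were fixed once as the tiny-variant conditions.

## Evaluation

The `c`-class confusion matrix (rows = truth, columns = prediction) is
reduced one-vs-all: `TP_i = m[i,i]`, `FN_i = rowSums(m)[i] − TP_i`,
`FP_i = colSums(m)[i] − TP_i`, `TN_i` the remainder. Macro accuracy,
sensitivity, specificity and precision are unweighted means of the
per-class binary formulas; the headline F1 is the harmonic mean of *macro*
precision and *macro* recall (matching the single printed F1 of the study
design), with per-class F1 also reported. Per-class terms with a zero
denominator (a class never predicted, or absent from the truth) are defined
as 0 and flagged with a warning — conservative and conventional. ROC curves
are one-vs-all threshold sweeps with trapezoidal AUC; the implementation is
cross-checked against `pROC` in the tests. Class order is fixed as
(normal, COM, OME, earwax).

## Grad-CAM

The map is built from the last convolutional layer of the last block
(before its pool): the gradient of the *pre-softmax* class score — not the
softmax probability, whose saturation can zero the gradients, and whose
shift-invariance the tests assert — is spatially averaged into per-channel
weights, the weighted feature-map sum is rectified, normalized by its
maximum, and bilinearly upsampled to the input size. An identically zero
rectified map is returned flagged `degenerate` rather than divided by zero.

## The synthetic generator

`synthetic_spec()` defines the study conditions the pipeline is exercised
under. Each video is a circular ear-canal scene (radial-gradient disc on a
dark surround) with a per-class geometric feature: radial streaks for COM
(vascularity), a lower-half fill for OME (fluid level), a central occluding
blob for earwax, a clean disc for normal. A feature pixel gains
`base_contrast` (default 15 intensity units) in *all* channels — the feature
is visible but chromatically neutral — plus `signal_strength` (default 40)
in `signal_channel` only, which is what localizes the *discriminative*
contrast in one channel. Acquisition artifacts are generated with ground
truth: `lead_frames` out-of-domain frames at each end (bright low-frequency
noise fields whose histogram is far from the scene's, making the domain
filter separable by construction), a `blur_fraction` share of in-domain
frames Gaussian-blurred with `blur_sigma = 3` px *after* pixel noise is
added (so blur genuinely suppresses the Laplacian response), and additive
Gaussian pixel noise (`noise_sigma = 8`). Defaults mirror consumer
digital-otoscope acquisition: 480×640 frames at 20 fps; tests and the
bundled experiments shrink to 96×128 frames, 40-frame videos, 3 videos per
class for tractability. Per-video seeds are derived deterministically from
the master seed and the class/video indices, so identical specs give
bit-identical output.

What the generator does *not* emulate: photorealistic membrane texture,
specular highlights, otoscope optics, illumination drift, compression
artifacts, inter-patient anatomical variation, or correlated label noise.
Passing the bundled experiments therefore shows the *pipeline* recovers a
known channel-localized signal under controlled conditions — it says
nothing about clinical accuracy on real otoscopy data.

## Scaled-down study conditions

The bundled channel-dependence experiment (test suite and acceptance
script) uses: 3 videos per class of 40 frames (6 lead frames each end, 15%
blurred), keyframe summarization to 20 frames per video, modes `gray_g` /
`gray_r` / `gray_b`, the tiny architecture, 3 trials of 20 epochs, and 15
test images per class. The split arithmetic is additionally checked at the
clinical database scale (5,500 images per class, 500 test, 80/20 →
4,000/1,000/500). These sizes are the package's desk-scale study
conditions, chosen once; the full clinical protocol remains the
`train_config()` default.

## Known limitations

* Image-level splitting matches the study design it follows, but frames of
  one video can land in different splits; within-video redundancy then
  inflates absolute test metrics. The synthetic experiments inherit this
  caveat deliberately. Split-by-video is the stricter alternative and can
  be had by splitting videos before keyframing.
* The domain filter trusts the central-frame assumption unconditionally; a
  video whose central frame is itself out of domain would calibrate wrongly.
* The CNN is pure R: fast enough for the tiny variant and correct for the
  full layout, but not a practical engine for 224×224 VGG-16 training.
* KL thresholds and blur thresholds do not transfer across acquisition
  setups; they are data-dependent and must be calibrated.
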