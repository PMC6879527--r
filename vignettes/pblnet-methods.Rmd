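---
title: "Detecting periodontal bone loss per tooth: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting periodontal bone loss per tooth: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Periodontal bone loss (PBL) — resorption of the alveolar bone supporting the
teeth — is a radiographic hallmark of periodontitis. On a panoramic dental
radiograph it appears as focal darkening at the tooth neck, where the
alveolar crest has receded. Clinically useful computer assistance must
report *which tooth* is affected, so `pblnet` frames detection as 32-way
multi-label classification over the FDI (ISO-3950) dentition chart, built
up through a multi-phase pipeline:

1. **Annotation aggregation.** Several clinicians (default `L = 5`)
   independently mask lesions and label teeth. Tooth labels are aggregated
   by thresholded voting (`aggregate_tooth_labels()`, default threshold 3 of
   5 — majority voting); lesion masks are aggregated pixelwise with
   threshold 1 (`aggregate_lesion_mask()`), i.e. the union, which maximises
   the recall of lesion pixels available for representation learning.
2. **Teeth-region (ROI) segmentation.** A U-shaped encoder-decoder
   segments the teeth region from the variable-field-of-view radiograph,
   trained with binary cross-entropy plus an L2 penalty
   (`train_roi_segmenter()`). The predicted mask is post-processed by hole
   filling and convex hull (`postprocess_mask()`), then the bounding box is
   cropped, resized, background-zeroed and z-scored (`extract_roi()`).
3. **Lesion pre-training.** The same U-shape is trained to segment the
   union lesion masks inside ROI crops with the pixel focal loss at
   `gamma = 2` (`train_lesion_segmenter()`), addressing the extreme
   foreground/background imbalance of small focal lesions. Its encoder is
   exported (`encoder_weights()`) as the transferable representation.
4. **Tooth classification.** Two classifiers share one architecture — the
   transferred encoder, two further convolution blocks, global average
   pooling, two fully connected layers and 32 sigmoid outputs. The
   generalist `fA` reads the full crop; the premolar/molar specialist `fB`
   reads vertical half-crops with incisor/canine labels masked to zero.
   Training minimises the tooth focal loss plus a small auxiliary
   co-occurrence loss (below). At inference, incisor/canine scores come
   from `fA`; premolar/molar scores are the convex combination
   `alpha * fA + (1 - alpha) * fB` with `alpha = 0.1`
   (`ensemble_predict()`).
5. **Evaluation.** Micro-averaged AUROC, F1, sensitivity, specificity, PPV
   and NPV over all (radiograph, tooth) decisions, with operating points
   selected on validation data: `balanced` maximises F1;
   `high_sensitivity` matches the worst clinician's specificity;
   `high_specificity` matches the worst clinician's sensitivity
   (`select_operating_point()`).

# Losses

With clamped probabilities \(\hat y \in [\epsilon, 1-\epsilon]\),
\(\epsilon = 10^{-7}\):

* ROI segmenter: \(-\frac1n\sum_i [y_i\log\hat y_i + (1-y_i)\log(1-\hat y_i)]
  + \frac{\lambda}{2n}\sum_k w_k^2\), \(\lambda = 10^{-4}\).
* Lesion segmenter: pixel focal loss
  \(-\frac1n\sum_i [(1-\hat y_i)^\gamma y_i \log\hat y_i +
  \hat y_i^\gamma (1-y_i)\log(1-\hat y_i)]\), \(\gamma = 2\). At
  \(\gamma = 0\) this is exactly the mean binary cross-entropy; a
  well-classified positive at \(\hat y = 0.9\) is down-weighted by
  \((1-0.9)^2 = 10^{-2}\).
* Classifier: the focal term applied per output node (mean over the batch,
  summed over the 32 nodes) plus the L2 penalty added once. The auxiliary
  target for jaw-half labels \(y\) and co-occurrence matrix \(C\) is
  \(c_j = \frac1Z \sum_{j'} y_{j'} C_{jj'}\), \(Z = \max_j\) of the sums, so
  \(c \in [0,1]^{16}\) with maximum exactly 1 whenever any tooth is
  positive; an all-zero \(y\) yields \(c = 0\) (the natural target for a
  lesion-free jaw; \(Z\) would otherwise be 0). The auxiliary loss
  \(\sum_j (c_j - \hat y_j)^2\) is computed separately for the upper and
  lower jaw against that jaw's own matrix and added with weight
  \(\beta = 0.01\).

One normalisation point is worth making explicit: the classifier loss is
written per output node, so its \(\gamma = 0\) reduction equals the sum over
nodes of per-node mean cross-entropies (32 times the overall mean). The
choice only rescales gradients — equivalent to a learning-rate change — and
the per-node form is the literal reading of a loss "used for each output
node". The batch reduction of the auxiliary term is a mean over samples,
keeping its scale stable across batch sizes.

The co-occurrence matrix itself (`build_cooccurrence()`) is the per-jaw
joint-occurrence frequency \(C_{jj'} = \#\{i: y_{ij} = y_{ij'} = 1\}/N\).
Counts, frequencies or any positive rescaling are equivalent under the
max-normalisation of the target, so the simplest symmetric choice is used.

# The network engine

No deep-learning framework is assumed: the package ships a compact CNN
engine (compiled kernels for same-padded convolution, 2x2 max pooling and
nearest-neighbour upsampling, with R orchestration) implementing the
U-shape, the classifier head, Adam, and backpropagation. Gradients are
verified against finite differences in the test suite to about `1e-8`
relative error. Training is plain sequential Adam with batch size 1; with a
fixed seed every run is bit-reproducible, which the tests rely on. The
decoder upsamples by nearest neighbour and concatenates skip connections;
the published template's exact layer table is not reproduced — depth and
width are configurable (`segmenter_config()`), defaulting to depth 4 /
16 base channels at full scale.

Grad-CAM (`gradcam()`) targets the last convolution before global average
pooling; because gradients are spatially constant after the pooling layer,
the channel weights have a closed form, and the rectified weighted channel
sum is upsampled to the input and max-normalised to 1.

# What the synthetic generator emulates

The clinical dataset behind this kind of study is not publicly available,
so `generate_case()` renders study material with the properties the
pipeline actually exercises:

* a bright arch-shaped teeth band inside a darker exposed field whose
  margins vary per image (field-of-view variability), with Gaussian
  intensity noise;
* 32 tooth-like ellipses in the FDI layout (upper/lower rows of 16, the
  patient's right on the image's left), centres recorded;
* dark wedge lesions at the necks of diseased teeth, sized by a severity
  draw — mimicking the appearance of vertical/horizontal bone loss without
  claiming anatomical realism;
* per-tooth disease labels from a one-dimensional autologistic chain along
  each jaw's arch: base rates graded by tooth type (incisor 0.30, canine
  0.28, premolar 0.22, molar 0.18, third molar 0.12), adjacency coupling
  of 1.5 logits, and coupling damped by 0.3 at links touching a third
  molar. This is the simplest model that reproduces the banded adjacency
  structure of clinical co-occurrence matrices, including the relative
  isolation of third molars. Coupling 0 gives exactly independent labels,
  which the tests verify empirically.
* simulated annotators: labels flipped per tooth at rate 0.1 (rates
  \(\ge 0.5\) are rejected since they void the majority-vote guarantee),
  masks dilated/eroded by one pixel, lesion components omitted, and
  occasional spurious blobs added.

The generator does **not** emulate anatomy (roots, crestal bone texture,
overlapping structures), device-specific artifacts, severity grades, or
annotator biases that correlate across clinicians. Passing tests therefore
demonstrate that the pipeline's machinery — aggregation, segmentation,
transfer, ensembling, evaluation — works end to end on data with the right
statistical shape, not that clinical performance figures transfer.

# Desk-scale study conditions

Tests and the acceptance script run the whole pipeline at 64 x 128
resolution on one CPU. The sizes were fixed once as the smallest
configuration on which each stage demonstrably learns: ROI segmentation
with 40 training / 8 validation images, depth 2, 8 base channels, 8
epochs; lesion pre-training with 40 crops, depth 3, 6 epochs; classifiers
with 100 training / 10 validation / 30 test crops, 16 epochs; learning rate
`1e-3` for all desk-scale runs (the full-scale defaults `1e-4`/`1e-5` suit
the much larger networks). The classifier uses encoder depth 3 so that the
network's positional sensitivity (which enters through zero padding at the
borders) spans the whole crop; at depth 2 the centre of a 128-wide crop is
positionally ambiguous to a global-average-pooled head.

Augmentation at desk scale is photometric only. The full-scale defaults
(rotation up to 10 degrees, shifts up to 10%) displace teeth by more than
one tooth pitch (about 8 px at this resolution) while the 32 labels stay
fixed, destroying the correspondence between output slots and image
positions; at clinical resolution with a deep network the same transforms
are mild relative to tooth size. The lesion segmenter keeps full
augmentation, because its masks transform jointly with the image.

Numerical conventions: probabilities clamped at `1e-7` in every
log-likelihood; `dice(empty, empty) = 1`; zero-variance z-scoring returns
zeros rather than dividing by zero; bilinear resize clamps sampling
coordinates to the frame (so constants stay constant), while geometric
augmentation fills with background 0 and resamples masks by nearest
neighbour; bounding boxes are axis-aligned, zero-based, half-open;
operating-point ties break toward the higher (more conservative)
threshold.

Open choices resolved here: z-score statistics use in-mask pixels only;
`fB` sees disjoint halves (columns `[0, w/2)` and `[w/2, w)`), accepting
possible midline truncation; the patient's right (quadrants 1 and 4) is
read from the left image half, a documented constant shared by the
generator and the ensemble; `fB` keeps a 32-way head with non-target labels
zeroed rather than a 20-way head, which keeps encoder transfer uniform;
joint training of `fA` and `fB` is realised as alternating per-sample
updates over one shared shuffled pass; each radiograph contributes one
`fA` sample and two `fB` half-samples per epoch.

# A worked desk-scale example

```{r, eval = FALSE}
library(pblnet)

cfg <- synthetic_config(image_shape = c(64, 128))
set.seed(1)
cases <- lapply(1:60, function(i) generate_case(cfg))

prep <- lapply(cases, function(cs) {
  crop <- extract_roi(cs$image, postprocess_mask(cs$roi_mask),
                      out_shape = c(64, 128))
  list(crop = crop,
       lesion = roi_warp_mask(aggregate_lesion_mask(cs$annotator_masks, 1),
                              crop),
       labels = aggregate_tooth_labels(cs$annotator_labels, 3))
})

seg_cfg <- segmenter_config(c(64, 128), depth = 3, base_channels = 8,
                            epochs = 6, learning_rate = 1e-3)
les <- train_lesion_segmenter(lapply(prep[1:40], function(p)
  list(image = p$crop$image, mask = p$lesion)), seg_cfg, seed = 1)

cooc <- build_cooccurrence(do.call(rbind, lapply(prep[1:40], `[[`, "labels")))
clf <- train_tooth_classifiers(lapply(prep[1:40], function(p)
  list(image = p$crop, labels = p$labels)),
  les$encoder, cooc,
  classifier_config(c(64, 128), depth = 3, base_channels = 8,
                    epochs = 12, learning_rate = 1e-3),
  seed = 1, augmentation = augment_params(0, 0, 0.15))

scores <- predict(clf, prep[[50]]$crop)
head(sort(scores, decreasing = TRUE))
```

# Known limitations

* The engine is CPU-bound and desk-scale; full-resolution (512 x 1024)
  training is out of reach without a GPU framework.
* Global average pooling limits spatial precision; per-tooth localisation
  rests on padding-induced position cues and is the weakest link at small
  widths.
* The synthetic annotator model is independent across annotators;
  correlated reader bias is not represented, so clinician-comparison
  numbers on synthetic data are optimistic about aggregation benefits.
* Third molars are rare under the default prevalence and remain the
  hardest teeth, mirroring the clinical situation.
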