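---
title: "Classifying shoulder implant manufacturers with DRE-Net"
author: "DRENet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying shoulder implant manufacturers with DRE-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a total or reverse total shoulder arthroplasty has to be revised,
the surgical team must know which manufacturer's prosthesis is in place:
instrumentation and revision procedures are manufacturer-specific, and the
original records are frequently unavailable. In practice the implant is
identified by visually comparing a plain radiograph against an implant
atlas — slow, expert-dependent and error-prone. The task is hard for
automated methods too: radiographs of implants by one manufacturer vary
widely across models (high intra-class variance), while implants from
different manufacturers — most notably Depuy and Zimmer — can look very
similar (low inter-class variance), and the available public data are small
(597 images: 83 Cofield, 294 Depuy, 71 Tornier, 149 Zimmer).

`DRENet` implements a feature-ensemble classifier for this problem together
with everything needed to evaluate it: rotational augmentation, closed- and
open-world protocols, metric computation, a PCA + KNN feature baseline, and
a synthetic radiograph generator so that the entire pipeline can be
exercised and tested without any external data.

## The model

Two truncated convolutional backbones process the same 224×224×3 input:

* a **modified ResNet-50** — the stock bottleneck architecture with its
  fully-connected, softmax and classification layers removed, ending at the
  7×7 global average pool, which yields the feature vector
  $f_1 \in \mathbb{R}^{2048}$;
* a **modified DenseNet-201** — growth rate 32, block sizes 6/12/48/32,
  halving transitions, likewise truncated at global average pooling,
  yielding $f_2 \in \mathbb{R}^{1920}$.

The **shallow concatenation network (SCN)** concatenates
$f = (f_1, f_2) \in \mathbb{R}^{3968}$ (ResNet first; the order is
statistically irrelevant but frozen for reproducibility) and applies a
single fully-connected layer
$z_j = \sum_l w_{j,l} f_l + b_j$ followed by the softmax
$p_i = e^{z_i} / \sum_j e^{z_j}$, computed with max-subtraction (identical
mathematically, stable numerically). Training minimizes the cross-entropy
$\mathrm{CE} = -\log p_{t}$ of the true class $t$. Argmax ties break toward
the lowest class index, with the global class order fixed as (Cofield,
Depuy, Tornier, Zimmer).

Because no deep-learning framework is required at runtime, the forward and
backward passes of both backbones run on a compact single-precision engine
written with RcppArmadillo: convolutions are lowered to BLAS matrix
products via an im2col transform, and the layer graph supports
convolution, batch normalization (frozen statistics with trainable affine
terms — the standard fine-tuning treatment, and exactly the identity map at
random initialization), ReLU, max/average pooling, residual addition,
channel concatenation and dense layers.

## Rotational invariant augmentation

Training images are rotated about the image centre through
$\{0°, 10°, \dots, 350°\}$ — 36 poses per image *including* the original.
This multiplier matches the protocol accounting used throughout the
package (538 training images expand to 19,368; 377 to 13,572). Rotations
at multiples of 90° are exact array reindexings; other angles use
inverse-mapping bilinear interpolation about the geometric centre
$((H-1)/2, (W-1)/2)$, with same-size output, corner cropping, and black
(0) fill for exposed corners — conventional choices, stated here because
the rotation resampling is otherwise underdetermined. Test images are
never augmented.

## Training regimes

`trainConfig()` defaults follow the standard recipe for this model family:
mini-batch 10, learning rate 0.001, momentum 0.9, L2 regularization
0.0001. *Sequential* training fine-tunes each backbone independently for
13 epochs behind a temporary 4-class head, discards the heads, freezes the
backbones, extracts concatenated features once, and trains the SCN for 9
epochs; stage 3 can only touch the head. *End-to-end* training updates
everything jointly for 7 epochs. A learning-rate drop factor of 0.1 is
recorded in the configuration, but no drop period is applied by default
because none is specified for this recipe; `lrDropPeriod` enables a step
schedule. 25% of training data can be held out as a monitoring validation
split (no early stopping).

Two numerical safeguards, both package design choices:

* **Gradient clipping** (`gradClipNorm`, default 10, global L2 norm) is
  applied only in loops that update backbone parameters. Randomly
  initialized 50–200 layer networks produce enormous early gradients
  (activations grow roughly geometrically through unnormalized residual
  sums); clipping keeps fine-tuning finite and is inert for well-scaled
  problems. The SCN-only trainer never clips.
* **SCN preconditioning** (`standardizeSCN`, default on): the head is
  trained on per-dimension standardized features and the affine scaling is
  absorbed back into the returned weights, so the deployed head still maps
  raw 3968-d features to logits. This is purely a conditioning device —
  concatenated backbone features mix coordinate scales that differ by
  orders of magnitude, which would otherwise force per-problem learning
  rates.

## Evaluation protocols

**Closed world.** Stratified 10-fold cross-validation: within each class,
samples are shuffled (seeded) and dealt into folds whose sizes differ by at
most one, remainders going to the earliest folds. Each fold's training
portion is RIA-expanded, the model trained, and the untouched test portion
classified; per-fold metrics are averaged.

**Metrics.** Precision is the macro mean of $TP_k/(TP_k+FP_k)$ and the
F1-score is always $2PR/(P+R)$. Accuracy and recall each have two
documented modes, because the conventional definitions and certain printed
formula variants disagree: the default accuracy is overall accuracy
(trace/total), with an `eq4_literal` mode computing the macro mean of
one-vs-rest binary accuracies (for $K=4$ the two are related affinely:
literal $= 100 - (100 - \mathrm{overall})/2$, since each error contributes
exactly one FP and one FN); the default recall is the macro mean of
$TP_k/(TP_k+FN_k)$, with an `eq7_literal` mode computing $TP_k/(TP_k+TN_k)$
— preserved for auditability although it is not a recall. Per-class terms
with zero denominators contribute 0 with a warning. Two methods are
compared by pooling their four metrics across the 10 folds into 40 paired
values and applying a two-tailed paired t-test (all-zero differences give
p = 1; constant non-zero differences give p = 0).

**Open world.** Classes seen in training and testing are disjoint: the
four runs train on (C1,C2), (C3,C4), (C3,C1), (C4,C2) and test on the
complementary pairs. A query image's 3968-d feature is taken at the SCN's
concatenation layer and assigned to the testing class whose mean feature
vector is nearest in L2 distance. Reference means are computed from the
*unaugmented* testing-class images, and **leave-one-out**: a query is never
part of its own reference mean, the most conservative reading since
self-inclusion would leak the query into its reference. New manufacturers
are supported by registering a mean vector and label
(`registerClass()`) — no retraining. No rejection threshold is applied:
the nearest class always wins.

**PCA + KNN baseline.** Concatenation-layer features are centred and
eigendecomposed; eigenvector signs are fixed (first non-zero coordinate
positive) for reproducibility. `lambdaSweep()` scores each eigenvector
count $\lambda$ by seeded k-fold cross-validated KNN accuracy computed on
training features only (the PCA is refit within each fold), with ties going
to the smallest $\lambda$. The KNN neighbourhood size defaults to
$K = 1$ — the smallest assumption, since no value is prescribed — and tie
handling is deterministic (stable distance ordering; vote ties to the
lowest label).

## The synthetic phantom generator

`phantomSpec()`/`renderPhantom()` draw a rod-shaped prosthesis — stem plus
class-specific head — on a vertical soft-tissue-like intensity gradient
with additive Gaussian noise, clipped to [0, 255]:

* **C1** short stem, rounded head, collar;
* **C2** long wide stem, large hemispherical head;
* **C3** short thin stem, small angled head;
* **C4** hemispherical head close to C2 but with a narrower stem —
  deliberately confusable with C2 to reproduce the Depuy/Zimmer similarity
  structure of the real data.

In *easy* mode the class-conditional geometry ranges are pairwise
disjoint; *hard* mode narrows the C2/C4 gap until the ranges nearly touch.
Poses vary by ±15° rotation and ±8 px offset; intensities and the
background gradient are drawn from fixed ranges; noise SD defaults to 8
intensity levels. Rendering is deterministic in (spec, seed), per-sample
seeds derive from the master seed by an order-independent integer hash,
and regeneration is byte-identical. The generator emulates pose, geometry,
intensity texture and class-similarity structure, but **not** beam
hardening, scatter, bone texture or projection effects of real
radiography — tests passing on phantoms demonstrate that the pipeline's
machinery is correct and that its discriminative path works when class
geometry carries the signal; they do not certify real-world accuracy.

## Reduced-scale study conditions

The full protocol (597 images, ImageNet-initialized backbones, 36-fold
augmentation, 10 folds) is a GPU-scale computation. The package's built-in
study — used by the test suite and the acceptance script — runs a reduced
protocol chosen once as a CPU-scale analogue:

* 30 easy-mode phantoms per class (120 images; roughly 60 train / 60 test
  under the 2-fold closed-world split);
* frozen randomly-initialized backbones (`epochsBackbone = 0`): the
  untrained deep features act as a fixed representation and only the SCN
  head is trained per fold. Features are computed once per distinct image
  and cached;
* augmentation disabled in the reduced runs: with a frozen representation
  and a linear head on well-separated phantom geometry, the rotated
  copies add extraction cost without changing the conclusions the reduced
  study is meant to support;
* three seeds, median reported.

Under these conditions the closed-world median accuracy is expected at or
above 90% and the open-world average at or above 85%, with the (C4,C2)
open-world run visibly weakest — the phantom analogue of the Depuy/Zimmer
similarity.

## Worked example

```{r example}
library(DRENet)

dir <- tempfile()
manifest <- generateDataset(c(C1 = 30, C2 = 30, C3 = 30, C4 = 30), dir,
                            masterSeed = 11)
resnet <- buildExtractor("resnet50_modified", seed = 101)
densenet <- buildExtractor("densenet201_modified", seed = 202)

res <- runClosedWorld(manifest, trainConfig(epochsBackbone = 0), k = 2,
                      seed = 1, resnet = resnet, densenet = densenet,
                      ria = FALSE)
res$mean
res$confusion

ow <- runOpenWorld(manifest, config = trainConfig(epochsBackbone = 0),
                   seed = 1, resnet = resnet, densenet = densenet,
                   ria = FALSE)
ow$mean
```

## Known limitations

* `pretrained = TRUE` requires externally supplied weights; nothing is
  downloaded. All bundled results use seeded random initialization, which
  is sufficient for the architecture contracts and the phantom study but
  far below fine-tuned transfer-learning accuracy on real radiographs.
* Batch normalization runs with frozen statistics; true mini-batch
  statistics are not implemented.
* The cross-entropy of a zero true-class probability is capped by
  evaluating $-\log \max(p, 10^{-300})$.
* Activation maps are channel means of post-activation feature maps
  (min–max normalized, bilinearly upsampled); with randomly initialized
  weights the DenseNet's final 7×7 stage shows border artifacts, so the
  localization demonstration uses the ResNet stage maps.
* The open-world "Total" accounting of augmented plus test images is not
  reported; only original-image counts are used.
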