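---
title: "Methods: a confounder-suppressed genopathomic TMB biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a confounder-suppressed genopathomic TMB biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumor mutational burden (TMB) predicts benefit from immune checkpoint
inhibition, but measuring it requires exome or panel sequencing. H&E-stained
diagnostic slides are acquired for every patient, and mutational load leaves
morphological traces in them. `piter` implements a pipeline that turns
whole-slide images into a patient-level probability of TMB-high status (the
PITER score): tile the slide into tissue patches, normalize stain appearance,
classify each patch with a convolutional network trained on patient-level TMB
labels, pool the patch probabilities by the median, and threshold at a cutoff
chosen by the Youden index.

The statistical obstacle is confounding. Because patches inherit their
label from the slide, anything that identifies the slide — scanner color
response, stain batch, section thickness — is a shortcut the classifier can
use instead of morphology. The package's training scheme, adversarial
confounder suppression (AdvCS), attaches a second, gradient-reversed head to
the network that tries to classify the slide of origin; the reversal makes
the shared representation *bad* at slide identification while the task head
keeps it good at TMB discrimination.

## Model and training objective

Each patch `x` is mapped by a compact convolutional backbone to a
representation `h(x)` feeding two linear softmax heads: a task head (TMB
high/low, or normal/LUAD/LUSC for the tumor-filter deployment) and an
optional confounder head over the `N` training slide IDs. The training loss
on a batch is

    L = CE_task + alpha * CE_confounder

where both terms are cross-entropies. The gradient reversal sits between the
representation and the confounder head: on the forward pass it is the
identity, on the backward pass it multiplies the gradient by `-lambda`. The
confounder head therefore descends its cross-entropy while the backbone
ascends it, pushing `h` toward slide-invariance. `alpha` (default 0.5)
weighs the adversarial term; `lambda` (default 1) scales the reversed
gradient and ramps linearly from 0 over the run (`lambda_warmup = 1`), so
the task is learned first and invariance is enforced progressively.

Optimization follows a fixed recipe: Adam with a cosine learning-rate
schedule from 6e-4 down to 6e-6 across the run, decoupled weight decay 0.01
on weight matrices, batches of 32 patches drawn with replacement from a
single slide, and augmentation by random 90-degree rotations plus horizontal
flips with probability 0.5. Targets are the patient-level TMB labels
propagated to all of the patient's patches.

### The backbone

No GPU framework is assumed: the backbone is a deliberately small CNN
(5x5 stride-2 convolution, layer normalization, ReLU, global average
pooling, one hidden dense layer with layer normalization) whose forward and
backward passes are explicit, BLAS-backed matrix algebra. Two choices
matter:

* **Layer normalization, not batch normalization.** Training batches come
  from a single slide, so batch statistics coincide with slide statistics:
  batch normalization would subtract the slide-level (and hence
  class-level) signal during training and then mismatch at evaluation.
  Per-sample normalization is batch-composition-independent and identical
  in training and evaluation.
* **Normalization at all.** With the small fixed learning rates of the
  cosine recipe and a short run, an unnormalized network barely moves from
  its initialization; normalized pre-activations make the feature scale
  (and thus the effective logit learning speed) independent of the weight
  init.

Heads are zero-initialized, so an untrained model emits uniform
probabilities. Every analytic gradient, including the reversal and the
normalization backward passes, is verified against finite differences in the
test suite.

### Making the adversary effective

Two properties of Adam-style training make a naively trained confounder
head useless at desk scale, and the package works around both:

* Adam's per-parameter normalization makes the head's learning speed
  independent of `alpha`, and a zero-initialized 20-class softmax head
  cannot reach useful accuracy within a short schedule at `lr <= 6e-4`.
  The head is therefore *refit to convergence* — a ridge-regularized
  multinomial logistic regression on the current representations of all
  training patches — every `conf_head_refit_batches` batches (default
  every 25). Between refits it is held fixed (`conf_head_lr_mult = 0` by
  default keeps the in-loop updates off; setting it > 0 re-enables them).
* A *fully saturated* refit head emits near-zero softmax gradients, giving
  the reversal nothing to push against, while an over-trained one starts
  exploiting the subtle morphological features that carry the label itself
  (labels are slide-level, so slide identity strictly contains the label).
  The refit's ridge penalty (`conf_head_decay`, default 1) keeps the head
  leaning on the high-separation color directions — exactly the shortcut
  that should be suppressed — and soft enough to emit usable gradients.

This tension is intrinsic to the setting, not an implementation artifact:
because each slide has one label, a perfect slide-ID-invariant
representation would also be label-invariant. The adversary must be strong
on the high-amplitude confounder and weak on the subtle signal, which is
what the regularized refit provides.

## The synthetic cohort generator

Every stage is testable without external data through a generator that
emulates the two properties of real cohorts the pipeline must handle:

* **A TMB-linked texture signal.** Patches are eosin-pink background noise
  with hematoxylin-like nuclei (Gaussian-profile ellipses). For TMB-high
  patients, nucleus density and radius increase with `signal_strength`,
  while the per-nucleus stain contrast decreases by the inverse of the
  total-ink factor. The expected mean color of a patch is therefore
  class-independent: the signal lives in the *granularity* of the texture.
  This ink-neutral construction keeps the morphological signal orthogonal
  to additive color shifts, mirroring the real situation in which staining
  intensity is a property of the slide, not of the tumor's mutational
  load. Blob counts stay verifiable by an independent connected-component
  oracle.
* **A slide-level color confound.** Each slide receives one additive RGB
  shift: a sign (correlated with the patient label at
  `confound_label_corr`, stratified so the realized correlation matches
  the nominal one), a fixed hue direction, and a per-slide jitter that
  makes slide identity linearly decodable from mean color. Setting the
  correlation high in training and zero in validation reproduces the
  shortcut-learning failure: a plain classifier rides the color and
  transfers at chance.

Labels are assigned at the patient level with stratified prevalence; TMB
values are drawn consistently with the 206-mutation exome cutoff; optional
survival columns use exponential draws (median ~600 days for TMB-high
vs ~250 for TMB-low under checkpoint inhibition, censored at 3 years).

What the generator does *not* emulate: nuclear atypia, tissue architecture,
multiple tissue types per slide (so no honest 3-class tumor-filter training
set exists at desk scale — the filtering rule is tested on constructed
probability matrices), pen marks and blur, and pyramidal file formats.
Passing tests therefore demonstrate the mechanics and the confounder
arithmetic of the pipeline, not clinical performance.

## Preprocessing choices

* **Foreground**: HSV saturation above 0.07 after a 3x3 box blur; stained
  tissue is saturated, glass is not.
* **Tiling**: non-overlapping grid (stride = patch size by default),
  0-based `(x, y)` = (column, row) offsets, partial edge tiles dropped,
  tiles kept when mask coverage >= 0.5.
* **Magnification**: area averaging for integer shrink factors, bilinear
  otherwise; no upsampling.
* **Stain normalization**: Macenko optical-density construction. Pixels
  with OD norm above 0.15 are projected on the top-2 principal plane of
  the OD cloud; stain vectors are the 1st/99th percentile angular
  extremes; the more blue-heavy OD column is called hematoxylin.
  Normalization deconvolves against the source basis, rescales by the 99th
  percentile concentrations, and recomposes with the target basis. The OD
  norm criterion (rather than a per-channel threshold) keeps
  eosin-dominant pixels, whose red OD is small, in the fit.

## Scoring and evaluation

Patient scores pool all tumor patches across the patient's slides into one
bag and take the median (even counts: mean of the central pair). The
tumor filter keeps a patch when its total tumor probability `1 - p_normal`
is at least `tau = 0.5` *and* the argmax class matches the patient's
histology. The decision cutoff maximizes Youden's J over midpoints between
adjacent distinct scores (plus infinite sentinels), ties resolved toward
the larger cutoff, with `score >= cutoff` called high — the `>=` convention
matches the panel-mode TMB rule (>= 10 mut/Mb; the 206 exome-count cutoff is
treated the same way).

Evaluation reports AUC (Mann-Whitney pair statistic; the trapezoidal area
of the reported curve equals it to numerical precision), a percentile
bootstrap CI resampling patients (nearest-rank order statistics on the
replicate vector; 10,000 replicates by default, 2,000 in the timed
acceptance run), Spearman correlation with the continuous TMB value
(Pearson on mid-ranks), and, when survival columns are present,
Kaplan-Meier curves per biomarker group with a log-rank test (the standard
companion test; the hand product-limit and O-E implementations are
cross-checked against `survival` in the tests). Heatmaps bin patch
probabilities on the tile grid with a viridis map, so warm yellow marks
predicted TMB-high regions.

## Problem sizes and desk-scale conditions

The bundled experiments run on one CPU. The confounded-cohort experiment
uses 20 training slides x 50 patches, 50 validation patients x 25 patches,
64 px patches, 10 epochs of 150 batches, and full confound strength;
signal-recovery runs use the same training size with 40 validation
patients and the default one-pass epoch. An epoch is a schedule unit of
`batches_per_epoch` batches (patches are sampled with replacement); the
default is one expected pass over the tissue patches, and the confounded
experiment raises it so the adversarial minimax has enough steps to
equilibrate within the fixed 10-epoch schedule.

At this scale the adversarial comparison remains seed-noisy: the
validation AUC of a 50-patient cohort has a standard error near 0.08, and
the minimax sometimes sacrifices task accuracy for invariance. The
acceptance suite therefore phrases the mechanism property as a majority
vote across five seeded repetitions rather than a per-seed guarantee.

## Known limitations

* Only the compact CNN backbone is implemented; the `backbone_spec`
  architecture field is the seam for heavier backbones, and no pretrained
  weights are shipped.
* The tumor filter cannot be trained end-to-end on synthetic data (single
  tissue type); `score_patients` accepts `tumornet = NULL`.
* Slide images are plain PNGs; pyramidal SVS reading is out of scope.
* Multivariable survival adjustment is delegated to the `survival` package
  and is not part of the tested core.
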