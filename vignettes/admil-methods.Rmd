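---
title: "Attention-based deep MIL for cytology images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based deep MIL for cytology images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

In cytological screening, a specimen from one patient yields many microscopy
fields containing hundreds of cells, and the clinically available label --
benign or malignant -- attaches to the *case*, not to individual cells.
Labelling every cell is impractical, and experts themselves judge specimens
comprehensively rather than cell by cell. This package implements weakly
supervised classification of such specimens with attention-based deep
multiple instance learning (AD MIL): specimen images are tiled into small
patch *instances*, all retained instances of a case form a *bag* carrying the
single case label, and a neural model classifies bags while learning which
instances matter.

## Model

Each instance $I_k$ (a fixed-size RGB patch, pixels scaled to $[0,1]$) is
mapped by a CNN backbone to a feature vector $h_k \in \mathbb{R}^L$. The bag
representation is the attention-weighted average

$$ z = \sum_{k=1}^{K} a_k h_k, \qquad
   a_k = \frac{\exp\{w^\top \tanh(V h_k)\}}
              {\sum_{j=1}^{K} \exp\{w^\top \tanh(V h_j)\}}, $$

with trainable parameters $V \in \mathbb{R}^{D\times L}$ and
$w \in \mathbb{R}^{D}$. The weights $a_k$ are positive and sum to one per
bag, so $z$ lies in the convex hull of the instance features, the model is
invariant to instance order, and $a_k$ doubles as an interpretability signal
(the attention map). A single sigmoid neuron
$p = \sigma(u^\top z + b)$ gives the malignancy probability, trained with
bag-level binary cross-entropy; a bag is called malignant when
$p \ge 0.5$ (a symmetric default -- the decision threshold is not dictated by
the model).

Two baselines are built in. *Conventional MIL pooling* replaces the
attention average by the plain arithmetic mean of the $h_k$ (equivalently,
attention with $w = 0$; the package tests exploit that identity as an
oracle). The *supervised baseline* trains an ordinary per-patch classifier
(backbone + one extra fully connected layer + 2-way softmax) in which every
patch inherits its case's label -- deliberately importing the label noise
that motivates MIL -- and aggregates to the case level by the maximum
malignancy probability over all the case's patches, mirroring the clinical
rule that one convincing malignant cell makes the case malignant.

## Instance generation

Specimen images are tiled into a non-overlapping grid from the top-left
corner; partial tiles at the right and bottom edges are dropped rather than
padded, because padding would inject synthetic background into instances.
At the native 1280 x 960 geometry a 64 px grid divides both dimensions
exactly (20 x 15 = 300 candidates); at 96 px the remainders are discarded
(13 x 10 = 130).

Most of a wide field is background, so candidates are filtered by cell
area: the image is converted to grayscale (Rec. 601 luminance,
$Y = 0.299R + 0.587G + 0.114B$, rounded half-up -- the conversion itself is
a pinned convention, not a modelling choice), a single threshold per image
is chosen by Otsu's method (maximising between-class variance over the
256-bin histogram, ties broken toward the lowest level), and a tile is
retained iff its foreground fraction *strictly* exceeds 10% ("more than
10%"). Foreground is intensity strictly *below* the threshold:
Papanicolaou-stained cells are darker than the illuminated background.
A constant image has no valid Otsu split; the threshold is then a sentinel
(`NA`) meaning "no foreground", and the image contributes no instances.

## Bags and cross-validation

A bag contains **all** retained patches from **all** images of one case --
evaluation is per case, and the published 322-case confusion matrices
(108 benign + 214 malignant row totals) only make sense under per-case
bags. Cases whose images retain no patches are excluded with a warning
(a bag must have $K \ge 1$).

Evaluation uses 10-fold cross-validation *by case*: a case's images and
patches never straddle the train/test boundary, so leakage is structurally
impossible (and additionally asserted at runtime). Folds are stratified by
label -- with one-third benign prevalence, unstratified folds of ~32 cases
would be noisy -- with fold sizes differing by at most one (322 cases give
folds of 32-33). Within each fold, 10% of the training cases (again chosen
case-wise and stratified, from the fold's own seeded stream) form a
validation set; the checkpoint with the lowest validation loss is selected,
ties going to the earlier epoch, with a last-epoch fallback if no finite
validation loss is seen. "10% of the training data" could also be read
image- or patch-wise; case-wise is the only reading that keeps the
no-leakage property, so that is what is implemented.

## Backbones and optimisation

Five backbone families are provided -- `lenet_like` (two 5x5
conv/max-pool pairs, 8/16 channels), `alexnet_like` (five 3x3 convolutions,
8/16/24/24/16 channels, three max-pools), `inception_like` (two plain
convolutions, then two three-branch 1x1/3x3/5x5 inception blocks),
`resnet_like` (three basic residual blocks of width 12) and `densenet_like`
(two dense blocks of growth 12 with a 1x1 transition). Every family ends
with an adaptive 4x4 average pool before the fully connected layer, so one
configuration accepts 64, 96 or 128 px patches. These are deliberately
compact "-like" variants of the classic design lineages, sized so that the
full cross-validated experiments in this package train in minutes on a
single CPU core; they are pinned here because reproducibility requires
fixed widths, and they make no claim to reconstruct the full published
topologies. Feature length $L = 500$ and attention width $D = 128$ follow
the established defaults for this pooling layer.

Optimisation is Adam with learning rate 5e-4, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, batch size 1 (one bag per step) for the MIL regimes, and
learning rate 5e-5 with batch size 16 patches for the supervised baseline;
the default epoch budget is 100. Because batch size 1 makes the bag order
part of the optimisation path, bags are reshuffled every epoch from the
run's seeded RNG stream, so a (seed, data) pair replays exactly. Weights
use Glorot-uniform initialisation with zero biases throughout -- including
the attention scorer ($V$, $w$, treated as dense layers $L \to D \to 1$)
and the sigmoid head -- matching the framework defaults of the original
formulation; instance pixels are scaled to $[0,1]$ with no mean/std
normalisation (the simplest contract, recorded so results are
reproducible).

## The synthetic specimen generator

The patient images behind the published evaluation are not distributed, so
the package ships a seeded generator that emulates Papanicolaou-stained
fields at the *geometry* level: a bright background (default grey level
235, slightly tinted) with darker nuclei drawn as filled rotated ellipses,
loosely clustered the way cells sediment on a slide, plus Gaussian pixel
noise (sd 8) and lossless PNG output so repeated runs are byte-identical.
Malignant fields carry a planted subpopulation of malignant-like nuclei
that are larger (radius 12-17 px vs 6-10 px), darker (intensity 30-80 vs
110-160) and more eccentric -- echoing the cytological picture of enlarged,
hyperchromatic, irregular nuclei. Benign cases contain no malignant-like
cell; every malignant image carries at least one whose centre lies inside
the tiled area, so the signal survives tiling at any supported patch size.
Exact cell positions and classes are recorded as ground truth, including
per-patch labels (a patch is malignant-like iff a malignant-like cell
centre falls inside it), which is what makes attention localization
measurable.

The generator's default *small* profile is 256 x 192 px (a 4 x 3 grid of
64 px tiles), 2 images and 15-22 cells per image, 25% malignant-like cells
in malignant fields; the *full* profile mirrors the 1280 x 960 camera
geometry. The small-profile densities were chosen once so that typical bags
retain roughly 3-8 instances -- enough that benign bags are non-degenerate
and a planted cell reliably clears the 10% area rule (a single malignant
nucleus covers ~15% of a tile; benign cells need small clusters).

What the generator does *not* model: chromatin texture, nucleoli,
cytoplasm, the three carcinoma subtypes, stain variability, focus drift, or
any imaging artefact. Passing the end-to-end tests therefore shows that the
pipeline -- tiling, filtering, bagging, attention pooling, optimisation,
case-stratified evaluation, attention read-out -- is correctly wired and
can recover a planted, well-separated signal; it says nothing about
accuracy on real cytology, where the signal is subtler and the published
numbers were obtained.

## Validation experiment sizes

The package's own end-to-end validation (in the test suite and
`scripts/acceptance.R`) uses 40 synthetic cases at the small profile,
`lenet_like`, 30 epochs, 10-fold CV, repeated over three seeds, for both the
attention and mean-pooling regimes -- sizes chosen so the whole experiment
trains in minutes on one core while still quantising balanced accuracy in
steps of 0.025. It checks that attention MIL reaches >= 0.9 cross-validated
balanced accuracy, that mean normalised attention on planted malignant
tiles exceeds that on background tiles in correctly classified malignant
bags, and it compares the two pooling regimes.

That last comparison deserves a caveat the test suite makes explicit: on
this deliberately easy, fully separable planted signal, *mean pooling
saturates* (the class difference survives averaging over a small bag), and
at ~30 training bags of ~5 instances the learned attention scorer can
overfit its selection rule -- occasionally attending, in a held-out bag, to
an uninformative near-threshold tile while ignoring a blatantly malignant
one -- so attention MIL may trail the mean-pooling ceiling by a case or two
here. The published advantage of attention belongs to real data at full
scale, where bags are large, the evidence is rare and subtle, and averaging
dilutes it. The corresponding regime-ordering test asserts the strict
"within 0.05 of mean pooling on every seed" property and is expected to
fail on seeds where mean pooling is perfect; it is kept strict rather than
weakened, as a documented honest boundary of the small-sample regime.

## Numerical choices

* Convolution activations and GEMMs run in single precision internally
  (inputs, parameters and gradients cross the layer boundary as doubles);
  attention pooling, heads and Adam run in double. Single-threaded BLAS is
  pinned at load so training trajectories are bit-reproducible.
* Adam updates are applied in place with a fused kernel; epoch checkpoints
  are deep-copied before further updates.
* Otsu ties break to the lowest threshold; the brute-force 256-threshold
  scan is kept in the test suite as an independent oracle.
* Displayed metrics round half-up to 3 decimals (matching printed tables;
  base `round()` is half-even). Balanced accuracy is computed from
  unrounded sensitivity/specificity by default; `rounded_inputs = TRUE`
  averages the 3-decimal values instead, which is the convention the
  published table follows.
* Attention maps normalise per displayed image by default; bag-level
  normalisation can flatten a single image's display when another image
  dominates the bag. The colour ramp (blue to yellow to red) is monotone in
  warmth: red non-decreasing, blue non-increasing in the weight.

## Known published-table inconsistencies

Re-deriving the published metric table from its own printed confusion
matrices reproduces every attention-MIL and supervised entry at 3 decimals
except three, which are flagged in `reference_metrics()` and excluded from
reproduction checks rather than silently copied:

* the residual-backbone balanced accuracy is printed as 0.900 but the
  matrix (tn 99, fp 9, fn 27, tp 187) gives 0.895 under any standard
  rounding;
* the supervised case-level sensitivity is printed as 0.985 but the matrix
  (tn 77, fp 31, fn 3, tp 211) gives 0.98598... -- a truncation rather
  than a rounding;
* the supervised case-level accuracy is printed as 0.849, which equals the
  balanced accuracy of that matrix; the accuracy itself is 0.894.

The mean-pooling rows have no published matrices, so only their metric
values are recorded.

## Limitations

The CNN engine is intentionally minimal (stride-1 convolutions, max and
adaptive-average pooling, ReLU); there is no GPU path, no data
augmentation, no pretrained weights (training is from scratch by design),
and no gated-attention variant. The synthetic generator's realism
limitations are described above. Whole-slide images are out of scope; the
pipeline expects camera fields of a fixed, modest size.
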