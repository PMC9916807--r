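---
title: "Weakly supervised slide classification with clustering-constrained attention MIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised slide classification with clustering-constrained attention MIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A whole-slide image (WSI) is a gigapixel scan of a stained microscope
slide. In many clinically important tasks — here, predicting BRAF
(V600E) mutation status from Papanicolaou-stained thyroid cytology —
the only label available is slide-level: a pathologist or an assay
says "positive" or "negative" for the whole slide, never for
individual regions. Multiple instance learning (MIL) is the natural
formulation: each slide is a *bag* of patch *instances*, the label
attaches to the bag, and the model must both classify the bag and
discover which instances carry the evidence.

`wsimil` implements the full annotation-free pipeline: tissue
segmentation, patch tiling, patch encoding, gated attention pooling
with class-specific branches, an instance-clustering auxiliary
objective trained with a smooth multi-class SVM loss, Adam training
with early stopping, slide-level metrics, and attention heatmaps.

## Model

Each patch embedding $z_k \in \mathbb{R}^{D}$ ($D = 1024$ by default)
is squeezed to $h_k = W_1 z_k \in \mathbb{R}^{m}$ ($m = 512$). For
each class $i \in \{1,\dots,N\}$ a gated attention branch scores every
instance,

$$a_{i,k} = \frac{\exp\{W_{a,i}(\tanh(V_a h_k) \odot
  \mathrm{sigm}(U_a h_k))\}}
 {\sum_{j=1}^{K}\exp\{W_{a,i}(\tanh(V_a h_j) \odot
  \mathrm{sigm}(U_a h_j))\}},$$

with $V_a, U_a \in \mathbb{R}^{q \times m}$ ($q = 256$) shared across
classes and $W_{a,i} \in \mathbb{R}^{1 \times q}$ class-specific. The
slide-level representation per class is the attention-weighted convex
combination $h_{\mathrm{slide},i} = \sum_k a_{i,k} h_k$, scored by a
class-specific classifier $s_{\mathrm{slide},i} = W_{c,i}
h_{\mathrm{slide},i}$; class probabilities are the softmax of the
scores.

One printed dimension in the source architecture is internally
inconsistent: the slide classifier is stated as $1 \times 256$ while
the pooled representation it multiplies is explicitly 512-dimensional.
We take $W_{c,i} \in \mathbb{R}^{1 \times 512}$, the only shape
consistent with the pooling equation.

### Instance clustering constraint

To sharpen class-specific features, every class also carries a binary
clustering head $W_{\mathrm{inst},i} \in \mathbb{R}^{2 \times m}$
scoring each instance, $p_{i,k} = W_{\mathrm{inst},i} h_k$. During
training the $k_s$ most strongly attended instances of the
ground-truth class are pseudo-labeled positive and the $k_s$ most
weakly attended negative (ties broken by lower index; the bottom set
is drawn after excluding the top set so the sets stay disjoint even
under exact ties). The head is trained against these pseudo labels
with the binary smooth SVM loss. The source is ambiguous about whether
all $N$ heads or only the ground-truth class's head is supervised per
slide; we supervise only the ground-truth class's head, which avoids
inventing pseudo labels for classes the slide does not belong to, and
note the alternative is a one-line change.

### Losses

The multi-class SVM loss with margin $\alpha$ is
$\ell(s,y) = \max\{\max_{j \ne y}\{s_j + \alpha\} - s_y,\, 0\}$, and
its temperature-$\tau$ smoothing is

$$L_{1,\tau}(s,y) = \tau \log \sum_{j} \exp\!\big(\tfrac{1}{\tau}
  (\alpha\,\mathbb{1}[j \ne y] + s_j - s_y)\big),$$

computed with a stable log-sum-exp. Three analytic properties anchor
the implementation and are asserted in the tests: $L_{1,\tau} \ge
\ell$ everywhere, $L_{1,\tau} \to \ell$ as $\tau \to 0$, and at
$\alpha = 0, \tau = 1$ the smooth loss *is* the cross-entropy. The
training objective is
$L_{\mathrm{total}} = c_1 L_{\mathrm{slide}} + c_2 L_{\mathrm{patch}}$
with the slide term the softmax cross-entropy and the patch term the
mean smooth-SVM loss over the $2 k_s$ sampled instances (averaged, not
summed, so $k_s$ does not rescale the objective).

The source states no values for $\alpha$, $\tau$, $c_1$, $c_2$, or
$k_s$; the package defaults $\alpha = 1$, $\tau = 1$, $c_1 = 0.7$,
$c_2 = 0.3$, $k_s = 8$ follow the conventions of the CLAM lineage and
are all exposed in `loss_config()`.

## Training protocol

Adam with learning rate $2 \times 10^{-4}$, weight decay
$10^{-5}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$,
dropout 0.25 after the shared projection and after each gate
activation, one slide per optimization step. The "E value" of the
source protocol is read as the Adam epsilon. Bags larger than 512
instances are randomly subsampled to 512 during training (our reading
of the stated batch size of 512 randomly sampled patches, reconciled
with bag-at-a-time MIL training); evaluation always uses all patches.
Validation slide-level cross-entropy is monitored each epoch — the
source names cross-entropy next to its early-stopping rule while the
combined objective drives the gradients, so we monitor the former and
optimize the latter. Training stops when validation loss has not
improved for 20 consecutive epochs (`patience`), capped at
`max_epochs = 200` as a safety net, and the checkpoint with the
smallest validation loss is returned. The source never states a
validation-set size; `split_bags()` carves a stratified validation
fraction from the training slides since early stopping requires one.

Gradients are computed by an exact analytic backward pass
(`mil_backward()`) through the full graph — softmax attention, gates,
pooling, both loss terms, and the inverted-dropout masks — with
pseudo-label selection treated as a stop-gradient, as is standard for
top-$k$ supervision. The test suite verifies the gradients against
central finite differences to $10^{-4}$ relative error, in both eval
and train (masked) modes.

## Branch identifiability and the evidence branch

A property worth understanding before reading heatmaps: the softmax
over class scores depends only on score *differences*. For a
presence/absence task — negative slides contain no witnesses, only
background — a perfect classifier can be realized two ways: the
positive branch attends witnesses and raises its own score, or the
negative branch attends witnesses and lowers its own. Which solution
gradient descent reaches is decided by the initialization, so the
witness-seeking attention may live in either branch even when test
accuracy is perfect.

`evidence_branch()` resolves this without any instance-level ground
truth: for each branch it compares the class-conditional means of the
pooled representation $h_{\mathrm{slide},i}$ over labeled validation
bags and selects the branch with the largest separation. A branch
pooling witnesses differs strongly between positive and negative
slides; a branch pooling background does not. Attention-recovery
evaluation and heatmap reading should use that branch. For genuine
subtyping tasks, where every class has its own positive evidence, each
branch acquires its own meaning and this concern fades.

## Synthetic fixtures

Two generators stand in for real data so every stage is testable
offline.

**Feature bags** (`simulate_bags()`): bags of i.i.d. Gaussian
instances with isotropic standard deviation $\sigma$; positive bags
contain a minority of "signal" instances (a fraction
`witness_rate` of the bag, at least one) whose mean is shifted by
`mu_signal − mu_background` in every coordinate. The isotropic scalar
shift is the simplest separable geometry and makes attention recovery
analytically predictable. The default prevalence of 0.82 mirrors the
heavy class imbalance of the motivating cohort (82% positive slides);
`bag_size_range = (30, 120)` and `dim = 1024` keep desk-scale runs
fast while matching the encoder contract. Each bag draws from its own
seeded substream, so growing the dataset never reshuffles earlier
bags. Per-instance flags are returned for evaluating attention only —
the training path never sees them.

**Toy slides** (`render_toy_slide()`, `simulate_toy_cohort()`):
bright, glass-like backgrounds with saturated rectangular "tissue"
blobs plus Gaussian pixel noise, and for positive cohort slides an
extra blob in a distinct lesion color. These exercise segmentation,
tiling, encoding, and the end-to-end pipeline.

What these fixtures deliberately do not emulate: cytomorphology, stain
variation, scanner artifacts, correlated patch content, or label
noise. Passing the recovery tests shows the optimization and the
attention mechanism work as specified — it says nothing about
performance on real cytology, which depends on a pretrained
convolutional encoder and real data.

## Segmentation, tiling and encoding choices

The source never specifies its foreground method. We use standard
computational-pathology practice: a chroma channel
($\max - \min$ over RGB, equal to HSV saturation times value),
median-blurred, Otsu-thresholded, morphologically closed, hole-filled,
with components under 64 working-resolution pixels removed. Chroma
rather than raw HSV saturation avoids division instability on dark
pixels and is exactly invariant under color inversion. An almost
achromatic slide (maximum blurred chroma below 0.05) is declared
all-background with a warning rather than letting Otsu hallucinate a
foreground class out of noise.

Tiling is non-overlapping, grid-anchored at the origin, patch size 256
by default (minimum 32), retaining patches with foreground fraction at
least 0.5; coordinates are level-0, 0-based, half-open, sorted
row-major, a convention every downstream module shares.

The patch encoder is a contract (`patch_encoder()`): any deterministic
map from patch images to fixed-dimension embeddings. The intended
full-scale encoder is a ResNet101 truncated after its third residual
stage — the stage whose 1024-channel output matches the embedding
dimension; the source names the network and the dimension but not the
cut, and that stage is the only consistent choice. The bundled
`desk_encoder()` (block-averaged 8×8×3 thumbnail, seeded random
projection, tanh) exists so everything runs offline and
deterministically; it is explicitly not a learned feature extractor.

## Numerical choices

- Softmax and log-sum-exp are always computed max-shifted; losses are
  finite for scores up to $|s| = 10^4$.
- Constant attention in a heatmap is a degenerate min-max
  normalization; all patches render at 0.5 with a warning.
- Metric denominators of zero (e.g. precision of an all-negative
  caller) yield `NaN` with a warning, never a silent 0.
- Weight initialization is scaled Gaussian (sd $= 1/\sqrt{\text{fan-in}}$)
  under a configurable seed; the source is silent on initialization.
- A "small profile" (dims 16/8/4) mirrors every shape of the
  full-scale model (1024/512/256) for fast experiments and exact
  finite-difference checking.
- Feature archives are per-slide directories of TSV/JSON; floats are
  written as `%.17g`, which round-trips IEEE doubles exactly.

## Problem sizes used in the shipped checks

The recovery study uses 350 bags (prevalence 0.5, witness rate 0.1,
$3\sigma$ separation, 16-dimensional features, small-profile model)
split 200/50/100, chosen to make label recovery and attention recovery
sharply testable while keeping a full training run to well under a
minute on one CPU core. The oracle-equivalence and gradient checks run
on bags of at most 10 and 5 instances respectively, where explicit
scalar loops are feasible.

## Known limitations

- The desk encoder carries no histological knowledge; real-data use
  requires plugging a pretrained trunk into the encoder contract.
- Pseudo-label supervision assumes the attended extremes are
  trustworthy; at very low witness rates with weak separation the
  clustering head can reinforce a wrong attention pattern.
- The per-class attention branches are not individually identified by
  the softmax objective (see the evidence-branch section); reported
  heatmaps should state which branch they show.
- Tiling is single-scale and non-overlapping; no pen-mark or artifact
  removal; no stain normalization.
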