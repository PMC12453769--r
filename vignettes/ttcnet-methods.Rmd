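---
title: "Multi-task blood-smear analysis with learned task-to-task connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task blood-smear analysis with learned task-to-task connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcnet)
```

## The problem

B-lineage acute lymphoblastic leukemia (ALL) is diagnosed from peripheral
blood smear (PBS) micrographs. Two tasks recur in computational support
for this diagnosis: classifying each image into Benign (hematogones,
benign B-cell precursors that closely mimic blasts) versus the malignant
maturation stages Early-B, Pre-B and Pro-B; and segmenting the nuclei of
the lymphoid cells for quantitative morphology. The two tasks share most
of their visual substrate — stain color, nucleus boundary, chromatin
texture — which makes them natural candidates for multi-task learning.

`ttcnet` implements a multi-task convolutional network in which the
*amount* of sharing between tasks is itself learned, through a
task-to-task connectivity (TTC) matrix.

## Model

Each task $p$ owns a complete subnetwork column: a convolutional encoder
(3x3 convolutions, batch normalization, ReLU, 2x2 max pooling per block)
plus a task-specific head. Columns are coupled after every encoder
block: the feature entering task $p$'s next stage is

$$\tilde h_p = \sum_q \alpha^{pq}\, h_q, \qquad
  \alpha^{pq} = \mathrm{sigmoid}(\beta^{pq}),\quad \alpha^{pp} \equiv 1,$$

with $\beta^{pq}$ unconstrained real couplings. The diagonal is a
structural constant, not a trained parameter. Because the coupling acts
on features inside the computation graph, the gradient of any task's
cost with respect to any other task's weights — and with respect to
$\beta$ via the sigmoid derivative $\alpha(1-\alpha)$ — falls out of
ordinary backpropagation; no bespoke second-order terms are needed.

Two limiting regimes anchor the design and are asserted by the test
suite:

* **Independence.** As all off-diagonal $\alpha \to 0$, the model
  decomposes exactly into independent single-task learners: the forward
  pass and a full training step match an identically seeded single-task
  model to within 1e-6 per parameter. This identity is only possible
  because *no* parameters are hard-shared; the encoder is "shared"
  through connectivity, not through tied weights.
* **Uniform sharing.** The joint update always equals the optimizer
  transform of the explicitly summed per-task gradients (linearity of
  backpropagation through the coupling points); with all couplings
  equal this is the standard averaged multi-task network.

### Heads

* **Classification**: global average pooling over the bottleneck, a
  per-sample layer normalization of the pooled features, dropout (0.2),
  and a dense softmax over the four classes. The layer norm is a
  conditioning device: pooled features have small dynamic range, and
  without normalization the softmax head converges far too slowly at
  desk scale. Batch normalization was rejected here because the pooled
  features' tiny variance amplifies any train/eval statistics mismatch.
* **Segmentation** (TransUNet-style): the bottleneck feature map is cut
  into patches, each flattened and linearly projected to a
  $D$-dimensional token, sinusoidal positional encoding added,
  pre-norm transformer blocks applied (layer norm, multi-head
  self-attention with $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ per head,
  residual, layer norm, token-wise two-layer feed-forward with GELU,
  residual), tokens projected back to the patch grid, then
  transposed-convolution upsampling with skip connections to the
  column's own encoder features, and a final 1x1 convolution with a
  sigmoid per pixel. The default attention geometry is 100 heads of
  dimension 4 (token dimension $D = 400$); test configurations use
  4 heads of dimension 4.

### Losses and training

Classification uses K-class cross-entropy. Segmentation uses the
per-pixel class-weighted binary focal loss

$$l = -\left[a_c\, y\, (1-p_c)^\gamma \ln p_c
        + (1-y)^\gamma \ln(1-p_c)\right]$$

with $a_c = N_b/N_f$ the background/foreground pixel ratio (recomputed
on every batch by default), focusing parameter $\gamma = 2$, and
probabilities clamped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-7}$. Two conventions in this formula deserve note:
the whole bracket is negated so the quantity is minimized, and the
$(1-y)^\gamma$ factor is read as gating the negative class ($0^0 := 0$),
which makes $\gamma = 0$, $a_c = 1$ reduce *exactly* to binary
cross-entropy. A `standard_focal` switch provides the conventional
symmetric form $-(1-y)\,p^\gamma \ln(1-p)$ for the negative class.

Updates follow $W_{t+1} = W_t + V_{t+1}$ where $V$ is the optimizer
transform of the negative gradient — Adam by default (learning rate
0.001, batch size 32, 50 epochs as package defaults), or plain SGD in a
mode that exists so single steps can be checked against hand-computed
and finite-difference oracles. The applied $V$ is stored per parameter
per step, so the bookkeeping identity holds exactly. Because the loss
is flat in $p$ beyond the clamp, saturated pixels contribute zero
gradient; this is the exact derivative of the loss as computed.

### Incremental task addition

`add_task()` freezes every existing subnetwork and adds a fresh column.
Two asymmetries preserve the frozen tasks' integrity bit-for-bit:
frozen parameters, their optimizer state, their batch-norm statistics
and their $\beta$ rows never update; and the coupling *from* the new
task *into* any frozen task is structurally absent ($\alpha = 0$), so a
frozen task's forward pass is unchanged by the addition. The new task's
row couples it to everything already learned, which is the direction
incremental learning needs.

## Numerical choices

* **Batch-norm statistics.** Training mode uses per-batch population
  statistics; evaluation uses stored running statistics. During short
  runs the running averages lag the fast-moving weights badly enough to
  destroy evaluation accuracy, so before each evaluation the package
  re-estimates the statistics for the *current* weights as an
  equal-weight average over 4 training batches (`recalibrate_bn()`).
  An untrained model evaluates with identity statistics so per-sample
  predictions never depend on batch composition.
* **Gradient verification.** Every layer's backward pass, the coupling
  adjoint, and the $\beta$ chain rule are tested against central finite
  differences on jittered models (jittering moves pre-activations off
  ReLU kinks, where subgradients and finite differences legitimately
  disagree).
* **Internal layout.** Activations are stored `[row, column, batch,
  channel]`, so convolutions run as one cached-index im2col gather plus
  a single BLAS GEMM with no permutation copies. The final decoder
  level fuses upsampled features and the full-resolution skip with a
  1x1 convolution; deeper levels use 3x3.
* **Determinism.** All randomness (initialization, shuffling, dropout)
  derives from user seeds; per-task streams are derived from
  (seed, task id) so a task column initializes identically whether it
  lives in a joint or single-task model.

## The synthetic smear generator

Real PBS data cannot ship with a package, so `generate_dataset()` emits
seed-reproducible images that emulate the *statistical structure* the
method needs: a stained lymphoid cell (blue-dominant cytoplasm, dark
purple nucleus) on a warm white-pink background with anuclear red-cell
distractors, plus a binary nucleus mask. The class signal is
cytological and measurable: the nucleus-to-cell area ratio is drawn
from pairwise-disjoint per-class ranges (Benign 0.20-0.30, Early-B
0.38-0.48, Pre-B 0.56-0.66, Pro-B 0.74-0.84), with class-specific
chromatin texture amplitude and nucleolus count as secondary cues.
Benign cells keep non-empty nucleus masks — hematogones have nuclei;
the class signal is morphology, not mask emptiness. Additive Gaussian
noise (sd 0.02, clipped to [0, 1]) is applied last; the background's
red-over-blue margin (0.10) is several noise standard deviations, so
the blue-dominance cell measurement used by `nucleus_area_ratio()` is
unambiguous and a nearest-centroid classifier on that single measured
ratio recovers 100% of labels.

What the generator does *not* emulate: staining variation, focus blur,
overlapping cells, patient-level correlation (the real dataset has
3,256 images from 89 patients), or subtle inter-class morphology.
Passing tests on this data therefore demonstrate that the mechanisms —
coupling, losses, freezing, heads — work and that the pipeline can
learn separable cytology; they say nothing about clinical performance.

Preprocessing matches the field's convention: resize to a square input
(224 px by default) and divide 8-bit pixel values by 255. The splitter
assigns floor(0.1 n) each to validation and test and the remainder to
training (80/10/10 by default), after a seeded shuffle. Augmentation
provides the exact spatial maps (right-angle rotations, flips) applied
identically to image and mask.

## Desk-scale configuration

The end-to-end checks train a two-task model on 800 synthetic 64x64
images for 10 epochs with a reduced encoder (2 blocks, 6 and 12
channels), 4x4 attention in the segmentation head, batch size 32, and
Adam at learning rate 0.01 — a rate suited to the small, well-
conditioned desk model; the package default stays at 0.001. On one CPU
this takes a few minutes per seed (seed 1 reaches 0.96 validation
accuracy and 0.98 mean test Dice); the test suite requires at least
0.90 validation accuracy and 0.85 mean Dice for a majority of seeds
1-3, and `scripts/acceptance.R` reproduces the run end to end for one
seed.

## Known limitations

* The coupling point placement (after every encoder block) is one
  realization of feature-level task connectivity; coupling inside the
  decoders is not implemented.
* The hierarchical (benign-vs-malignant, then subtype) decision mode
  (`hierarchical_decision()`) is derived from the flat 4-class softmax
  rather than trained as two separate stages; the flat argmax is the
  default everywhere.
* Training is single-threaded and CPU-bound by design; the
  implementation favors verifiability (every gradient finite-difference
  checked) over raw speed, and full-scale (224 px, 4-block, 400-token)
  training is out of desk-scale reach.
* Cohen's kappa is reported in two variants because the printed chance
  term $P(e) = (TP \cdot TN + FP \cdot FN)/T^2$ is nonstandard; the
  conventional marginal-product form is emitted alongside it in every
  report.
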