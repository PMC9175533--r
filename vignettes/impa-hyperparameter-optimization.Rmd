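---
title: "Marine-predator search for CNN hyperparameters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marine-predator search for CNN hyperparameters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impaopt)
```

## The problem

Transfer-learning image classifiers — a pretrained convolutional backbone
with a fresh dense head — are sensitive to a handful of hyperparameters:
the learning rate, the mini-batch size, the dropout rates and the widths
of the new dense layers. Manual tuning is slow and irreproducible.
`impaopt` implements a population metaheuristic, the marine predators
algorithm (MPA), and its opposition-based-learning improvement (IMPA), as
a general optimizer for bounded mixed-type spaces, and wires it to a
two-stage transfer-learning harness so the whole pipeline can be run and
tested at desk scale on synthetic data.

## The optimizer

### Population model

The optimizer maintains a *prey* matrix of `N_n` candidate positions in a
`Dim`-dimensional box and an *Elite* matrix whose every row replicates the
best position found so far. Initialization draws each coordinate
uniformly between its bounds,

$$x^0_i = lb_i + q\,(ub_i - lb_i), \qquad q \sim U[0,1].$$

Iterations are counted 0-based, `it = 0, ..., it_max - 1`, and split into
three velocity regimes:

* **High velocity** (first third): Brownian exploration around the Elite,
  `step = R_B (Elite - R_B\,prey)`, `prey <- prey + P R \cdot step` with
  `R_B` standard normal, `R` uniform and `P = 0.5`.
* **Unit velocity** (middle third): the first half of the population
  explores with Lévy steps relative to its own position; the second half
  exploits around the Elite with Brownian steps scaled by `P \cdot CF`,
  where
  $$CF = \left(1 - \frac{it}{it_{max}}\right)^{2\,it/it_{max}}$$
  decays monotonically from 1 to 0.
* **Low velocity** (final third): all rows take Lévy steps anchored at the
  Elite, scaled by `P \cdot CF`.

After each phase the whole population may take an eddy/FADs jump: with
probability `FADs = 0.2` a row moves toward a random box point through a
per-dimension binary mask, otherwise it drifts along the difference of
two random rows. *Memory saving* then restores, rowwise, whichever of the
current and previous (position, fitness) pairs is better, and the Elite
is refreshed only on strict improvement — together these make the
convergence curve non-increasing by construction.

Lévy steps use Mantegna's two-Gaussian ratio construction with tail index
1.5, the convention of the original MPA; the heavy tail produces the
occasional long jumps that let the search leave local basins.

### Opposition-based learning

The IMPA adds an opposition step: the mirror image of a candidate through
the box centre, `opp(x) = lb + ub - x`, is evaluated, and the fitter of
each (candidate, opposite) pair is kept. This happens once at
initialization and once per iteration after the FADs step. Opposition is
applied in the optimizer's own coordinates (see below), with the static
box bounds, and ties keep the original candidate. The extra evaluations
make IMPA cost `N_n (3\,it_{max} + 2)` objective calls versus
`N_n (2\,it_{max} + 1)` for plain MPA — the improvement is bought with
roughly 50% more compute, and the package asserts these counts on every
run.

### Design choices that the problem left open

* **Iteration indexing.** The three phase windows and the CF schedule are
  driven by a 0-based iteration counter. A 1-based loop would both skip
  the high-velocity phase entirely for very small `it_max` and spend the
  final iteration at `CF = 0`, where the exploit phases collapse onto the
  Elite and the FADs jump vanishes — a wasted population evaluation.
* **Learning rate in log space.** The learning-rate dimension spans four
  orders of magnitude (`1e-7` to `1e-3`), so the optimizer moves in its
  log10 coordinate; sampling, opposition and decoding all happen there.
* **Integer decoding.** Batch size and layer widths are searched as
  reals and decoded by rounding half-away-from-zero, then clamping.
* **Boundary handling.** Hard clamping after every update. The FADs rule
  explicitly references the box bounds, so a bounded domain is assumed
  throughout.
* **Phase-2 step draws.** The exploit-half rule multiplies the Elite by a
  Brownian factor inside another Brownian factor; the two draws are taken
  independently.
* **Eq-9 scalars.** One uniform scalar `r` per row per FADs application;
  the two comparison rows `r1, r2` are drawn without replacement.
* **Fitness orientation.** The optimizer minimizes; maximization
  objectives are negated at the adapter boundary.
* **Termination.** By `it_max` only; no stagnation-based early stopping.

All randomness flows through explicit seeded stream objects
(`rng_stream`), so runs are bit-reproducible and never touch the caller's
`.Random.seed`.

## The classifier harness

### Architecture

The surrogate backbone is a small fixed convolutional feature extractor:
three conv(3×3)–ReLU–meanpool(2×2) blocks with 4, 8 and 8 filters,
He-initialized from a fixed seed, taking 32×32 grayscale input to a
128-dimensional feature vector. It stands in for a large pretrained
backbone so that the full optimization loop runs in minutes on one CPU;
its "last two blocks" (blocks 2 and 3) play the role of the fine-tunable
final stages. A true ResNet50 path is a registry hook only: without
locally supplied pretrained weights it raises an explicit error (there is
no deep-learning framework behind this package, and silently substituting
anything would be misleading).

The replacement head has exactly eight layers: flatten, three
dense–ReLU/dropout pairs with searched widths and rates, and a final
1-unit output. A single-unit softmax is degenerate (constantly 1), so the
output unit is a sigmoid trained with binary cross-entropy — the natural
reading for a two-class task. Dense layers are He-initialized.

### Training protocol

`train_transfer` runs two stages under one epoch budget, split half/half
(stage A gets the extra epoch when the budget is odd): stage A freezes
every backbone parameter and trains the head; stage B unfreezes the last
two blocks and continues jointly. Freezing is bit-exact and verified by
the tests. Optimization is Adam (`beta1 = 0.9`, `beta2 = 0.999`) at the
searched learning rate and batch size.

Learning rates are *discriminative*: the freshly initialized head trains
at 10× the searched rate (capped at 1e-2), while unfrozen backbone
blocks use the searched rate itself. This is the standard convention
when a fine-tuning learning-rate range — chosen to make small changes to
pretrained weights — is paired with brand-new random layers that have a
whole decision boundary to learn. Without it, with Adam's
per-parameter-normalized steps, only configurations taking on the order
of `0.02 / lr` gradient steps can learn at all; at a 2-epoch candidate
budget that confines learning to a few percent of the search space, and
a fitness-maximizing search over a mostly flat landscape degrades into
harvesting validation-fold luck. The multiplier widens the genuinely
learnable region roughly tenfold, so true learners dominate the argmax.
The factor is exposed as `head_lr_factor` in [train_transfer()].

Training keeps the parameters of the epoch with the highest validation
accuracy (model checkpointing, `checkpoint = TRUE`): stochastic
augmentation and a hot head learning rate can push the last epoch
slightly past the best one, and the best-epoch model is what a
practitioner would deploy. Selection uses only the validation fold; the
test split is never consulted during training or model selection.

Augmentation applies, to the training stream only: shear ±0.1, zoom
±10%, width/height shifts ±30%, rotation ±15°, vertical and horizontal
flips, with reflect boundary fill, plus featurewise centering and SD
normalization fitted on the training set (the deterministic normalization
is also applied to validation images; the random warps never are). The
affine warp is implemented in the package because the available image
library's affine transform only supports constant background fill.

### The fitness function

The scalar the optimizer minimizes is `1 - validation accuracy`, where
validation is a stratified 20% of the training set — the test split is
reserved for final evaluation only. The per-candidate epoch budget
(default 2) is deliberately much smaller than the final training budget
(30 epochs, fixed, not searched): full-budget scoring of every candidate
would be prohibitively slow, and a short budget already separates
learning from non-learning configurations. A candidate whose training
produces a non-finite loss receives the sentinel worst fitness 1.0.

## The synthetic data generator

Class 0 images are smoothed Gaussian noise (SD 0.1 around mean 0.35);
class 1 adds a bright elliptical blob of random position, size and
orientation whose peak contrast is `separation` noise SDs. At
`separation >= 3` a simple mean-intensity threshold classifier reaches
≥ 95% accuracy, which the test suite uses as an independent oracle. The
generator emulates exactly one property of the real task — two classes of
textured grayscale images separable by a small CNN — and none of the
domain structure of mammograms (tissue texture, calcifications, label
noise, class imbalance, acquisition artifacts). Tests passing on these
fixtures therefore demonstrate that the optimization and training
machinery works, not that the pipeline would reach any particular
accuracy on clinical data.

Desk-scale study conditions used by the end-to-end checks: 60 images per
class at 32×32 and separation 4. The size is chosen so that a 2-epoch
candidate at mid-range batch sizes still takes a few dozen gradient
steps (with many fewer images most candidates get fewer than ten Adam
steps and the fitness landscape degenerates), while a full pipeline run —
44 trainings plus the final 30-epoch fit — stays under two minutes on one
CPU.

## Metrics

The evaluation module computes accuracy, sensitivity, specificity and
precision from the 2×2 confusion table, macro-averaged F-score, and the
rank-based AUC

$$\mathrm{AUC} = \frac{\sum_i R_i - I_t(I_t+1)/2}{I_t\,I_f},$$

with mid-ranks for ties (`I_t`, `I_f` are the positive/negative counts
and `R_i` the positives' ranks). Two definitional choices deserve note:
the F-score is the harmonic mean of precision and sensitivity,
macro-averaged over classes (one sometimes sees `TP/(TP+FP)` written in
its place, but that is precision, not F1), and the AUC denominator is
the Mann–Whitney `I_t · I_f` (with a sum `I_t + I_f` in the denominator
the statistic would not be bounded by 1). Improvement tables report
two-decimal percentage-point differences between an optimized and a
baseline report and are antisymmetric by construction.

## Numerical and testing notes

* Phase equations are verified against hand-computed single steps with
  pinned random draws to 1e-12.
* The AUC implementation is checked against brute-force pair counting on
  random tied instances to 1e-12.
* The planted-optimum recovery check reports the Euclidean distance
  between the recovered and planted optimum as a fraction of the box
  diagonal (median over 10 seeds, threshold 5%). In the default
  hyperparameter box the coordinate ranges span five orders of magnitude,
  so per-dimension relative error is not uniform: dimensions with small
  ranges contribute so little to a squared-error objective that
  late-stage improvements in them are vetoed, in memory saving, by
  simultaneous step noise in the large-range dimensions. This is a
  property of the algorithm at these settings, not of the implementation.
* Benchmark problem sizes in the tests (population 30, 50 iterations, 10
  seeds; 120-image fixtures) are chosen so the whole suite runs in a few
  minutes on one CPU.

## Limitations

* The surrogate backbone is randomly initialized, not pretrained, so the
  learning-rate range tuned for fine-tuning a pretrained network maps
  onto a harder problem here: very small learning rates genuinely cannot
  learn from scratch within the budget, and the search must discover
  that.
* Only binary classification heads are supported.
* The GSA/HHO/WOA comparison algorithms are not implemented; the
  comparison harness accepts them as plug-in functions.
* Augmentation parameter semantics follow the common image-generator
  conventions (shear in radians, zoom as a symmetric fraction); exact
  numerical equivalence with any specific framework's generator is not
  claimed.
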