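---
title: "Sensitivity-regularized feature extraction for binary-sensor activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity-regularized feature extraction for binary-sensor activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lissarbf)
```

## The model

An activity instance is a vector of d binary sensor activations. The
pipeline has two stages trained in sequence.

**Stage 1: autoencoder with a sensitivity penalty.** The single-hidden-
layer sigmoid autoencoder

$$c = \sigma(xW + b_1), \qquad y = \sigma(cV + b_2)$$

is trained by full-batch gradient descent on the joint objective

$$R + w \cdot \mathrm{STSM}, \qquad
R = \tfrac{1}{N}\sum_i \lVert y^{(i)} - x^{(i)} \rVert^2 .$$

STSM (stochastic sensitivity measure) is the expected squared change of
the reconstruction map $g : x \mapsto y$ when the input moves within the
Q-neighborhood $[-Q, Q]^d$ of a training instance:

$$\mathrm{STSM} \approx \frac{1}{NJ}\sum_{i=1}^{N}\sum_{j=1}^{J}
  \lVert g(x^{(i)}) - g(x^{(i)} + \Delta x_j) \rVert^2 ,$$

with offsets $\Delta x_j$ obtained by mapping a J-point Halton sequence
(van der Corput sequences in the first d prime bases, starting at index
1, no scrambling) onto $[-Q, Q]^d$. A quasi-Monte-Carlo design needs
far fewer points than pseudo-random sampling for the same accuracy; the
test suite checks the 50-point Halton estimate against a
10,000-sample plain Monte-Carlo oracle and requires agreement within
10%. Minimizing $R + \mathrm{STSM}$ minimizes an upper bound on the
localized generalization error over those neighborhoods, which is the
rationale for expecting robustness to unreliable sensor bits. The
bound itself, available as `lge_bound()`, combines
$(\sqrt{R} + \sqrt{\mathrm{STSM}} + \sqrt{A})^2$ with a
$B\sqrt{\ln\eta\,/(-2N)}$ confidence term; it is reported for
diagnostics only and never optimized directly, and we deliberately
treat its exact composition as a reporting convention since only
$R + \mathrm{STSM}$ enters training.

Gradients flow through both $g(x)$ and every $g(x + \Delta x_j)$; the
perturbed passes are evaluated as one stacked $NJ \times d$ forward
pass, and the analytic gradients are verified against central finite
differences to a relative error of $10^{-5}$.

**Stage 2: RBF classifier on frozen codes.** After stage 1 the encoder
is frozen. Training codes are clustered with k-means; cluster center
$u_k$ and width $\sigma_k$ (the RMS distance of the cluster's members)
define the Gaussian unit
$\varphi_k(c) = \exp(-\lVert c-u_k\rVert^2 / 2\sigma_k^2)$. A linear
one-hot output layer is fit by ridge least squares, the standard closed
form for RBF networks. The unit count r is selected greedily: starting
at the number of classes p and stepping to $\lfloor N/2 \rfloor$, one
full RBF network is fit per candidate and the one with minimum training
MSE wins, ties going to the smaller r. Only the RBF stage is retrained
per candidate; retraining the autoencoder inside the loop would change
the feature space the candidates are compared in (and multiply the
cost) without being required by the two-step design.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `hidden_units` (h) | 20 | code dimension; deliberately larger than d for typical deployments (dimensionality *expansion* helps extract interactions between sensors). 20 suffices on compact deployments; sparse ones can need up to 140 — hence `sweep_hidden()`. |
| `Q` | 0.1 | neighborhood half-width, in feature units. Features are 0/1, so 0.1 is a small perturbation relative to the bit gap; `Q = 0` switches the penalty off exactly. |
| `J` | 50 | Halton points per instance; fixed across instances and epochs so the estimator is deterministic. |
| `stsm_weight` | 1 | 1 is the method's unweighted sum; 0 gives a plain autoencoder. The knob exists for ablation only. |
| `learning_rate`, `epochs` | 0.05, 500 | plain full-batch gradient descent; the objective is smooth and the problem sizes small, so fancier optimizers are unnecessary and would cost determinism. |
| `init_scale` | $1/\sqrt{d}$ | uniform weight initialization range, seeded. |
| `ridge` | 1e-8 | keeps the output-layer normal equations well-posed; small enough not to bias the fit measurably. |

Numerical choices: sigmoids are evaluated with `stats::plogis` (stable
at extreme arguments); k-means uses seeded k-means++ initialization,
Lloyd iterations with tolerance $10^{-6}$ and at most 300 iterations,
and re-seeds an emptied cluster from the farthest point; an empty or
singleton cluster's undefined width falls back to the mean width of the
others (0.1 if none exists); prediction ties break toward the lowest
class id; a class never predicted gets precision 0 with a warning
rather than NaN, which small held-out folds make routine.

## Evaluation protocol

`confusion()` follows the rows-inferred / columns-actual convention.
Per-class precision $TP_i/SI_i$ and recall $TP_i/ST_i$ combine into
per-class F1, and the headline F1 is the *support-weighted mean*
$\sum_i ST_i F1_i / \sum_i ST_i$ — the raw support-weighted sum would
exceed 1, so normalization by total support is the only reading
consistent with percent-scale reporting. Per-class accuracy tables are
rounded half-up to integer percent. `repeated_cv()` runs k-fold
cross-validation (default 10-fold, 5 repeats, stratified) retraining
both stages per fold, and reports both the mean ± sd of per-fold
metrics and the instance-level metrics of the aggregate confusion
matrix pooled over folds; published work rarely states which of the two
an "average accuracy" is, so both are exposed. Stratification is the
default because real activity datasets are heavily imbalanced (a 482-
instance deployment can have supports from 11 to 115); plain random
folds remain available by flag. `compare_ttest()` uses Welch's form by
default — fold-level metric variances of two different classifiers have
no reason to be equal — with the pooled test behind a flag.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws one binary sensor-signature prototype per
activity (bit density 0.35 by default — a handful of sensors fire per
activity) and emits instances as prototypes with independent per-bit
flips at rate `flip_prob`. Defaults (d = 12, p = 9, 27 instances per
class, 5% flips) mirror the scale of real annotated deployments:
a few hundred instances, 10–21 sensors, 7–11 activity types.
`aliased_pairs` forces chosen classes to share a prototype, reproducing
the breakfast/lunch/dinner/snack failure mode where distinct activities
have identical sensor signatures and no instance-wise classifier can
separate them; `imbalance` skews supports geometrically; `asymmetric`
restricts noise to missed activations (1→0). What it does *not*
emulate: time stamps, activity durations, sequence structure between
activities, and sensor-to-sensor correlation in the noise. Passing
tests on this generator therefore demonstrate the pipeline's
correctness and its robustness to independent bit noise, not
performance on real time-structured deployments.

With `flip_prob = 0` and distinct prototypes a nearest-prototype
classifier is perfect, which gives every end-to-end test a hard
ceiling: the cross-validation check requires the full pipeline to reach
at least 99% mean accuracy on such data (N = 198, d = 12, p = 6, 10
folds, 2 repeats — 2 repeats rather than 5 keeps the routine test run
short while still exercising repeat aggregation; 198 is the closest
balanced size to 200 at p = 6).

## Design choices where the design was open

- **Estimator normalization.** The sensitivity sum is divided by
  $NJ$, making it an expectation over the neighborhood sample; the raw
  $1/N$ sum is available via `scaling = "sum"`. The expectation
  semantics is what makes values comparable across different J.
- **One fixed perturbation set.** The offsets carry no instance index
  and are not regenerated per epoch: determinism, and the smallest
  faithful reading of a fixed Halton construction.
- **Frozen encoder in the greedy loop** (see above).
- **Greedy upper bound.** The loop runs while $r < N/2$ starting at p,
  i.e. candidates $p \le r \le \lfloor N/2 \rfloor$; whether the bound
  is strict or inclusive is immaterial in practice and the inclusive
  reading is used.
- **Output-layer fit.** Ridge least squares rather than gradient
  training: deterministic, exact, and the standard RBF closed form.
- **Label encoding** by first appearance in the file, so a dataset file
  fully determines its own encoding without a schema sidecar.

## Problem sizes used in the shipped checks

Unit tests run on tiny fixtures (d ≤ 12, N ≤ 100, shortened training of
30–120 epochs). The acceptance-style checks use full-length training
(500 epochs) for the separability study (N = 198), a 100-instance
fixture for the greedy-search contract, 10,000 Monte-Carlo samples for
the estimator oracle, and a 3-fold, 60-epoch configuration for the
hidden-width sweep over h ∈ {20, …, 140} — the sweep's claim is the
protocol shape (one accuracy/F1 row per width), not any particular
value, so a light cross-validation depth is appropriate.

## Known limitations

- Single hidden layer only; no stacked or denoising variants.
- No segmentation: inputs must already be per-instance binary vectors,
  not raw time-stamped event streams.
- Baseline classifiers (SVM, random forests, ...) are not reimplemented;
  `compare_ttest()` accepts any external method's per-run metrics, and
  `confusion()`/`metrics_report()` accept any predictor's labels.
- The greedy search is $O(N/2 - p)$ full RBF fits; for N in the tens of
  thousands a coarser `step` is advisable.
- Reported accuracies on real public deployments depend on their exact
  instance extraction and unpublished hyperparameters; this package
  ships the method and protocol, not those datasets.
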