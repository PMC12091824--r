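---
title: "Chi-square weighted ensembling: model, assumptions and design notes"
author: "ChiSquareEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chi-square weighted ensembling: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChiSquareEnsemble)
```

## The model

Given a bank of multi-class classifiers that all emit class-probability
vectors for the same labelled samples, the package assigns each classifier
a weight proportional to a two-cell chi-square goodness-of-fit statistic
and blends the probability matrices by the weighted mean.

For classifier $i$ on $n$ samples with true labels $y$, the observed cells
are its correct count $O_1$ (row argmax equals $y$, ties broken toward the
lowest class index) and $O_2 = n - O_1$. The expected cells come from a
*chance-agreement null*: a predictor that draws classes from the empirical
label frequencies $\pi_c$ independently of the truth is correct with
probability $q = \sum_c \pi_c^2$, giving $E_1 = nq$, $E_2 = n(1-q)$. Then

$$\chi^2_i = \frac{(O_1-E_1)^2}{E_1} + \frac{(O_2-E_2)^2}{E_2},
\qquad w_i = \frac{\chi^2_i}{\sum_j \chi^2_j},
\qquad \hat p_j = \sum_i w_i\, p_{ij}.$$

The blend is a convex combination, so outputs are valid probability
matrices whenever the inputs are; final hard labels are the argmax with
the lowest-index tie-break.

### Why a one-sided default

$\chi^2$ is sign-blind: a classifier far *below* chance produces a large
statistic and raw normalization would hand it a large weight, the opposite
of the method's intent of promoting classifiers whose predictions align
with the truth. `computeWeights(mode = "one_sided")` (the default)
therefore zeroes the effective statistic of any classifier whose correct
count falls below its expected count; `mode = "raw"` applies the
normalization verbatim for fidelity with the plain formula. When every
effective statistic is zero (e.g. all members exactly at chance, or all
identical and below chance) the weights fall back to uniform with a
warning, which keeps the blend defined and equal to plain averaging.

### The choice of null

The null is computable from the true-label distribution alone, which is
the only information the expected-frequency recipe assumes. Two options
are provided:

* `null = "marginal"` (default): $E_1 = n\sum_c \pi_c^2$, chance agreement
  under label-marginal guessing. On a heavily imbalanced composition this
  is a demanding reference — for the seven-class dermoscopy-like
  composition shipped in `hamLikePriors()` (prior 663/828 on the dominant
  class), $q \approx 0.651$, so a 60%-accurate classifier is genuinely
  below chance.
* `null = "uniform"`: $E_1 = n/C$, for the degenerate case where all
  calibration labels belong to one class (the marginal null then has
  $E_2 = 0$ and the statistic is undefined; the package raises an error
  directing the user here).

### Which labels fit the weights

Fitting the weights on the same labels used for final evaluation leaks
information. `executeTopology()` therefore takes distinct `calibLabels`
(weight fitting) and `evalLabels` (metrics); passing the same object in
both is the explicit replication mode. `groupedSplit()` exists precisely
to carve a calibration/validation split that shares no lesion with the
test split.

## The multi-layer topology

`buildLayeredTopology()` constructs the canonical 4-layer scheme over two
families of 12 backbones, each in 4 attention variants (96 leaves):

* Layer 1 — 24 nodes, one per backbone over its 4 variants;
* Layer 2 — the two family nodes `RNX`/`RNY` (12 inputs each) plus 12
  `XY*` nodes pairing the X and Y layer-1 nodes of a common size;
* Layer 3 — `RNXY` over the family nodes, `RN_XY` over the size pairings;
* Layer 4 — the terminal `RN`.

Each node re-fits the full chi-square procedure on its own inputs rather
than propagating upstream weights: layering exists to compound the
emphasis on strong branches, and refitting is what makes a layer's
weighting reflect the quality of its *blended* inputs, not its leaves.
Single-input nodes act as identity blends so degenerate topologies remain
valid. Execution order is content-determined (by layer, then node id), so
permuting node insertion order cannot change results.

## Metrics

Per-class one-vs-rest cells are taken from the $C \times C$ confusion
matrix; precision, recall, F1 and specificity use $0/0 = 0$ for empty
denominators. Aggregation is support-weighted (class frequency among true
labels), under which the weighted recall equals overall accuracy as an
algebraic identity — the reason accuracy and recall columns coincide in
support-weighted reports. Specificity has no single established
aggregation convention; it follows the same support weighting for
consistency. ROC-AUC is one-vs-rest from the midrank (Mann–Whitney)
statistic, equivalent to trapezoidal integration over all thresholds with
ties handled by midranks; classes absent from the labels report `NA` and
are excluded from the macro mean.

## Attention operators and Grad-CAM

The three attention forward passes operate on a single $C \times H \times
W$ feature map with injected parameters (no training):

* **Channel attention** pools a mean and a population-standard-deviation
  descriptor per channel, passes each through the shared bottleneck
  projection $W_2\,\mathrm{ReLU}(W_1 \cdot)$, sums the two
  pre-activations, and applies one sigmoid; the text description of this
  operator names the two descriptors but its printed formula applies the
  projection to the raw map, so the pooled-descriptor form used here is
  this package's concretization. With zero parameters the gate is exactly
  $\sigma(0) = 0.5$.
* **Squeeze-excitation** supports two activation orders. `order =
  "paper"` reproduces the printed excitation
  $\mathrm{ReLU}(W_2\,\sigma(W_1 z))$, which is nonnegative but unbounded
  above; `order = "standard"` is the canonical
  $\sigma(W_2\,\mathrm{ReLU}(W_1 z))$ gate in $(0,1)$. The printed order
  is most likely a transcription slip, but it is kept as the default for
  fidelity; tests pin both behaviours.
* **Soft attention** projects each spatial position's channel vector to a
  scalar score and softmaxes over the $T = HW$ positions
  (max-subtraction for numerical stability — mandatory, since scores are
  unbounded); the attention map sums to one by construction. Where the
  scalar scores come from inside a real network is architecture-specific;
  the linear projection here is an explicit stand-in.

Grad-CAM aggregation takes caller-supplied activations and gradients
(H × W × K), pools gradients to per-channel importances, weights and sums
the channels, rectifies, and min-max normalizes to $[0,1]$. Rectification
is applied by default even though the source procedure does not mention
it: without ReLU, regions that *suppress* the class dominate the map and
contradict the positive-evidence reading of the overlays (a flag disables
it). Flat rectified maps normalize to all zeros rather than NaN. The
overlay uses an in-package bilinear resize and a fixed 256-entry jet-like
lookup table computed in code, so rendered output is identical across
platforms; the blend factor defaults to 0.4 (no canonical value exists).

## The synthetic generator

`simulateBundle()` emulates a bank of *sibling* classifiers — fine-tuned
variants of related architectures evaluated on the same images — not
independent experts. That distinction drives the design: in the target
setting, reported layer-over-layer ensemble gains are a few tenths of a
percentage point, which implies near-total error correlation; a generator
with conditionally independent errors would instead make uniform
averaging unbeatable by any weighting (diversification alone would
dominate) and would misrepresent what weighting can achieve.

Concretely, with marginal accuracies $a_k$, class priors $\pi$, and shared
difficulty $\rho$:

* each sample is *hard* with probability $\rho$; on hard samples all
  classifiers emit one shared prediction drawn from $\pi$ independently of
  the truth (jointly correct with chance probability $q$);
* easy samples carry one shared latent $u \sim U(0,1)$; classifier $k$ is
  correct iff $u \le a^{\mathrm{easy}}_k = (a_k - \rho q)/(1-\rho)$, so
  error sets are nested (a weaker classifier fails wherever a stronger
  one does) and each marginal accuracy is exactly $a_k$. Accuracies
  outside $[\rho q,\; 1 - \rho(1-q)]$ are unreachable and raise an error;
* wrong easy-sample predictions are drawn per classifier from $\pi$
  restricted to non-true classes (confusions concentrate on frequent
  classes, as observed for melanoma/nevus; `confusion = "uniform"` is the
  alternative);
* probability rows are Dirichlet draws with unit base mass plus
  `concentration` (default 8, giving confident but non-degenerate rows)
  on the predicted class; the largest entry is swapped into the predicted
  position so each row's argmax equals the intended prediction exactly.

What passing tests on this generator do **not** show about real data: the
nested-error structure is an idealization (real sibling models disagree
more than nesting allows), rows are Dirichlet rather than
softmax-of-logits shaped, and per-class difficulty structure (e.g.
melanoma being intrinsically harder) is not modelled — only global
difficulty is. Results on this generator demonstrate the weighting
mechanics, not clinical performance.

Default study conditions used by the tests and the acceptance script:
five classifiers with accuracies 0.60–0.80 (step 0.05), $n = 5000$,
the `hamLikePriors()` composition, $\rho = 0.3$, 20 replicate seeds; the
topology run uses 96 leaves with accuracies drawn uniformly in
[0.66, 0.84] and $n = 2000$. Under the marginal null with these priors,
chance accuracy is $q \approx 0.651$: the 0.60 classifier is *below*
chance and the 0.65 classifier straddles it, so the one-sided default
zeroes one to two weights by design. The weight-ordering property is
therefore checked as non-decreasing weights with strict increase among
above-chance classifiers — strict increase across zeroed classifiers is
impossible by construction, not a defect.

## Grouped splitting

`groupedSplit()` shuffles lesion ids by seed and assigns lesions greedily
— test first, then validation, then train — against image-count targets,
so no lesion ever spans two splits. Greedy filling can overshoot a target
by at most one lesion's images, which keeps realized fractions within
±2% of (0.70, 0.15, 0.15) for cohorts of ≥ 200 lesions. A single lesion
larger than a split target is assigned to train with a warning. The
source pipeline's additional step of re-inserting "redundant images" into
training is deliberately not reproduced: its operational meaning is
unclear, and the leakage-free partition is the part that matters for
sound evaluation.

## Numerical choices

* Row-sum tolerance on input: rows within $1 \pm 10^{-3}$ are
  renormalized (float export noise); larger deviations are hard errors
  (malformed data).
* Weight vectors are renormalized at construction so they sum to 1 to
  machine precision; validity enforces nonnegativity.
* Argmax ties break toward the lowest class index everywhere, making
  results order-deterministic.
* Majority-vote ties are resolved toward the tied class with the highest
  mean probability (then lowest index); because vote fractions alone
  cannot encode that choice, tied rows receive a vanishing ($10^{-6}$
  vote) bonus on the winner — untied rows are exact vote fractions.
* CSV probability output uses 17 significant digits (round-trips within
  $10^{-12}$); the RDS dialect round-trips bit-identically.
* All generators draw from a single explicitly seeded stream per call and
  restore the caller's RNG state; labels and bundle use distinct derived
  seeds so label draws and difficulty draws are not aliased.

## Known limitations

* The chi-square score collapses each classifier to one correct/incorrect
  count: two classifiers with equal accuracy but different per-class
  error profiles receive equal weight.
* Weights fitted on small calibration sets inherit the statistic's
  sampling noise; no shrinkage is applied.
* The topology is fixed by configuration, not learned, and no
  cross-validated weight estimation is provided.
* The attention and Grad-CAM modules are forward-only building blocks for
  inspection and testing; they do not integrate with a deep-learning
  framework.
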