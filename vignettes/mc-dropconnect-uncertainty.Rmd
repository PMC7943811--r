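---
title: "Monte Carlo DropConnect: model, uncertainty measures, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo DropConnect: model, uncertainty measures, and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mcdropconnect)
```

## The model

A Bayesian neural network places a posterior over its weights; exact
inference is intractable, so this package uses a Bernoulli variational
family imposed *directly on the weights*. Each layer's weight matrix is
written `W = Θ ⊙ Z` with variational parameters `Θ` and an elementwise
Bernoulli(`p`) mask `Z` (DropConnect); the Dropout baseline instead masks
output units, `a = σ(z ⊙ (Θ'v))`. Biases are folded into `Θ` as an extra
row fed by a constant one and are masked with everything else by default.

Two consequences drive the whole design:

1. **Training.** Minimizing mean cross-entropy plus an L2 penalty
   `λ Σᵢ‖Θᵢ‖²` with fresh masks per SGD step is a Monte Carlo estimate of
   the variational objective (the KL to the prior reduces to the L2 term
   for this family). `train_model()` implements exactly this, with
   momentum SGD.
2. **Testing.** Masks stay *active* at test time. Each forward pass is a
   posterior draw; `mc_predict()` collects `T` softmax samples per item
   and their average `p̄` is the posterior predictive
   (`predictive_mean()`). The conventional "standard test" keeps every
   weight in place (`deterministic_predict()`).

### Inverse-p rescaling

With raw `Θ ⊙ Z` masking, the stochastic pre-activations have expectation
`p·Θ'v`, while the all-ones deterministic pass computes `Θ'v` — a factor
`1/p` mismatch. We default to `scale_by_inverse_p = TRUE`: kept weights
are rescaled by `1/p`, which is the reparametrization `Θ' = Θ/p` of the
same family and makes the deterministic pass equal the expected stochastic
activation. The unscaled semantics remain available as a flag for anyone
wanting the literal factorization; every result type is unaffected by the
choice up to this reparametrization.

### Mask granularity and reproducibility

One mask is drawn per layer per forward pass, shared across the batch
(per-item masks would multiply memory and are not what common
implementations do; for segmentation this means all pixels of a batch
share a weight draw, matching the per-image sampling of the reference
setting). Convolutions are evaluated by patch extraction, so a
convolution is an affine stochastic layer shared across pixels; weight
mode masks the kernel tensor elementwise, unit mode masks output
channels.

All randomness flows from a root seed split into named streams (data,
initialization, masks, shuffling, baselines) by a deterministic mixing
function. A mask is addressed by `(stream, draw index)`, so any run can
be replayed bit-for-bit, and a run of `T` passes can be *continued*: the
passes of a longer run coincide with a fresh run started at a
`draw_offset`.

## Uncertainty measures

For one item with samples `p(1), …, p(T)` and mean `p̄`:

- predictive entropy `Ĥ = −Σ_c p̄_c log p̄_c` — total uncertainty;
- expected sample entropy `(1/T) Σ_t H(p(t))` — its aleatoric part;
- mutual information `Î = Ĥ − (1/T) Σ_t H(p(t))` — the epistemic part,
  the information the true label would carry about the weights.

Natural logarithms are used throughout (the choice of base cancels in the
normalized measure, a property the tests check). Probabilities are
clamped at `1e-12` inside logarithms; `Î` is clamped at zero against
roundoff. `classwise_variance()` provides the variance-based alternative
measure; it is not the default because `Î` is the quantity with the
information-theoretic reading above.

Because the scale of `Î` depends on dataset, architecture and `T`,
thresholds operate on `I_norm = (Î − I_min)/(I_max − I_min)` with the
extremes taken over the evaluation set being scored. For workflows that
freeze a threshold on validation data and apply it to test data,
`normalize_uncertainty()` accepts frozen `(i_min, i_max)` bounds and
clips out-of-range values; per-image normalization for segmentation is
available by scoring images separately, but the default normalizes over
all pixels of the evaluation set, consistent with dataset-level
normalization.

## Evaluation framework

`certainty_split()` classes an item certain iff `I_norm < I_T`; ties go
to *uncertain*, the conservative direction for safety-critical screening
(the defining inequalities are strict on both sides, so the boundary
convention is ours to fix). The four-way counts with correctness give
`R_cc`, `R_iu` and `UA`; 0/0 ratios are reported as `NA`, never silently
replaced. For the AUC over the default 101-point threshold grid the
undefined values must be filled: `R_cc`'s undefined head (nothing
certain) and `R_iu`'s undefined tail (nothing incorrect) are vacuously
perfect and are filled with 1 by default; the fill value is recorded in
the result and configurable, since published practice does not pin it
down. AUCs are reported in percent.

Referral analysis retains the `⌈f·N⌉` least-uncertain items
(stable order on ties) or those below a tolerance, and compares against
removing the same number of items uniformly at random (20 samplings by
default). `select_operating_threshold()` grid-searches a validation set
for the UA-maximizing threshold and returns the midpoint of the longest
optimal plateau; an all-correct validation set has nothing to reject and
returns the maximum threshold.

Segmentation scores follow the standard confusion-matrix definitions with
classes absent from the ground truth excluded from the class means
(configurable via the reported class-presence count) and an ignore label
(default 255) excluded everywhere, including uncertainty normalization.
Confidence-percentile accuracy keeps the `(100 − q)`% most certain pixels.

## Synthetic study conditions

The generators define the study conditions; their defaults are fixed and
are what the acceptance checks run under.

**Classification.** Three isotropic unit-variance Gaussians in ten
dimensions, means on orthogonal axes at radius 1.96 (pairwise separation
2.77), n = 2000 balanced, split 1000/1000. Numerical integration of the
mixture puts the Bayes error near 14%, inside the engineered 10–20% band,
so a well-trained model misclassifies a usable fraction of items. The
dimension matters and was chosen deliberately: in two dimensions the
class overlap is densely populated, a converged network learns the soft
Bayes posterior there, and errors are purely aleatoric — mutual
information then cannot flag them. In moderately high dimension the
overlap region is sparsely populated, posterior draws disagree exactly
where errors occur, and the epistemic signal behaves the way it does for
image classifiers. Out-of-distribution probes (60 by default) are placed
on random directions and pushed outward until they are farther from every
class mean than that mean's 99th-percentile in-distribution distance —
a domain-shift analogue. What the task does *not* emulate: feature
correlations, label noise heterogeneity, class imbalance; passing tests
show the machinery works, not that any particular real dataset would
enjoy the same margins.

**Segmentation.** 24×24 single-channel scenes: background, a rectangle,
a disk, and a rare 2×2 square kept under 2% of pixels by construction;
class intensities separated by 0.8 with pixel noise of 0.4, and shape
positions jittered between scenes so class boundaries are ambiguous at
the noise level. This mimics the frequent-background / rare-small-class
structure of street-scene and organ segmentation at desk scale; it does
not emulate texture, occlusion or 3-D structure.

**Networks and trainer.** The reference models are miniatures: an MLP
(10→64→64→3), a three-block convolutional classifier with two 3×3
convolutions per block, and a one-level U-Net-style segmenter with a skip
connection (the skip is needed for boundary precision; without it the
decoder's upsampled features cap the achievable IoU). All keep
`p = 0.5` by default in both weight and unit mask modes with identical
parameter counts, so the DropConnect/Dropout comparison is fair. The
trainer uses plain momentum SGD (momentum 0.9), `λ = 1e-4` (unreported in
the source setting; exposed prominently), learning rate 0.02 with a step
schedule (×0.1 at 60% and 85% of the epoch budget), and 300 epochs by
default — enough to reach the converged regime in which the published
trends (for instance, MC averaging not being worse than the deterministic
pass) are systematic rather than noise-dominated. The 0.02 rate was
chosen from training-loss behaviour alone; 0.1 diverges on these tiny
inverse-p-scaled networks.

**Problem sizes in the studies.** The behavioral studies run 20 seeds;
per seed: training on 1000 items, uncertainty metrics on the 1000-item
test split at `T = 100`, the deterministic-vs-MC error comparison on a
5000-point held-out sample (the paired difference is a few tenths of a
percent, so it needs that precision), and the MC variance-scaling check
with 30 repetitions at `T = 4` and `T = 64` on a 100-item subset. The
segmentation study trains on 6 scenes and evaluates on 2, `T = 50`, with
200 epochs at rate 0.05.

## Numerical choices and degenerate inputs

- Argmax ties resolve to the lowest class index, deterministically.
- `keep_prob = 1` is exactly deterministic (all-ones mask, no rescaling);
  `mc_predict()` warns and returns identical samples.
- Constant `Î` vectors normalize to all zeros.
- Percentile and referral cuts use stable ordering, lowest index first.
- Empty retained sets yield `NA` accuracy markers, not errors.
- Training aborts with the loss trace attached when the loss becomes
  non-finite.
- `sample_mask()` validates `p ∈ (0, 1]`; degenerate generator
  covariances and shapes that do not fit the scene are rejected.

## Known limitations

- The trainer is plain SGD on dense matrices; it is meant for the
  miniature study networks, not for real image workloads.
- Bernoulli masking with a fixed rate is the only variational family;
  learnable drop rates and other families are out of scope.
- Aleatoric uncertainty is surfaced only as the expected sample entropy;
  no heteroscedastic noise modeling.
- The mutual-information estimator shares the bias of plugging `T`-sample
  averages into entropies; at small `T` both `Ĥ` and `Î` are biased, so
  comparisons should hold `T` fixed (the convergence tooling exists to
  choose it).
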