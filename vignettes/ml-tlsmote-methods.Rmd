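---
title: "Hybrid resampling for imbalanced multi-label data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid resampling for imbalanced multi-label data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mltlsmote)
```

This vignette is the package's own account of its methods: what is being
modelled, which knobs matter, what the synthetic generator does and does not
emulate, and where genuinely open design choices were settled.

## Imbalance in multi-label data

A multi-label dataset (`mld`) pairs an instances-by-features matrix with an
instances-by-labels binary matrix. Imbalance *between* labels is measured
per label by the ratio of the most frequent label's positive count to the
label's own count (IRLbl); the most frequent label therefore scores exactly
1. MeanIR and MaxIR are the mean and maximum of these ratios, and CVIR is
their coefficient of variation, computed with the sample (q − 1) standard
deviation. The conjunction MeanIR > 1.5 and CVIR > 0.2 is the conventional
imbalance verdict, and `imbalance_profile()` reports it together with the
minority/majority partition: minority labels are those with IRLbl strictly
above MeanIR. A label whose ratio equals MeanIR exactly is assigned to the
majority side — the conservative reading, since majority labels are cleaned
rather than oversampled and a near-balanced label should not be inflated.

Labels with zero positive count make the ratio undefined; the profile
refuses such datasets with an explicit error rather than propagating
infinities into MeanIR, and `ml_tlsmote()` refuses them for the same reason.

## The hybrid resampler

`ml_tlsmote()` chains three steps: profile, SMOTE oversampling of minority
labels, Tomek-link cleaning of majority labels against a profile of the
augmented data, and a final profile for the report. A dataset that already
sits under both thresholds is returned unchanged.

### Oversampling: per-round reassessment

For each minority label, synthetic instances are interpolated between a seed
from the label's pool and one of the seed's `k` nearest pool neighbours
(Euclidean distance), `x_new = x_seed + u (x_neighbor − x_seed)` with `u`
uniform on [0, 1); the synthetic instance copies the seed's full label
vector. The seed pool is, by default, the *strict* set of instances carrying
the label and no other (`seed_pool = "no-majority"` relaxes this to
requiring only the current majority labels to be absent). Oversampling a
label stops once its ratio falls to the current MeanIR.

One pass of this rule cannot balance a dataset: with the frailty-like
marginals the ratios (1, 1.07, 1.33, 2.19, 5.58, 5.90) would become
(1, 1.07, 1.33, 2.19, ≤2.85, ≤2.85), leaving MeanIR near 1.9 and CVIR near
0.45 — still imbalanced, and the intermediate label untouched. The
implementation therefore proceeds in rounds: after each round the profile is
recomputed, the minority set is re-derived (a label that was majority under
the original profile can become minority once the rarest labels have been
lifted), and rounds continue until both MeanIR ≤ 1.5 and CVIR ≤ 0.2, no
label can make progress, or `max_rounds` (default 10) is reached. On the
frailty-like marginals this converges in about three rounds to MeanIR ≈ 1.3
and CVIR ≈ 0.17 — the behaviour the balanced-state summaries in the test
suite verify. Two guards keep small pools safe: a label whose pool has
fewer than two members is skipped with a warning (interpolation is
undefined), and each label adds at most `cap_factor` (default 5) times its
pool size per round.

### Cleaning: sequential per-label Tomek links

A Tomek link is a pair of instances of opposite class that are mutual
nearest neighbours; its members are boundary points or noise. For each
majority label in ascending-IRLbl order (most frequent first), links are
computed on the instances *surviving so far* under that label's binary view,
and both members of each link are removed — the post-process-cleaning
variant, which also sweeps up synthetic instances that invaded a majority
label's territory. Removing both members rather than only the majority-side
member is the deliberate choice here; the opposite convention would never
touch minority-side noise. One guard applies: an instance is never removed
if it is the last remaining carrier of any label, so cleaning can never
empty a label. Links are recomputed per label rather than precomputed
globally because each removal can create or destroy links in the next
label's view; the sequential order is the only self-consistent reading.

### Determinism

All randomness (seed choice, neighbour choice, interpolation weights) flows
from one seed recorded in the report; nearest-neighbour ties are broken by
the lowest instance index. With a fixed seed the output is bit-reproducible,
which the suite checks end to end.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 5 | SMOTE neighbour count (canonical SMOTE default), clamped to pool − 1 |
| `seed_pool` | `"strict"` | pure single-label pools; `"no-majority"` for datasets where those are rare |
| `max_rounds` | 10 | upper bound on oversampling rounds |
| `cap_factor` | 5 | per-round synthetic cap as a multiple of pool size |

Distances are Euclidean on the raw features for both SMOTE and Tomek links;
features are *not* standardised internally, because silent rescaling would
change the link structure invisibly. Callers whose features live on
heterogeneous scales should scale before resampling.

## Evaluation metrics

Average precision and ranking loss are rank-based; ranks are derived from
scores with rank 1 for the highest score and ties broken by ascending label
index, so every ranking is a deterministic permutation. Instances with an
empty true label set are skipped in both (they carry no ranking
information), and ranking loss also skips all-relevant instances; Hamming
loss and micro F1 count every cell. Micro F1 is the standard pooled
harmonic mean 2TP/(2TP + FP + FN) — the bounded-at-1 F-measure that
comparison tools report — and returns 0 when its denominator is empty.
Macro AUROC uses the Mann–Whitney estimator with ties credited one half,
matching the standard empirical AUROC; labels lacking either class are
skipped with a warning. All five are verified against loop-based
enumeration oracles, exhaustively for single instances at q = 3 and on
random matrices.

## Classifiers

The six strategies consume base learners through a minimal contract (fit on
features plus a binary/multi-class target, return class confidences),
backed by rpart, ranger and e1071. Settled choices where the conventions
genuinely vary:

* **CC** chains in ascending label order by default (order is a parameter);
  at inference each link consumes the chain's own thresholded predictions.
* **LP** scores a label by the summed confidence of the observed labelsets
  containing it, so labelsets never seen in training are unreachable and
  labels outside every training labelset score 0.
* **RAkEL** draws `n_models = 12` subsets of `labelset_size = 3` labels
  (duplicates across models allowed), votes with threshold 0.5, and falls
  back to the training prior for a label no subset covers.
* **CLR** trains one pairwise model per label pair on the instances
  carrying exactly one of the two, plus one calibration model per label
  standing in for the virtual boundary label. Votes are soft (predicted
  probabilities rather than hard wins), which gives smoother rankings; an
  untrainable pair contributes a neutral half-vote to both members. A label
  is predicted when its votes exceed the virtual label's.
* **MLkNN** uses the canonical defaults k = 10, smoothing 1, with priors
  and neighbour-count likelihoods estimated from leave-one-out statistics.

## The synthetic generator

`generate_mld()` draws each instance's labelset from an explicit labelset
distribution and places its features at the sum of the active labels'
prototypes plus isotropic Gaussian noise — a pure function of its spec,
seed included. The generator emulates exactly the structure that makes
multi-label resampling hard: controllable marginal imbalance and explicit
minority/majority co-occurrence.

`frailty_like_preset()` fixes six labels whose analytic marginals are
proportional to the reciprocals of the published per-label ratios (so the
analytic IRLbl column, MeanIR ≈ 2.85 and CVIR ≈ 0.80 are reproduced by
construction), label cardinality 1.38, 70% of each rare label's occurrences
co-occurring with the most frequent label, and the remaining 30% as pure
single-label mass so strict seed pools are never empty. Features are d = 20
Gaussian prototype mixtures with unit noise — deliberately overlapping, as
administrative health data are; the overlap is what gives Tomek cleaning
boundary pairs to remove.

What the preset does *not* emulate: the real cohort's mixed
demographic/chronic-condition covariates (features here are continuous by
design, since SMOTE interpolation and Euclidean links live in continuous
space), its full labelset joint distribution (only marginals and the
qualitative co-occurrence property are matched; the true 64-combination
structure is unpublished), censoring, and temporal structure. Passing tests
therefore demonstrate the resampler's behaviour on data with the stated
imbalance geometry, not on the cohort itself.

## The experiment protocol

`run_experiment()` mirrors the published evaluation design: the resampler
touches only the training data; each strategy is assessed by k-fold
cross-validation within the (resampled) training data and by a final fit
evaluated on untouched test data, which defaults to the original
unresampled dataset. Two properties of that design are worth naming.
First, cross-validation *within* resampled data is optimistic, because
synthetic instances are near-duplicates of their seeds and straddle folds.
Second, when the test set is the original dataset, a model trained on its
resampled version has seen most test instances; the baseline's
cross-validated row does not share this advantage. Both are properties of
the protocol this package reproduces, not artefacts of the implementation —
under a fully independent-draw protocol (train and test from separate
generator draws) the resampling benefit on this generator's geometry is
much smaller. The directional comparison in the test suite follows the
published protocol and says so in its comments.

## Problem sizes

The suite exercises the resampler at n = 5000 across 20 seeds (the scale at
which the preset's empirical profile is stable), the classifier comparisons
at n in the hundreds to low thousands with 2–10 folds, and the oracles on
hundreds of small random cases — sizes chosen so the whole suite runs in a
few minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* Categorical features are not supported; SMOTE-NC-style interpolation is
  out of scope, and missing feature values are rejected at construction.
* The strict seed pool can be empty for a minority label that never occurs
  alone; the label is then skipped (with a warning) rather than
  oversampled. The `"no-majority"` pool is the built-in relaxation.
* Tomek cleaning is quadratic-ish in the number of instances per majority
  label pass (chunked exact nearest neighbours); datasets beyond ~10^5
  instances will want subsampling or an approximate neighbour index.
* The resampler assumes every label has at least one positive instance and
  refuses otherwise.
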