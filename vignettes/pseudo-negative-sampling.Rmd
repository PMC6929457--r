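---
title: "Pseudo-negative sampling: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-negative sampling: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpcc)
```

## The problem

Many binary classification tasks in bioinformatics — DNA-binding residue
prediction, deleterious SNP calling, and similar annotation problems — are
heavily imbalanced: a handful of experimentally confirmed positives sits
inside a sea of "negatives" that are really just *unannotated* samples. Some
of those unannotated samples are positives in disguise. Training a
classifier against them as negatives both wastes the minority class's signal
and actively teaches the model the wrong boundary.

Pseudo-negative sampling attacks the imbalance from this angle: instead of
inventing synthetic minority points (SMOTE) or discarding majority points
(random undersampling), it looks for the negative-labeled samples that most
resemble the positive class and *relabels* them as positives for training.

## The selection criterion

Samples are compared by the Pearson correlation coefficient (PCC) between
their feature vectors,

$$P(u, v) = \frac{\operatorname{cov}(u, v)}
  {\sqrt{\operatorname{var}(u)\operatorname{var}(v)}},$$

which measures profile-shape similarity and is invariant to the
population-vs-sample variance convention and to positive affine rescaling of
either sample. Two criteria are combined:

* **Max-relevance (MAXR).** A negative sample's relevance $D_i$ is its PCC
  to the positive class. The relevance-only selector takes the $l$ negatives
  with the largest $D_i$.
* **Min-redundancy (MINR).** A candidate's redundancy $R_i$ is its mean PCC
  to the already-selected set; the redundancy-only selector greedily picks
  the candidate minimizing $R_i$.

The joint criterion (MMPCC) runs a greedy forward search from the empty
set: at step $k$ every remaining candidate $i$ is scored by

$$\Psi_i = D_i \;-\; \frac{1}{k-1}\sum_{s \in S^{*}_{k-1}} P(x_i, x_s),$$

with the redundancy term defined as $0$ at the first step, and the
maximizer joins the selected set $S^{*}_{k}$. The selected samples are then
relabeled positive for training (moved between classes, never duplicated —
a pseudo-negative is a mislabeled positive, and duplication would let the
same row vote on both sides of the boundary).

Caching the $n \times m$ relevance block once and updating the redundancy
sums by a single column per step keeps the cost at $O(n\,m\,f + n\,l\,f)$ —
the optimized selectors record their actual correlation-evaluation counts
and the test suite asserts the $n\,m + n\,l$ budget.

## Decisions where the criterion is underdetermined

Several points are not pinned down by the formulas above; the package takes
one documented position on each, with config switches where the alternative
is defensible:

* **Aggregation over the positive set.** $D_i$ involves every positive
  sample $j$; the reduction over $j$ is not specified by the argmax form.
  The default is the **mean** over positives, which is self-consistent with
  the redundancy term (also a mean, over the selected set); `aggregation =
  "max"` is available.
* **Redundancy normalizer.** The batch form of the redundancy criterion is
  sometimes written with $1/|S^*|^2$; the incremental step divides by the
  current selected-set size $k-1$. The incremental form governs here, since
  the algorithm is defined step-wise.
* **Signed correlations.** $P$ is used as printed, signed. An anticorrelated
  sample arguably also "resembles" the positive class, so `use_abs = TRUE`
  opts into absolute values; the default stays with the printed formula.
* **MINR's first step.** Mean redundancy to an empty set is undefined. The
  first pick minimizes mean correlation to all *other* negatives — a
  pure-redundancy rule consistent with MINR's role as the relevance-free
  ablation.
* **Ties.** All argmax/argmin ties break to the lowest original sample
  index, making every selector fully deterministic; `seed` in the config is
  recorded for audit only.
* **Percentage base.** When $l$ is given as a percentage, it is resolved
  against the positive count $m$ by default (`percentage_base =
  "negatives"` switches to $n$), rounding half-up, so that "50% pseudo-
  negatives" reads as "half as many pseudo-negatives as true positives".
  How a percentage sweep is anchored is a genuine open choice; it is
  exposed in the config and echoed in every result.
* **Zero-variance samples.** A constant feature row has no defined PCC.
  Loading fails with the offending row indices rather than silently scoring
  such rows 0 (a silent 0 would distort the argmax); `drop_degenerate =
  TRUE` drops them with a warning.

## Evaluation protocol

Classification quality is summarized by sensitivity, specificity, accuracy
and Matthews correlation coefficient computed from TP/TN/FP/FN, with the
positive class always the *original* minority class. Two conventions cover
corner cases the formulas leave undefined: Sen/Spe of an empty class is
reported as `NA` and excluded from fold means (flagged on the report), and
MCC with a zero factor under the root is 0.

Cross-validation is stratified (class ratios preserved per fold) and
seeded. The sampler is fitted on and applied to **training folds only**;
test folds are scored against original labels, because pseudo-negativity is
a training construct — a sample the selector would have relabeled still
counts as a negative when it appears in a test fold. Whether resampling
belongs inside or before the split is ambiguous in common practice, so
`sample_scope = "whole_dataset"` also implements the leakage-prone variant
for comparison; the report's `sampler_seen_indices` records exactly which
rows the sampler could see, which is how the no-leakage property is tested
rather than merely asserted. Per-feature z-scoring (fit on training folds)
is available behind `standardize`, default off, since both PCC and SMOTE's
Euclidean neighborhoods are scale-sensitive and raw features are the
conservative default.

The classifier registry provides the four learners used throughout —
linear discriminant analysis (`MASS::lda`), random forest
(`randomForest`, 200 trees), a single-hidden-layer neural network
(`nnet`, 5 units, decay $10^{-3}$) and discrete AdaBoost.M1 over
`rpart` decision stumps (50 rounds), whose prediction is the sign of the
weighted weak-learner sum $\operatorname{sign}\sum_m \theta_m f_m(x)$ —
plus a trivial majority predictor for protocol checks. Hyperparameters are
the backends' defaults at these stated values; the harness is not a tuning
framework.

## What the synthetic generator emulates

`generate_planted()` builds the setting the method assumes, with ground
truth attached: `m` positives, `n_true_neg` genuine negatives, and `l_true`
planted pseudo-negatives drawn from the positive distribution but labeled
negative. Both classes are spherical Gaussians with within-class standard
deviation `sd`. Two design choices matter:

* **Class separation is per-feature.** The class means differ by a random
  direction scaled so the per-coordinate RMS offset is `delta * sd`
  (Euclidean distance `delta * sd * sqrt(f)`). `delta` is thus the familiar
  univariate "how many standard deviations apart" knob: at `delta = 0` the
  classes coincide and planted recovery must fall to the chance level
  `l_true / n`; at `delta = 4` the classes are far apart and recovery
  should be nearly perfect. A pilot of the naive reference selector fixed
  the standard validation instance (`m = 20`, `n_true_neg = 180`,
  `l_true = 20`, `f = 10`, `delta = 4`) at a median planted precision of
  0.9 over 20 seeds, which is what the acceptance suite asserts.
* **Profile spread.** Sample-wise PCC responds to profile *shape*, so the
  positive mean profile is itself drawn with spread `profile_sd = 3` (in
  units of `sd`) across features. Smaller spreads flatten all profiles and
  PCC loses its signal even for well-separated classes; the pilot showed
  recovery is stable for spreads of roughly 2–4, and 3 was fixed once as
  the default.

Negative rows are shuffled so plantedness is not encoded in row order (the
deterministic lowest-index tie-break must not correlate with the truth).

The generator deliberately does **not** emulate correlated features,
heavy tails, PSSM score marginals or real UCI feature semantics. Passing
the planted-recovery and trend tests therefore shows the selector does what
its criterion promises under the model's own geometry — not that it will
recover mislabeled positives in any particular real dataset, where
relevance may be a weaker or differently-shaped signal.

## Validation experiments

The suite (and `scripts/acceptance.R`, which recomputes the same
quantities and writes them as JSON) runs at these problem sizes, chosen so
the whole battery completes in well under a minute:

* **Oracle equivalence.** 54 random instances ($n \le 30$, $m \le 10$,
  $f \le 8$, $l \le 10$): every greedy step of all three selectors must
  match a naive brute-force scan built from scalar `pearson()` calls only.
* **Metric closed forms.** 1000 random confusion tables against hand
  formulas at $10^{-12}$, plus MCC bounds and the zero-denominator
  conventions.
* **Planted recovery.** 20 seeds of the standard instance: MMPCC median
  precision $\ge 0.9$ at `delta = 4`, MMPCC and MAXR mean precision above
  MINR's (the relevance-free ablation has no reason to find plants), and
  mean precision within a Monte-Carlo band of the 0.1 chance level at
  `delta = 0`.
* **SMOTE geometry.** 100 synthetic points verified to lie exactly on a
  segment between their base and one of its recomputed $k = 5$ minority
  neighbors with interpolation factor in $[0, 1]$.
* **Sensitivity trend.** Median (over 10 seeds) sensitivity of a
  discriminant-analysis classifier under five-fold CV is non-decreasing in
  the pseudo-negative percentage over $\{0, 10, \dots, 50\}\%$. With 4
  test positives per fold the per-fold sensitivity is granular at 0.25, so
  the fold mean moves in steps of 0.05 and dips within that granularity
  are treated as Monte-Carlo noise.
* **No-leakage audit.** Under `train_folds` scope the recorded
  `sampler_seen_indices` never intersect the corresponding test fold.

## Known limitations

* Greedy forward selection only; no global subset optimization or backward
  elimination, and no automatic choice of $l$ — the number of
  pseudo-negatives is an expert knob, resolved from a count or percentage.
* The selection criterion is validation-free: it never consults a
  classifier, so a pathological feature scaling that distorts PCC will
  distort selection (use `standardize` or rescale upstream).
* The PSSM featurizer consumes pre-scaled scores as given (windows of 9
  residues, zero-padded at chain edges, $9 \times 20 = 180$ features);
  producing PSSMs from sequence databases is upstream of this package.
* MCC on very small folds is noisy, and the zero-denominator conventions
  (NA-and-exclude for Sen/Spe, 0 for MCC) matter there; the report flags
  when they fire.

## A worked example

```{r example}
pd <- generate_planted(m = 20, n_true_neg = 180, l_true = 20, f = 10,
                       delta = 4, seed = 1)
res <- select_mmpcc(pd$dataset, sampler_config("MMPCC", l = 10))
res
recovery_score(res, pd)[c("precision", "recall")]
```
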