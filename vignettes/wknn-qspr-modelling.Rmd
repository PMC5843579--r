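---
title: "Weighted kNN QSPR modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted kNN QSPR modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knnqspr)
```

# The modelling problem

knnqspr builds quantitative structure–property relationship (QSPR) models:
given a table of chemicals with a measured endpoint (a physicochemical
property such as logP or melting point, or a two-class label such as ready
biodegradability) and a numeric molecular-descriptor matrix, it learns a
predictor and — just as importantly — tells the user *when to trust it*.
The design follows the transparency-first school of regulatory QSAR
modelling: a deliberately simple, fully inspectable learner (weighted
k-nearest neighbours), a descriptor subset small enough to interpret
mechanistically, standard external-validation statistics, and a two-tier
applicability-domain (AD) assessment attached to every prediction.

Descriptor *computation* is out of scope: the package consumes precomputed
numeric descriptor tables from any engine (PaDEL-style CSV exports read
directly via `read_descriptors()`), and a pluggable engine hook
(`compute_descriptors()`) is provided for callers who want to wire one in.

# The model

## Weighted k-nearest neighbours

All distances are Euclidean in the *autoscaled* descriptor space: each
descriptor is centred and scaled by its training-set mean and sample
standard deviation (n − 1 denominator; the convention is declared once here
and used everywhere). The scaling parameters are saved with the model and
applied unchanged to every query, so test chemicals are mapped into the
training frame rather than rescaled on their own.

For a query x, the k nearest training chemicals are found (ties at the k-th
distance are broken by training-set order, which makes predictions
deterministic), and each neighbour i receives weight

$$w_i = \frac{1/\max(d_i, \varepsilon)}{\sum_j 1/\max(d_j, \varepsilon)},
\qquad \varepsilon = 10^{-12}.$$

A continuous prediction is the weighted mean of the neighbours' responses;
a classification is the class with the largest summed weight (ties go to
the first class level). If any neighbour sits at distance exactly 0, the
prediction short-circuits to the mean (or majority) of those exact matches —
without this rule an exact duplicate would still be diluted by its other
neighbours. Inverse-distance weighting is the default because it
reproduces classical kNN in the equal-distance limit and concentrates all
weight on exact matches; `1/(1+d)` (Shepard) and `exp(-d)` kernels are
selectable through `weighting=` for users who prefer bounded weights.

The neighbourhood size k is optimized over 3–7 (configurable) by stratified
fivefold cross-validation, choosing the k with the lowest pooled CV error:
misclassification rate for classes and RMSE for continuous endpoints (the
continuous rule is the natural extension of the classification one). Ties —
including ties up to floating-point noise, compared with an absolute
tolerance of 1e-10 — go to the smallest k, favouring the simpler model.

## Dataset curation

Chemicals are grouped by a structure key (any canonical structure string,
e.g. a standard-InChI-style key, optionally suffixed with a salt tag).
Replicated measurements of the same structure are averaged when their range
is at most `sigma` (default 1) times the standard deviation of the whole
dataset; wider groups are treated as mutually inconsistent outliers and
removed entirely. The anchor quantity — the whole-dataset SD — is the
stated basis of the rule; the multiplier is exposed because the exact
cut-off is a judgement call. For qualitative endpoints, discordant
duplicate groups are dropped by default (the analogue of the outlier rule);
`conflict = "majority"` resolves them by strict majority instead, with tied
votes still dropped.

Where the salt form matters (melting/boiling point), the salt flag can be
carried as an ordinary appended descriptor column
(`append_descriptor()`), participating in scaling and distances like any
other descriptor.

## Descriptor filtering

Two filters reduce the raw matrix before selection:

* `remove_degenerate()` drops columns that are constant, near-constant
  (sample SD ≤ 0.25), or contain any missing value.
* `filter_correlation()` enforces a pairwise absolute-correlation ceiling
  of 0.96: while any surviving pair exceeds it, the worst pair is found and
  the member with the larger mean |r| against all other surviving columns
  is removed (ties remove the later column in input order). Correlations
  are re-evaluated after every removal, so the post-condition — no
  surviving pair above the threshold — is guaranteed, and the worst-first
  sweep makes the outcome order-independent. The filter compares |r| by
  default; `use_abs = FALSE` switches to signed r for users who want to
  keep strongly anti-correlated pairs.

Both thresholds are conventional defaults in descriptor pruning and both
are arguments, not constants.

## Genetic-algorithm descriptor selection

Selection couples a GA over binary descriptor-inclusion chromosomes to the
kNN learner. The default budget is 100 independent runs of 100 generations
on 30 chromosomes, with a 0.01 per-gene mutation probability and a 0.5
crossover probability; fitness is the fivefold-CV quality of the encoded
subset (a pooled Q²-style score for continuous endpoints, balanced accuracy
for classes) with k re-optimized in 3–7 for every subset. The all-zero
chromosome is assigned −∞ and can never win. Reduced budgets are plain
arguments (`ga_config(runs =, generations =)`), which is how the tests and
the acceptance script run it (10 runs × 20 generations on 300 × 30
problems).

Three GA operators are not pinned down by convention and were chosen here:
tournament selection of size 2 with elitism of 1 (simple, deterministic
given the seed, and keeps the best-so-far chromosome alive), uniform
crossover applied per mating pair with probability 0.5, and gene
initialisation probability min(0.5, 10/p) so that initial models stay small
when thousands of descriptors are offered. A parsimony penalty
λ·(subset size)/p is available (`lambda`), but the default λ = 0 leaves
the parsimony pressure to the forward-selection rule below, which is more
transparent than a mixed fitness functional.

Selection runs in two rounds: the second round repeats the search on the
top half (ceiling(p/2)) of descriptors ranked by first-round selection
frequency, concentrating the budget and driving the ranking towards a
consistent subset. The final ranking uses round-two frequencies.
`forward_select()` then walks down the ranking, recording the CV fitness of
every prefix (k re-optimized each time) alongside the exclude-self fitting
statistic, and returns the smallest prefix whose CV fitness is within δ
(default 0.01) of the best prefix — minimum descriptors at essentially no
CV cost. The |fit − CV| gap per prefix is reported as an overfitting
diagnostic.

## Validation statistics

For classes: Sn = TP/(TP+FN), Sp = TN/(TN+FP), BA = (Sn+Sp)/2, reported as
ratios. For continuous endpoints: RMSE (and its external-set twin RMSEP),
R² as the coefficient of determination 1 − RSS/TSS, and the external
predictive coefficient

$$Q^2 = 1 - \frac{\sum_{test}(y_i-\hat y_i)^2 / n_{EXT}}
                 {\sum_{train}(y_i-\bar y_{TR})^2 / n_{TR}},$$

which references the test-set error against the training variance. This
form is scale-independent, fixed by a fixed RMSEP, and invariant to
splitting the external set into subsets — properties the tests verify
directly.

Cross-validation in `kfold_cv()` is stratified (per class, or per
response decile for continuous data) and leak-free: scaling is refit inside
every fold, and when k is not fixed it is re-optimized on each fold's
training part. Out-of-fold predictions are *pooled* and summarised once,
mirroring the pooled form of Q² above, rather than averaged over folds.
One deliberate exception: inside `optimize_k()` and the GA fitness the
training table is autoscaled once before CV — there the CV is a relative
ranking device over thousands of subsets, and refitting the scaler per fold
per chromosome would multiply the cost for no change in ranking.

Training-set ("fitting") statistics are computed from exclude-self
(leave-one-out) predictions: with a kNN learner the in-sample prediction of
a training chemical is the chemical itself (the exact-match rule), so
naive training statistics would be vacuously perfect.

## Applicability domain and prediction reliability

Two independent, distance-based tiers:

* **Global leverage.** h = xᵀ(XᵀX)⁻¹x on the scaled training matrix of the
  model's descriptors; training leverages are the diagonal of the hat
  matrix. Queries with h above 3p/n are outside the global AD. A
  rank-deficient XᵀX (collinear descriptors) is inverted with the
  Moore–Penrose pseudo-inverse at the standard tolerance, which reproduces
  the ordinary inverse exactly in the full-rank case.
* **Local 5-NN index.** A continuous [0, 1] similarity to the five nearest
  training neighbours: index = exp(−d̄_w / c), where d̄_w is the mean 5-NN
  distance weighted by the model's own neighbour weights. The functional
  form is a design choice; what is pinned down is its calibration: c is set
  so that the 95th percentile of the *training chemicals' own*
  leave-one-out d̄_w values maps to 0.4 — i.e. the 0.4/0.6 interpretation
  bands are anchored to the data's own distance scale, and roughly 5% of
  training chemicals would sit below the 0.4 line. A query identical to a
  training chemical scores exactly 1 by rule.

The interpretation table is the deterministic product of the two tiers:
outside + index < 0.4 → `unreliable`; outside + 0.4–0.6 →
`boundary_average`; outside + > 0.6 → `boundary_trusted`; inside +
0.4–0.6 → `gap_caution` (the query falls in a gap of the model's chemical
space); inside + > 0.6 → `reliable`. The band [0.4, 0.6] is closed at both
ends. The combination inside + index < 0.4 belongs to no documented case;
it is mapped to `gap_caution` and flagged (`flagged = TRUE`) so downstream
consumers can treat it specially.

Each prediction also carries a **confidence level**: the distance-weighted
leave-one-out accuracy of the five nearest neighbours,
Σwⱼaⱼ / Σwⱼ with aⱼ = 1/(1 + |yⱼ − ŷⱼᴸᴼᴼ|/s) for continuous endpoints and
aⱼ = 1{neighbour j correct in LOO} for classes. The accuracy scale s is the
leave-one-out RMSE of the training set: an in-sample RMSE would be
identically zero under the exact-match rule and make the kernel degenerate,
so the LOO error scale is the right normaliser — a neighbour predicted
about as well as the average training chemical scores a ≈ 0.5.

# The synthetic-data generator

`simulate_qspr()` stands in for curated experimental property datasets so
that every stage is testable without downloads. It emulates exactly the
features the pipeline keys on: independent standard-normal background
descriptors; a linear latent signal over chosen informative columns with
Gaussian noise (classification labels by thresholding the latent at the
rank quantile implied by the class balance, giving exact class counts and a
noise-controlled Bayes error); collinear column pairs at a target
correlation; near-constant columns; missing cells; and
`inject_duplicates()` for the duplicate-merging rule with a known
merge/drop ground truth.

What it does **not** emulate — and what passing tests therefore do not
show — is the character of real molecular descriptors: heavy-tailed and
discrete count distributions, block-wise correlation structure among
descriptor families, non-linear structure–property relationships, activity
cliffs, and measurement error that varies by source. Results on the
synthetic conditions demonstrate that the machinery is correct (signal
recovery, statistics, AD geometry), not that any particular real endpoint
will reach a given Q².

Problem sizes used by the test-suite and the acceptance script — 300
chemicals × 30 descriptors with 3 informative columns (noise SD 0.1) for
selection, 500 × 3 noiseless for predictive recovery, GA budget 10 runs ×
20 generations — were chosen as the smallest instances on which recovery of
the planted signal is clean and repeatable across seeds.

# Numerical choices, degenerate inputs, determinism

* Sample SD (n − 1) everywhere a standard deviation is estimated.
* Distance floor ε = 1e-12 in inverse-distance weights; exact-match rule
  fires only at distance exactly 0.
* Float-noise ties in k optimization and prefix fitness are collapsed with
  an absolute 1e-10 tolerance before applying the "smallest k / smallest
  prefix" rules.
* All randomness (splits, folds, GA runs) flows from a single integer seed,
  expanded into per-component sub-seeds by one documented derivation
  (`sample.int` under the master seed); RNG state of the caller is saved
  and restored. Repeated runs are bit-identical, and the CLI pipeline is
  byte-stable across reruns at a fixed seed.
* Models persist to a single JSON text file with 17 significant digits,
  which round-trips IEEE doubles exactly: a reloaded model reproduces
  predictions bit for bit, and its AD assessor is rebuilt deterministically
  from the stored training data.
* Degenerate inputs fail loudly and early: empty matrices, all-degenerate
  descriptor sets, zero training SD (named column), constant responses in
  R²/Q², classes absent from a CV fold, k outside [1, n−1].

# Known limitations

* The two filtering thresholds (0.96, 0.25) and the AD bands (0.4/0.6,
  3p/n) are conventional but not adaptive; unusual descriptor sets may want
  different values, and all are exposed as arguments.
* The local AD index's exponential form is one reasonable monotone map from
  distance to [0, 1]; only its calibration point is data-driven.
* Forward selection explores prefixes of one frequency ranking, not all
  subsets; a descriptor useful only in combination with a low-ranked
  partner can be missed — the price of the transparent selection path.
* The GA fitness ranks subsets by a CV score whose folds are fixed per
  selection call; very small datasets (tens of chemicals) will show fold
  noise in the rankings.
* Multi-class endpoints are supported by the learner and macro-averaged
  balanced accuracy, but the confusion-matrix report and the stratified
  split's exactness guarantees are designed around the two-class case.
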