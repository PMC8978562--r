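---
title: "Methods: correlation-redundancy and interaction analysis for discrete feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-redundancy and interaction analysis for discrete feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the parameters that matter, the numerical choices, and
the limits of what the test suite demonstrates.

## Estimation model

All information measures are **plug-in estimates on categorical data**:
probabilities are empirical frequencies, joint distributions are exact
row-tuple counts, logarithms are base 2 (bits), and `0·log 0 = 0`. This
is the natural estimator once the data are discrete — GISTIC copy-number
calls already are, and continuous inputs pass through MDLP
discretization first. No bias correction (Miller–Madow and kin) is
applied and no continuous/differential entropies are ever computed; the
multivariate dependence measure is the *discrete* copula entropy, which
for categorical variables is exactly the negative total correlation

$$TC(X_1,\dots,X_q) \;=\; \sum_i H(X_i) - H(X_1,\dots,X_q),$$

so the package computes it through entropy sums rather than a copula
density integral. Plug-in estimates from a common sample keep every
derived quantity (MI, CMI, joint MI, total correlation) non-negative up
to floating-point noise; tiny negatives above −10⁻¹² are clamped to
zero, anything more negative would indicate a bug and is left visible.

Assumptions worth stating: samples are i.i.d. rows; category codes have
no ordering semantics inside the estimators (the decision-tree
classifier is the one deliberate exception, treating codes as ordinal,
which suits copy-number dosage); and missing values are rejected at the
estimator layer — any imputation or filtering must happen before a
`feature_matrix` is built.

## The selection criterion

A candidate $f$ against the selected set $\Omega_S$ and class $c$ scores

$$J(f) = \Big[\,SU(f,c) - \tfrac{1}{n_s}\textstyle\sum_{f_s\in\Omega_S} SU(f,f_s)\Big]\times \frac{TC(\Omega_S, f, c)}{TC(\Omega_S, c)}.$$

Symmetrical uncertainty rather than raw MI is used for relevance and
redundancy because MI inflates with alphabet size; SU normalizes by the
marginal entropies into [0, 1]. The interaction factor is a ratio of
total correlations over the *whole* selected subset, not a three-way
term against individual members: it asks how much multivariate
dependence the candidate adds on top of what $\Omega_S$ and $c$ already
share. Because adding a variable can only grow total correlation, the
factor is ≥ 1 whenever its denominator is positive — so it amplifies
but never flips the sign of the relevance−redundancy margin. Two
consequences the tests lean on: an exact duplicate of a selected
feature has margin ≤ 0 and can only be picked when nothing positive
remains, and the score's sign is interpretable on its own.

Degenerate denominators get neutral guards: if $TC(\Omega_S, c) \le
10^{-12}$ (selected set carries no dependence with the class) the
factor is defined as 1, preserving the margin ordering; SU of two
constant vectors is defined as 0 (a constant feature carries no
information). The identity $J$ computed through the TC ratio versus the
fully expanded entropy form is asserted to $10^{-10}$ on random states
in the suite.

## The greedy engines

Stage 1 picks the **main-effect feature**, the SU argmax with the
class. Each later round re-scores all candidates and adds the argmax.
Ties are broken towards the lowest original column index — the
tie-break had to be *some* fixed rule, and first-index makes runs
reproducible and oracle-comparable. The loop stops when exactly `M`
features are selected; the trace preserves selection order and stores
the score decomposition (relevance, redundancy, interaction factor) per
round.

The eleven comparator criteria run through the same engine. Their
first pick uses each criterion's own relevance measure: SU for the
weighted SU-based family (DWFS, IWFS, RAIW), plain MI for the rest —
with an empty selected set every criterion's objective reduces to
exactly that quantity, so the seeding is not a special case so much as
the objective evaluated at $\Omega_S=\emptyset$. Design points that were
genuinely open:

* **DWFS weight factor.** The two published renderings of the update
  disagree algebraically; the package implements the
  interaction-information form $1 + 2\,I(f;f_s;c)/(H(f)+H(c))$, which is
  consistent with the three-way interaction convention used everywhere
  else in the family.
* **RAIW.** Its redundancy term names "one of" the selected features;
  the package uses the most recently selected one, and defaults the
  redundancy coefficient to $\alpha = 1/n_{features}$ (overridable),
  matching the stated dependence of $\alpha$ on the dataset's feature
  count.
* **CMI criterion.** Its printed form is typeset ambiguously; the
  implemented reading is
  $I(f;c) - \frac{H(f|c)}{H(f)}\sum_s I(f_s;c)\,I(f;f_s)/(H(f_s)H(c))$
  with zero-entropy terms contributing 0.

Caching: pairwise SU/MI terms, per-candidate weight factors and the
joint row-tuple codes of $\Omega_S$ are memoized, but the cached
aggregates store raw per-round terms and re-reduce them with
`sum()`/`prod()`/`min()`, so cached scores are bit-identical to the
from-scratch scorers — the suite compares every engine's pick sequence
to a brute-force per-round oracle with `identical()`, tie rule
included.

## MDLP discretization

Continuous features are cut by recursive entropy minimization with the
minimum-description-length stopping rule: candidate thresholds are
midpoints between consecutive distinct values at class boundaries, the
best-gain split is kept iff

$$Gain > \frac{\log_2(N-1) + \log_2(3^k-2) - [\,k\,H(S) - k_1 H(S_1) - k_2 H(S_2)]}{N},$$

and recursion continues in both children. Ties in gain prefer the
smaller cut. A feature may end with no cuts (collapsing to a single
bin, i.e. dropped from the information measures' point of view) — that
is the intended behaviour for uninformative columns. Integer-valued
columns are treated as already discrete by default (`skip_discrete`),
since copy-number calls must not be re-binned against the labels.
Labels-aware discretization performed once on the full data leaks label
information into CV folds; the evaluation functions therefore accept
already-discrete matrices and the discretization step is kept explicit
and separate so users can place it inside or outside their resampling
loop as their protocol requires.

## Cross-validation, IFS and metrics

Folds are stratified by class (disable with `stratify = FALSE`) and
fully determined by an integer seed; within each class, shuffled
indices are dealt round-robin, continuing the deal across classes so
global fold sizes differ by at most one. The IFS curve reuses the same
folds across all prefix sizes within a repeat, so adjacent curve points
differ only by the added feature, and defines the optimal subset size
as the *smallest* maximizer of mean accuracy. Metrics follow the
one-vs-rest convention with 0/0 defined as 0; accuracy is the confusion
matrix trace over the total; the run-level dispersion is the
*population* standard deviation over per-repeat accuracies (the
per-run mean is a complete population of runs, not a sample, and this
reading is the one that yields non-degenerate values).

Bundled classifiers: 1-NN with the Hamming/overlap metric (the natural
instance-based learner for nominal codes, deterministic via
earliest-index tie-breaks), categorical naive Bayes (via `e1071`,
Laplace 1), a decision tree (via `rpart`), and a majority-class floor.
Gradient-boosting or SVM learners plug in through `new_classifier()`
without being dependencies.

## The synthetic generator

The generator emulates exactly the structure the criteria are designed
to detect: *main* features are the label through a symmetric
category-flip channel; *redundant* features copy mains (by default
exactly — duplicates are the sharpest test of redundancy handling);
*interaction pairs* are $(u,\; u \oplus label)$ for binary labels, the
one construction with zero marginal and maximal joint information;
*noise* is uniform and independent. Defaults — 1000 samples, 2 classes,
5 main + 5 redundant + 40 noise, label flip 0.05 — are the package's
standard study conditions: large enough that plug-in MI bias (~
alphabet/2n bits) is far below the main-feature signal, small enough to
run everywhere. All randomness streams from one seed; identical specs
give byte-identical data.

What the generator does **not** emulate: segment-length and GC
structure of real CNV profiles, correlated noise between neighbouring
genes, class imbalance beyond priors, multi-class synergy (the XOR
construction is binary by design). Passing tests therefore demonstrate
correctness of the estimators and engines under known structure — not
that CRIA will outrank its comparators on any particular real cohort.

## Problem sizes and verification scope

The suite verifies estimators against direct probability-table
summation on 200+ enumerated joint distributions (≤ 4 variables, ≤ 3
categories) realized as exact samples; the copula-entropy identity on
100 random fixtures; both algebraic routes to the CRIA score on 100
random states; and all twelve engines against the exhaustive oracle on
12-feature fixtures with M = 6. Ranking recovery uses 20 replicates of
the default fixture; the IFS and CV checks use 200–1000 samples with
5–10 folds and 2–10 repeats. These sizes were chosen to make the whole
suite run in well under a minute per concern while keeping every
assertion exact or tightly toleranced; scaling up is a matter of the
user's patience, not of the algorithms (selection is
O(M · n_features · n · n_s) in the worst case, dominated by joint
entropy counting).

## Known limitations

* Plug-in entropies are biased upward on small samples; with very many
  candidate features the stage-1 SU ranking can favour chance
  associations. The generator's structure report exists precisely to
  quantify that on synthetic data.
* The interaction factor saturates as $\Omega_S$ grows: once the joint
  of the selected set approaches distinct-row granularity, total
  correlations change little and the margin dominates. With `M` near
  the sample size, late-round scores are mostly relevance−redundancy.
* `M` defaults to 200 at the command line — a dimensionality cap, not a
  recommendation; the IFS curve is the principled way to choose the
  final subset size.
* The continuous copula-density route to multivariate dependence is out
  of scope by design; only the discrete entropy-decomposition route is
  implemented.
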