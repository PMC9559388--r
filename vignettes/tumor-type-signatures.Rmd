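---
title: "Classifying tumor types from mutation profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor types from mutation profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A tumor sample can be summarized by the set of genes carrying somatic
mutations. Different cancer types preferentially disrupt different biological
programs, so the *functional footprint* of a mutation set — which pathways it
hits, which network neighborhoods it lives in — carries a tumor-type signal
even when the individual mutated genes differ from patient to patient.
`tumorsig` implements a complete pipeline that turns per-sample mutated-gene
sets into three complementary feature families, screens and ranks those
features, selects a compact predictive subset by incremental feature
selection, and extracts human-readable decision rules.

The pipeline is exercised end-to-end on synthetic cohorts with *planted*
class-specific driver pathways, so every stage has a recoverable ground truth.

## Feature encodings

**Enrichment features.** For a sample with `n` in-universe mutated genes, of
which `m` fall in a gene set of size `M` drawn from a universe of `N` genes,
the score is

\[
\mathrm{score} = -\log_{10}
\sum_{k=m}^{\min(n,M)} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},
\]

the upper-tail hypergeometric probability of an overlap at least as large as
observed. One score per (sample, term) pair gives the enrichment block. The
tail is evaluated in log space (log-gamma terms combined by log-sum-exp), so
overlaps that would underflow a direct summation remain finite; scores are
capped at 300 (`p ~ 1e-300`) to keep downstream learners in a bounded range.
An overlap of zero scores exactly 0 — the tail probability is 1 by
definition, not by rounding. The universe is always the catalog's declared
gene list: profile genes outside it are dropped from both `n` and `m`, which
keeps the score self-contained and independent of any annotation release.

**Text features.** Each sample's gene set is treated as a sentence of gene
"words" and a skip-gram model with negative sampling learns one vector per
gene; a sample is the arithmetic mean of its genes' vectors. Because a gene
set is unordered, tokens are shuffled per sentence under a seed rather than
sorted — sorting would manufacture alphabetical co-occurrence windows. The
default width is 256; validation runs use 32, which preserves the
co-occurrence geometry at a fraction of the cost. One implementation note:
negative samples matching *either* member of the training pair are skipped.
With vocabulary sizes typical of gene panels (hundreds to thousands, versus
the 10^5+ of natural-language corpora) partner-and-self negatives are drawn
often enough to anti-align exactly the tokens that co-occur most; skipping
them restores the intended geometry, which we verify with a
planted-structure corpus property (co-occurring genes closer in cosine than
never-co-occurring ones across seeds).

**Network features.** A weighted gene-interaction graph (edge confidences in
(0, 1]) is explored by second-order biased random walks: the step from `v`
with predecessor `t` is proportional to `alpha(t, x) * w(v, x)`, where
`alpha` is `1/p` to return to `t`, 1 for `x` adjacent to `t`, and `1/q`
otherwise; the first step uses weights alone. Defaults `p = q = 1`,
walk length 80, 10 walks per node. Walks feed the same skip-gram trainer
(nodes as words, walks as sentences; default width 500, validation width
32), and samples again average their member-gene vectors. Genes absent from
the graph are skipped in the average; a sample with no embedded genes gets a
zero vector and a warning rather than an error, since downstream stages can
still proceed.

## Screening and ranking

**Shadow-feature screening.** Each iteration appends a permuted copy of every
feature, fits a 200-tree random forest, and scores a "hit" for features
whose impurity importance beats the best shadow. Hits accumulate and a
two-sided binomial test (p = 0.5, Bonferroni-corrected across the currently
undecided features) promotes features to accepted or rejected; survivors at
the iteration cap stay tentative and are excluded from ranking by default (a
hard cut, matching the practice of retaining a fixed important set).
Zero-variance features are auto-rejected up front.

**Four rankers.**

* *lasso* — one-vs-rest L1-penalized regressions on class indicators over
  standardized features; score = max |coefficient| across classes. The
  one-vs-rest reading is a design choice: a single linear regression on an
  11-way label has no defensible encoding. Lambda comes from seeded 5-fold
  cross-validation.
* *mRMR* — greedy difference-form selection on features discretized to three
  states at mean ± one standard deviation: maximize label relevance minus
  mean redundancy, both as mutual information. The greedy trajectory is
  tested against a brute-force oracle.
* *MCFS* — `c` stratified resamplings × `s` random projections of
  `m` features each train one decision tree; a feature's relative importance
  accumulates (balanced test accuracy)^u × information gain × (node
  fraction)^v over its splits, with `u = v = 1`. Zero-importance features
  are dropped from the list. Defaults `c = 20`, `s = 100`,
  `m = ceil(0.05 d)`, train fraction 0.66.
* *GBDT* — a histogram-based gradient-boosted ensemble (31 leaves,
  learning rate 0.1, 100 rounds); score = number of splits using the
  feature, i.e. frequency importance rather than gain.

## Incremental feature selection

For a ranked list, prefixes of size `step, 2 step, ...` (and always the full
list) are each evaluated by stratified 10-fold cross-validation. Within each
fold the training part — and only the training part — is SMOTE-balanced:
every class is upsampled to the majority count by interpolating a minority
sample toward one of its `k = 5` nearest same-class neighbors with a
uniform weight. Class imbalance is the norm in tumor cohorts, and weighted
F1 (class-support-weighted mean of per-class F1) is therefore the selection
objective; accuracy, macro F1 and the multiclass Matthews correlation
coefficient are reported alongside. MCC is computed as
`cov(X, Y) / sqrt(cov(X, X) cov(Y, Y))` over one-hot true/predicted
matrices, which we verify equals the standard confusion-matrix closed form
to machine precision.

Out-of-fold predictions are pooled before computing metrics (per-fold
averaging is unstable when a small class lands few samples in a fold). The
*optimal* prefix is the smallest one attaining the maximum weighted F1
(parsimony breaks ties); the *feasible* prefix is the smallest one within
`delta = 0.05` of that maximum — an explicit surrogate for the practice of
trading a little performance for a much smaller feature set. Classifier
plug-ins use fixed reference defaults: CART (Gini, fully grown), random
forest (100 trees), and an RBF-kernel SVM; features are standardized with
training-fold statistics for the SVM.

## Rule extraction and reporting

A decision tree fit on all samples over the selected features yields one
IF-THEN rule per leaf (root-to-leaf path), with repeated predicates on a
feature collapsed to the tightest interval, the leaf's majority class as the
consequent, and support/purity recorded. Thresholds are midpoints between
observed values, so the `<=`/`>` predicate form replays the tree's
predictions exactly on training data, which is asserted as a test. Feasible
feature sets from the four rankers are intersected (membership tiers, core
set) and broken down by feature type, mirroring how one would compare what
independent selection methods agree on.

## The synthetic cohort generator

The generator plants exactly the structure the analysis assumes and nothing
else:

* a universe of `n_genes` synthetic identifiers and `n_terms` gene sets with
  sizes uniform on a range — default 2,000 genes, 150 terms of 10–200 genes;
* per class, `drivers_per_class` driver terms (disjoint across classes
  whenever the catalog allows, so recovery is unambiguous);
* per sample, a negative-binomial mutation count (mean 30, dispersion 1.5,
  floored at 3) — tumor mutation burden is heavily overdispersed across
  patients; each mutation comes from the class's driver-gene union with
  probability `signal_fraction` (default 0.5) and from the whole universe
  otherwise, then duplicates collapse;
* imbalanced class sizes by default (60/160/130/80/120/50 across six
  classes), echoing the roughly 3:1 spread of real pan-cancer cohorts;
* an interaction graph whose edges appear with probability 0.3 inside terms
  and 0.002 elsewhere, weighted by rescaled Beta(2, 2) confidences in
  (0.15, 0.999], so network communities align with gene sets.

What it deliberately does **not** model: mutational signatures
(trinucleotide context), gene length and copy-number biases, inter-patient
contamination, or annotation-graph structure (a gene can belong to several
terms only by chance overlap). Passing the recovery tests therefore shows
the machinery is sound — planted signal in, planted signal out — not that
any particular real cohort will reach a given accuracy.

## Validation scale and numerical choices

The standard validation cohort is 6 classes / 600 samples / 2,000 genes /
150 terms at `signal_fraction = 0.5`, with embedding widths reduced to 32
for both encoders; screening runs 50 iterations and IFS uses step 10 with
10-fold cross-validation. These sizes keep a full end-to-end run on a single
CPU in the minutes range while leaving every stage's statistics
interpretable. The leakage regression uses mildly imbalanced pure-noise
cohorts so that SMOTE actually fires inside folds; the expected weighted F1
is the 1/K chance level, and exceeding it systematically would indicate
balancing leaked across the fold boundary.

Determinism: every stochastic stage derives its own RNG stream from one user
seed (generator, shuffles, shadow permutations, folds, SMOTE, classifier
fits, embedding training — the latter single-threaded on purpose), so
identical inputs and seeds give bit-identical outputs. Ties in rankings
break by input feature order; at equal weighted F1 the smaller prefix wins;
degenerate metric denominators (an all-one-class prediction) define MCC as
0; `m = 0` overlaps score exactly 0.

## Limitations

Enrichment scores are features, not inferences — no multiple-testing
correction or annotation propagation is applied, and catalog gene sets are
taken as given. The skip-gram and walk hyperparameters are reference
defaults, not tuned values. The feasible-prefix `delta` rule is a documented
surrogate for an informal "good enough with fewer features" judgement. Real
cohorts bring batch effects, panel differences and annotation versioning
that the synthetic generator intentionally omits.
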