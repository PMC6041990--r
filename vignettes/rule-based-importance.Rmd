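---
title: "Rule-based importance of positive feature values in Random Forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based importance of positive feature values in Random Forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compactfv)
```

## The problem

Gene Ontology (GO) annotations are the standard binary feature set for
predicting gene properties: feature `f` is 1 when the gene is annotated with
term `f` and 0 otherwise. The two values are not symmetric. A positive value
is curated evidence that the gene has a biological property; a negative
value is only *absence of evidence*. Conventional Random Forest (RF)
variable-importance measures (Gini decrease, permutation importance, usage
frequency) score a feature as a whole, so for sparse binary annotations they
are dominated by the uninformative negative value, which classifies the vast
majority of instances.

This package scores the *positive value* of each binary feature instead.
Every root-to-leaf path of a random tree is an IF–THEN rule: the conditions
along the path form the IF part, the leaf's majority in-bag class the THEN
part. For a binary feature $f$ and class $c$ we pool, over all trees and all
rules that test $f$ positively and predict $c$:

* $\mathrm{Cov}_{f+c}$ — the number of out-of-bag (OOB) instances covered by
  those rules,
* $\mathrm{Hits}_{f+c}$ — the covered OOB instances whose true class is $c$,
* $\mathrm{Prec}_{f+c} = \mathrm{Hits}_{f+c} / \mathrm{Cov}_{f+c}$ — the
  rule-based precision, the importance of $f$'s positive value for $c$.

OOB instances are essential: each tree is evaluated only on instances it was
not trained on, so the statistics are not optimistically biased. A feature
whose positive value is never tested by any rule predicting $c$ has
$\mathrm{Cov} = 0$ and its precision is *undefined* — it is excluded from
rankings, never coerced to 0 or 1.

The worked example shipped as `worked_example_forest()` fixes three rules
that test `GO:0006887` positively and predict class N, with stored OOB class
distributions (N:35, U:1), (N:145, O:2, U:3) and (N:7, U:3); the pooled
precision is $(35+145+7)/(36+150+10) = 187/196 = 0.9541$. The fixture
supplies the OOB leaf statistics literally, so this regression test is exact
and independent of training stochasticity.

```{r}
sc <- compact_fv(worked_example_forest())
subset(sc, feature_id == "GO:0006887" & class == "N")
```

## The Random Forest engine

The forest is grown in the package rather than taken from an existing RF
implementation because the rule statistics need per-tree bookkeeping that
those implementations do not expose: the exact in-bag multiset, the OOB set,
the balanced training multiset after under-sampling, and leaf-level class
counts. Design choices, each of which matters for reproducibility:

* **Bootstrap.** Each tree draws $n$ instances with replacement; the OOB set
  is the complement of the drawn support (about $1-(1-1/n)^n \approx 36.8\%$
  of instances for large $n$).
* **Under-sampling** (optional, recommended for the 2.4% / 0.8% / 96.8%
  class skew of the motivating data): occurrences of over-represented
  classes are deleted from the in-bag multiset, uniformly without
  replacement, until all classes match the minority count. Deleted instances
  are *not* added to the OOB set — the tree has nearly seen them, so
  crediting them as held-out would leak optimism into the rule statistics.
  Test folds are never rebalanced.
* **Splits.** Gini impurity minimization over `mtry` candidate features
  resampled at every node. Binary features split 0 vs 1; the numeric
  total-annotation feature tries midpoints between consecutive observed
  values. Ties in impurity resolve to the lowest feature index, then the
  lowest threshold; leaf-class ties resolve in the fixed class order
  (O, U, N). These tie-breaks make a (dataset, configuration, seed) triple
  fully determine the model.
* **Stopping.** A node becomes a leaf when it is pure, holds fewer than
  `min_node_size` (default 2) in-bag instances, or no candidate split
  reduces impurity. A binary feature that is constant on a node's rows is
  skipped as a candidate, so binary re-tests along a path cannot occur.
* **Seeding.** One RNG stream per tree, derived from `seed` and the tree
  index, so the first $k$ trees are identical whatever `ntree` is.

## The IPM baseline

The Intervention in Prediction Measure counts, for each tree and each of its
OOB instances, how often each feature is tested on the instance's
classification path, normalizes the count vector to sum to 1, and averages
over all (tree, instance) OOB pairs — by default grouped by the instance's
true class, since per-class rankings are what the rule-based measure is
compared against. Two readings of the averaging are possible; the package
uses a flat mean over pairs, with mean-of-per-tree-means behind the
`averaging` argument. Zero-length paths (single-leaf trees) carry no usage
information and are skipped. Unlike the rule-based measure, IPM scores a
feature as a whole, and the numeric total-annotation feature is included —
on both synthetic and real annotation data it tends to rank first, precisely
because IPM rewards frequency of use rather than the accuracy of one feature
value.

## Dataset preparation

`parse_obo()` reads the `is_a` skeleton of an OBO 1.2 file (obsolete terms
dropped, `relationship:` lines ignored — an annotation implies only its
is-a ancestors). `build_annotation_matrix()` closes each gene's annotation
set under ancestry, then assembles a binary matrix with sorted gene rows and
sorted term columns so output is byte-reproducible. `filter_min_support()`
removes terms annotating fewer than 10 instances (configurable), the usual
guard against terms with too little statistical support. The numeric
`"total"` feature is the size of a gene's annotation set; the package counts
it **after closure and before filtering** — closure is part of what an
annotation means, while the support filter is a statistical device — and
`add_total_feature()` simply counts the current matrix, so a user who
prefers another convention can reorder the pipeline. Terms present in
annotation files but absent from the ontology are skipped with a warning by
default (annotation and ontology releases routinely drift apart); strict
mode is available.

## Evaluation protocol

AUROC is computed in its Mann–Whitney form (fraction of positive–negative
pairs ranked correctly, ties credited 0.5), which is exact and needs no
curve construction. Multiclass performance is the one-vs-rest AUROC per
class, weighted by class instance counts; classes undefined in a fold are
dropped with weight renormalization. `nested_cv()` runs stratified outer
folds with an inner stratified grid search over
`mtry` $\in \{\lfloor 0.5\sqrt J\rfloor,\ \mathrm{round}(\sqrt J),\
\mathrm{round}(2\sqrt J)\}$ and `ntree` $\in \{100, 200, 300\}$; the winning
pair per outer fold refits on the training portion and is scored on the
held-out fold. Folds are stratified because with a 0.8% minority class,
unstratified folds can lose the class entirely. The rounding convention —
floor for the 0.5 multiplier, half-up otherwise — reproduces 43 candidate
features at $J = 7490$. The modal pair across outer folds
(`select_final_params()`, ties to larger `ntree` then smaller `mtry`) is
the configuration for a final model trained on all data.

## The synthetic-data generator

`generate_ontology()` builds a layered single-root DAG (layer sizes double
with depth; every non-root term has one parent in the previous layer plus an
occasional second parent), and `generate_dataset()` draws instances from the
class prior (defaults O 2.4%, U 0.8%, N 96.8%, matching the motivating
study), plants a small set of deep leaf terms whose positive values imply a
minority class with a stated penetrance (default 3 features per minority
class at penetrance 1), adds independent background annotations at rate 0.05
per gene–term pair, and closes everything under ancestry. Minority counts
are floored at 20 instances so that stratified cross-validation remains
feasible at the default desk scale of 2,000 genes × 300 terms.

What the generator emulates: sparsity, ancestor closure (so planted signal
leaks upward into ancestors, as real annotation signal does), extreme class
imbalance, and rare-but-reliable positive feature values. What it does not:
real GO topology statistics, evidence codes, correlated annotation modules,
or any model of expression data. Passing the planted-recovery tests
therefore shows that the measure finds rare high-precision positive values
under imbalance and closure — not that it reproduces the biological rankings
of any particular real dataset.

## The ranking protocol and why `mtry` is small

Study-condition checks in the test suite use: 2,000 genes × 300 terms,
penetrance 1, background rate 0.05, 20 generator seeds; forests of 2,500
under-sampled trees with `mtry = 4` and default stopping; rankings by
precision, then coverage, then feature id. Two numerical phenomena drove
the forest size and candidate-subset size:

* **Small-coverage flukes.** In few-tree forests a background feature can
  appear positively in a single rule that happens to cover one or two OOB
  instances correctly, giving it a perfect precision on negligible coverage.
  Because rankings are precision-first, such features outrank genuinely
  predictive ones. Growing the forest removes them: every feature with a
  non-negligible appearance rate accumulates coverage, and its precision
  converges to its true value. 2,500 trees suffice at desk scale.
* **Context-selection bias.** With larger candidate subsets, a background
  feature is positively tested almost only where it (by chance) improves an
  already-refined minority-class path, so the few rules it appears in are
  systematically the best ones, and its pooled precision is biased upward
  relative to planted features that appear in *all* rules, shallow and deep.
  A small candidate subset (`mtry = 4` here, about $J/75$) randomizes the
  contexts in which features are tested and removes this selection bias at
  the cost of individually weaker trees — an acceptable trade for a
  measure that pools statistics across the whole ensemble.

The cross-validation smoke configuration in the tests (1 run of 2 outer × 2
inner folds, `ntree` ∈ {50, 100}) is a deliberately small instantiation of
the protocol used to verify that the planted fixture is separable
end-to-end; per-class AUROCs at this scale are computed by the test itself.

## Degenerate inputs and numerical notes

* Gini impurity is undefined (error) on all-zero counts; precision is
  undefined (NA) at zero coverage; AUROC is an error when either class is
  empty.
* Impurity comparisons use a $10^{-12}$ slack so floating-point noise cannot
  override the deterministic tie-break order.
* IPM normalized vectors sum to 1 within $10^{-12}$ per pair; per-class
  scores sum to 1 within $10^{-9}$ over thousands of pairs.
* Forest serialization writes thresholds at full precision; a JSON
  round-trip reproduces routing and statistics exactly.

## Known limitations

* Rule-based precision is a ratio estimate; at very small coverage it is
  noisy, and the ranking deliberately reports coverage alongside precision
  so users can judge support. Consider `compact_fv_repeats()` to average
  over model rebuilds when reporting.
* Negative feature values are unscored by design; a feature whose *absence*
  is predictive will be invisible to this measure (and visible to IPM).
* The engine is plain R and targets desk-scale data (thousands of genes,
  hundreds of terms); the real-data scale of the motivating study (17,716 ×
  7,490) is reachable but slow without under-sampling.
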