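# compactfv

Rule-based importance of **positive feature values** in Random Forests, for
sparse binary annotation data such as Gene Ontology (GO) term features.

## Why

For GO-style binary features the two values are not symmetric: a positive
value (the gene *is* annotated) is curated evidence, while a negative value
is only absence of evidence. Classical RF importance measures (Gini
decrease, permutation importance, usage frequency) score a feature as a
whole and are therefore dominated by the uninformative negative value, which
classifies most instances. This package scores the positive value alone.

Every root-to-leaf path of a random tree is an IF–THEN rule. For a binary
feature *f* and class *c*, pooled over all trees and all rules that test *f*
positively and predict *c*:

* **Cov**<sub>f+c</sub> — out-of-bag (OOB) instances covered by those rules;
* **Hits**<sub>f+c</sub> — the covered OOB instances whose true class is *c*;
* **Prec**<sub>f+c</sub> = Hits<sub>f+c</sub> / Cov<sub>f+c</sub> — the
  rule-based precision, the importance of *f*'s positive value for class *c*
  (undefined when Cov = 0; such features are excluded from rankings).

The package provides everything needed to use and test the measure
end-to-end: an OBO (`is_a`) reader with ancestor closure and minimum-support
filtering, an RF engine with explicit per-tree in-bag/OOB bookkeeping and
in-bag class under-sampling, the Intervention in Prediction Measure (IPM)
baseline, weighted multiclass AUROC with nested cross-validation for
parameter selection, and a synthetic generator of GO-like datasets with
planted predictive feature values. Classes follow the motivating gene
expression-with-age study: **O** (over-expressed), **U** (under-expressed),
**N** (no change), with priors 2.4% / 0.8% / 96.8%.

## Worked example

The fixture forest encodes three rules that test `GO:0006887` positively
and predict class N, with stored OOB class distributions (N:35, U:1),
(N:145, O:2, U:3), (N:7, U:3):

```r
library(compactfv)
model  <- worked_example_forest()
scores <- compact_fv(model)
subset(scores, feature_id == "GO:0006887")
#>   feature_id class cov hits      prec
#> 1 GO:0006887     O   0    0        NA
#> 2 GO:0006887     U   0    0        NA
#> 3 GO:0006887     N 196  187 0.9540816
```

The positive value of `GO:0006887` covers 36 + 150 + 10 = 196 OOB instances,
187 of which are correctly classified, giving a rule-based precision of
0.9541. Ranking features for class N orders by precision, then coverage:

```r
rank_for_class(scores, "N")
#>   rank feature_id class cov hits      prec
#> 1    1 GO:0043005     N  36   35 0.9722222
#> 2    2 GO:0043230     N 186  180 0.9677419
#> 3    3 GO:0006887     N 196  187 0.9540816
```

A full synthetic run — generate a GO-like ontology and a 2,000-gene dataset
with three planted features per minority class, prepare it, train an
under-sampled forest and rank features for the over-expressed class:

```r
dag <- generate_ontology(n_terms = 300, dag_depth = 6, seed = 1)
sim <- generate_dataset(planted_spec(), dag, seed = 1)
ds  <- filter_min_support(add_total_feature(sim$dataset), 10)
fit <- train_forest(ds, ntree = 500, mtry = 4, undersample = TRUE, seed = 1)
rank_for_class(compact_fv(fit, ds), "O", top_k = 5)
#>   rank feature_id class  cov hits      prec
#> 1    1 GO:0000148     O 1544  608 0.3937824
#> 2    2 GO:0000149     O 1843  671 0.3640803
#> 3    3 GO:0000147     O 1836  663 0.3611111
#> 4    4 GO:0000103     O 2109  357 0.1692745
#> 5    5 GO:0000006     O  111   18 0.1621622
sim$truth$planted$O
#> [1] "GO:0000147" "GO:0000148" "GO:0000149"
```

The three planted features head the ranking with precision around 0.36–0.39
— far above the 2.4% class prior — followed by a clear drop to background
features; `GO:0000103` is an ancestor of the planted terms and inherits a
diluted version of their signal through annotation closure.

`ipm(fit, ds)` computes the IPM baseline on the same model; on annotation
data it characteristically ranks the numeric total-annotation feature and
broad, near-root terms first for every class.

## Command line

`inst/cli/compactfv.R` wraps the package for shell use:

```sh
Rscript inst/cli/compactfv.R simulate --genes 2000 --terms 300 --seed 1 --out-prefix sim
Rscript inst/cli/compactfv.R train    --data sim_dataset.tsv --ntree 500 --mtry 4 \
                                      --undersample --seed 1 --out model.json
Rscript inst/cli/compactfv.R rank     --measure compactfv --class O --model model.json \
                                      --data sim_dataset.tsv --obo sim_ontology.obo --out ranking.tsv
Rscript inst/cli/compactfv.R evaluate --data sim_dataset.tsv --runs 1 --outer-folds 2 \
                                      --inner-folds 2 --undersample --seed 1 --report report.json
```

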