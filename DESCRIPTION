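Package: compactfv
Title: Positive Feature-Value Importance for Random Forests on Gene
    Ontology Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains Random Forest classifiers on sparse binary Gene
    Ontology (GO) annotation features with explicit per-tree in-bag and
    out-of-bag bookkeeping, optional in-bag class under-sampling for
    heavily imbalanced gene classes, and deterministic seeding.  Implements
    the COMPACT+FV rule-based importance measure, which scores the positive
    value of each binary feature by the out-of-bag precision of all
    root-to-leaf rules that test the feature positively, as well as the
    Intervention in Prediction Measure (IPM) baseline.  Includes an OBO
    (is-a subset) ontology reader, annotation-matrix construction with
    ancestor closure and minimum-support filtering, weighted multiclass
    AUROC with a nested cross-validation protocol for parameter selection,
    and a synthetic-data generator that plants predictive positive feature
    values in GO-like datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
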