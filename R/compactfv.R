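# COMPACT+FV: rule-based importance of positive feature values.
#
# Every root-to-leaf path in a tree is an IF-THEN rule.  For a binary
# feature f and class c, Cov_{f+c} sums the OOB coverage of all rules that
# test f positively and predict c, Hits_{f+c} sums the OOB instances among
# those whose true class is c, and Prec_{f+c} = Hits/Cov is the importance
# score.  Only positive values are credited: a GO annotation's absence is
# lack of evidence and carries no interpretable signal.

# Positive binary features on the path from root to `leaf` (unique feature
# indices; a rule contributes once per feature, not per occurrence).
path_positive_features <- function(tree, leaf, kind) {
  feats <- integer(0)
  v <- leaf
  while (!is.na(tree$parent[v])) {
    p <- tree$parent[v]
    if (tree$side[v] == 1L) {
      f <- tree$feature[p]
      if (kind[f] == "binary") feats <- c(feats, f)
    }
    v <- p
  }
  unique(feats)
}

# Full ordered condition list for the path to `leaf`.
path_conditions <- function(tree, leaf, feature_ids, kind) {
  feat <- integer(0); sides <- integer(0); thr <- numeric(0)
  v <- leaf
  while (!is.na(tree$parent[v])) {
    p <- tree$parent[v]
    feat <- c(tree$feature[p], feat)
    sides <- c(tree$side[v], sides)
    thr <- c(tree$threshold[p], thr)
    v <- p
  }
  if (length(feat) == 0) {
    return(data.frame(feature_id = character(0), kind = character(0),
                      polarity = character(0), threshold = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    feature_id = unname(feature_ids[feat]),
    kind = unname(kind[feat]),
    polarity = ifelse(kind[feat] == "binary",
                      ifelse(sides == 1L, "positive", "negative"),
                      ifelse(sides == 1L, "gt", "le")),
    threshold = ifelse(kind[feat] == "numeric", thr, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Per-leaf OOB class counts for one tree
#'
#' Routes the tree's OOB instances from the root down and tallies their true
#' classes per leaf.  Counts over all leaves sum to the OOB set size.
#'
#' @param model An `rf_model`.
#' @param ds The [annotation_dataset()] the model was trained on.
#' @param tree Tree index (default 1).
#'
#' @return Matrix (nodes x classes); internal-node rows are zero.
#' @export
oob_leaf_statistics <- function(model, ds, tree = 1) {
  tr <- model$trees[[tree]]
  tree_oob_counts(tr, align_newdata(model, ds), as.integer(ds$labels),
                  length(model$classes), model$classes)
}

tree_oob_counts <- function(tr, X, y, nclass, class_names) {
  counts <- matrix(0L, nrow = length(tr$is_leaf), ncol = nclass,
                   dimnames = list(NULL, class_names))
  if (length(tr$oob) > 0) {
    leaf <- route_instances(tr, X[tr$oob, , drop = FALSE])
    tab <- table(factor(leaf, levels = seq_len(length(tr$is_leaf))),
                 factor(y[tr$oob], levels = seq_len(nclass)))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Enumerate the IF-THEN rules of one tree
#'
#' One rule per leaf, with conditions in root-to-leaf order.  When the model
#' carries stored OOB leaf statistics (fixture forests) or `ds` is supplied,
#' each rule also reports its OOB class counts.
#'
#' @param model An `rf_model`.
#' @param tree Tree index (default 1).
#' @param ds Optional [annotation_dataset()] used to compute OOB counts.
#'
#' @return List of rules; each has `conditions` (data.frame with columns
#'   `feature_id`, `kind`, `polarity`, `threshold`), `predicted_class`,
#'   `leaf` and (when available) `oob_class_counts`.
#' @export
enumerate_rules <- function(model, tree = 1, ds = NULL) {
  tr <- model$trees[[tree]]
  kind <- model$feature_kind
  oobc <- tr$oob_counts
  if (is.null(oobc) && !is.null(ds)) {
    oobc <- oob_leaf_statistics(model, ds, tree)
  }
  leaves <- which(tr$is_leaf)
  lapply(leaves, function(lf) {
    r <- list(conditions = path_conditions(tr, lf, model$feature_ids, kind),
              predicted_class = model$classes[tr$pred[lf]],
              leaf = lf)
    if (!is.null(oobc)) {
      r$oob_class_counts <- stats::setNames(as.numeric(oobc[lf, ]),
                                            model$classes)
    }
    r
  })
}

#' Rules of a tree containing the positive value of a feature
#'
#' @inheritParams enumerate_rules
#' @param feature Binary feature id.
#' @return Subset of [enumerate_rules()] whose condition list tests
#'   `feature` positively.
#' @export
rules_with_positive_value <- function(model, feature, tree = 1, ds = NULL) {
  fi <- match(feature, model$feature_ids)
  if (is.na(fi)) stop("unknown feature: ", feature)
  if (model$feature_kind[fi] != "binary") {
    stop("feature '", feature,
         "' is numeric; positive value undefined for non-binary features")
  }
  rules <- enumerate_rules(model, tree, ds)
  Filter(function(r) {
    any(r$conditions$feature_id == feature & r$conditions$polarity == "positive")
  }, rules)
}

#' COMPACT+FV rule-based importance scores
#'
#' For every binary feature f and class c, accumulates over all trees and
#' all rules that test f positively and predict c: the rules' OOB coverage
#' (`cov`), the covered OOB instances whose true class is c (`hits`), and
#' their ratio (`prec`, `NA` when `cov` is 0).  The numeric `"total"`
#' feature participates in trees but is not scored (it has no positive
#' value).
#'
#' @param model An `rf_model`.
#' @param ds The training [annotation_dataset()]; may be `NULL` when every
#'   tree stores precomputed OOB leaf statistics (fixture forests).
#'
#' @return Data.frame of class `compactfv_scores` with columns
#'   `feature_id`, `class`, `cov`, `hits`, `prec`.
#' @export
compact_fv <- function(model, ds = NULL) {
  nclass <- length(model$classes)
  J <- length(model$feature_ids)
  binary <- which(model$feature_kind == "binary")
  Cov <- matrix(0, J, nclass)
  Hits <- matrix(0, J, nclass)
  X <- NULL
  y <- NULL
  if (!is.null(ds)) {
    X <- align_newdata(model, ds)
    y <- as.integer(ds$labels)
  }
  for (tr in model$trees) {
    oobc <- tr$oob_counts
    if (is.null(oobc)) {
      if (is.null(ds)) {
        stop("tree lacks stored OOB statistics; supply the training dataset")
      }
      oobc <- tree_oob_counts(tr, X, y, nclass, model$classes)
    }
    for (lf in which(tr$is_leaf)) {
      cov <- sum(oobc[lf, ])
      cls <- tr$pred[lf]
      feats <- path_positive_features(tr, lf, model$feature_kind)
      if (length(feats) == 0) next
      Cov[feats, cls] <- Cov[feats, cls] + cov
      Hits[feats, cls] <- Hits[feats, cls] + oobc[lf, cls]
    }
  }
  out <- data.frame(
    feature_id = rep(model$feature_ids[binary], each = nclass),
    class = rep(model$classes, times = length(binary)),
    cov = as.vector(t(Cov[binary, , drop = FALSE])),
    hits = as.vector(t(Hits[binary, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
  out$prec <- ifelse(out$cov > 0, out$hits / out$cov, NA_real_)
  class(out) <- c("compactfv_scores", "data.frame")
  out
}

#' COMPACT+FV scores averaged over repeated model builds
#'
#' Rebuilds the forest `repeats` times with seeds derived from `seed`,
#' computes [compact_fv()] for each build, and averages `cov`, `hits` and
#' `prec` per (feature, class) over the builds in which the score is
#' defined.  With `repeats = 1` this reduces to a single [compact_fv()]
#' call.
#'
#' @param ds Training [annotation_dataset()].
#' @param repeats Number of independent model builds.
#' @param seed Base seed.
#' @inheritParams train_forest
#' @return A `compactfv_scores` data.frame with an extra `n_defined` column
#'   (number of builds contributing to `prec`).
#' @export
compact_fv_repeats <- function(ds, ntree, mtry, repeats = 1,
                               undersample = FALSE, min_node_size = 2,
                               seed = 1) {
  stopifnot(repeats >= 1)
  acc <- NULL
  for (r in seq_len(repeats)) {
    model <- train_forest(ds, ntree = ntree, mtry = mtry,
                          undersample = undersample,
                          min_node_size = min_node_size,
                          seed = derive_seed(seed, 7919, r))
    sc <- compact_fv(model, ds)
    if (is.null(acc)) {
      acc <- sc
      acc$prec_sum <- ifelse(is.na(sc$prec), 0, sc$prec)
      acc$n_defined <- as.integer(!is.na(sc$prec))
    } else {
      acc$cov <- acc$cov + sc$cov
      acc$hits <- acc$hits + sc$hits
      acc$prec_sum <- acc$prec_sum + ifelse(is.na(sc$prec), 0, sc$prec)
      acc$n_defined <- acc$n_defined + as.integer(!is.na(sc$prec))
    }
  }
  acc$cov <- acc$cov / repeats
  acc$hits <- acc$hits / repeats
  acc$prec <- ifelse(acc$n_defined > 0, acc$prec_sum / acc$n_defined, NA_real_)
  acc$prec_sum <- NULL
  class(acc) <- c("compactfv_scores", "data.frame")
  acc
}

#' Rank features for one class
#'
#' Orders the features with a defined score for `class_id` by precision
#' descending, breaking ties by OOB coverage descending (the convention used
#' when many features reach precision 1.0), then by feature id ascending.
#'
#' @param scores A `compactfv_scores` data.frame (or any data.frame with
#'   `feature_id`, `class`, `prec`, `cov` columns; an `ipm_scores` table
#'   ranks by its `score` column instead).
#' @param class_id One of `"O"`, `"U"`, `"N"`.
#' @param top_k Truncate to this many rows (default all).
#'
#' @return Data.frame with a leading `rank` column.
#' @export
rank_for_class <- function(scores, class_id, top_k = Inf) {
  if (!class_id %in% scores$class) {
    stop("no scores for class '", class_id, "'")
  }
  s <- scores[scores$class == class_id, , drop = FALSE]
  if ("prec" %in% names(s)) {
    s <- s[!is.na(s$prec), , drop = FALSE]
    s <- s[order(-s$prec, -s$cov, s$feature_id), , drop = FALSE]
  } else if ("score" %in% names(s)) {
    s <- s[!is.na(s$score), , drop = FALSE]
    s <- s[order(-s$score, s$feature_id), , drop = FALSE]
  } else {
    stop("scores table has neither a 'prec' nor a 'score' column")
  }
  if (nrow(s) > top_k) s <- s[seq_len(top_k), , drop = FALSE]
  if (nrow(s) > 0) s <- cbind(rank = seq_len(nrow(s)), s)
  else s <- cbind(rank = integer(0), s)
  rownames(s) <- NULL
  s
}

#' Write a ranking table as TSV
#'
#' Columns: `rank`, `feature_id`, `feature_name` (looked up in the
#' ontology's term names when supplied), `class`, then the score columns of
#' the ranking (`prec`, `cov`, `hits` or `score`).
#'
#' @param ranking Output of [rank_for_class()].
#' @param path Output path.
#' @param dag Optional [ontology_dag()] supplying feature names.
#' @export
write_ranking_tsv <- function(ranking, path, dag = NULL) {
  nm <- if (!is.null(dag)) {
    unname(dag$term_names[ranking$feature_id])
  } else {
    rep(NA_character_, nrow(ranking))
  }
  out <- cbind(ranking[, c("rank", "feature_id")],
               feature_name = ifelse(is.na(nm), "", nm),
               ranking[, setdiff(names(ranking), c("rank", "feature_id")),
                       drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
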