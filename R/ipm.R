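# Intervention in Prediction Measure (IPM) baseline.
#
# For each tree and each of its OOB instances, count how often each feature
# is tested on the instance's root-to-leaf path, normalize the count vector
# to sum to 1, and average the normalized vectors over all (tree, instance)
# OOB pairs — by default grouped by the instance's true class.  Unlike
# COMPACT+FV, IPM scores a feature as a whole (both values), and the
# numeric "total" feature is included.

#' Feature-usage counts on one instance's classification path
#'
#' @param model An `rf_model`.
#' @param instance Named numeric vector (or 1-row matrix / 1-instance
#'   dataset) of feature values.
#' @param tree Tree index (default 1).
#'
#' @return Named integer vector over the model's features: the number of
#'   internal nodes on the instance's root-to-leaf path splitting on each
#'   feature.  Its sum is the path depth.
#' @export
path_usage <- function(model, instance, tree = 1) {
  if (is.null(dim(instance))) instance <- t(as.matrix(instance))
  X <- align_newdata(model, instance)
  tr <- model$trees[[tree]]
  counts <- integer(length(model$feature_ids))
  names(counts) <- model$feature_ids
  v <- 1L
  while (!tr$is_leaf[v]) {
    f <- tr$feature[v]
    counts[f] <- counts[f] + 1L
    v <- if (X[1, f] <= tr$threshold[v]) tr$left[v] else tr$right[v]
  }
  counts
}

# Per-leaf feature-usage count vectors (with multiplicity) for one tree,
# as a list indexed by node id; NULL for internal nodes.
leaf_usage_vectors <- function(tr, J) {
  usage <- vector("list", length(tr$is_leaf))
  walk <- function(v, feats) {
    if (tr$is_leaf[v]) {
      u <- tabulate(feats, nbins = J)
      usage[[v]] <<- u
      return()
    }
    feats2 <- c(feats, tr$feature[v])
    walk(tr$left[v], feats2)
    walk(tr$right[v], feats2)
  }
  walk(1L, integer(0))
  usage
}

#' Intervention in Prediction Measure scores
#'
#' @param model An `rf_model`.
#' @param ds The training [annotation_dataset()].
#' @param group_by When `"true"` (default), normalized usage vectors are
#'   averaged separately over OOB instances of each true class; `"predicted"`
#'   groups by the leaf's predicted class instead; `"none"` averages over
#'   all OOB pairs into a single ranking (reported under class `"all"`).
#' @param averaging `"flat"` (default): one mean over all (tree, instance)
#'   OOB pairs; `"per_tree"`: average within each tree first, then across
#'   trees.  Pairs routed through single-leaf trees (zero-length paths)
#'   carry no usage information and are skipped.
#'
#' @return Data.frame of class `ipm_scores` with columns `feature_id`,
#'   `class`, `score`.  Scores for each class sum to 1 when at least one
#'   OOB pair exists for it; otherwise they are `NA` with a warning.
#' @export
ipm <- function(model, ds, group_by = c("true", "predicted", "none"),
                averaging = c("flat", "per_tree")) {
  group_by <- match.arg(group_by)
  averaging <- match.arg(averaging)
  X <- align_newdata(model, ds)
  y <- as.integer(ds$labels)
  J <- length(model$feature_ids)
  groups <- if (group_by == "none") "all" else model$classes
  G <- length(groups)
  sums <- matrix(0, J, G, dimnames = list(model$feature_ids, groups))
  npairs <- numeric(G)
  tree_means <- if (averaging == "per_tree") {
    list(sums = sums, n = numeric(G))
  } else {
    NULL
  }
  for (tr in model$trees) {
    if (length(tr$oob) == 0) next
    usage <- leaf_usage_vectors(tr, J)
    leaf <- route_instances(tr, X[tr$oob, , drop = FALSE])
    grp <- switch(group_by,
                  true = y[tr$oob],
                  predicted = tr$pred[leaf],
                  none = rep(1L, length(tr$oob)))
    leaf_ids <- which(tr$is_leaf)
    depths <- vapply(usage[leaf_ids], sum, 0)
    if (all(depths == 0)) next  # single-leaf tree: no usage information
    tab <- table(factor(leaf, levels = leaf_ids),
                 factor(grp, levels = seq_len(G)))
    Un <- vapply(seq_along(leaf_ids),
                 function(k) if (depths[k] > 0) usage[[leaf_ids[k]]] / depths[k]
                             else numeric(J),
                 numeric(J))
    keep <- depths > 0
    t_sums <- Un[, keep, drop = FALSE] %*% tab[keep, , drop = FALSE]
    t_n <- colSums(tab[keep, , drop = FALSE])
    if (averaging == "flat") {
      sums <- sums + t_sums
      npairs <- npairs + t_n
    } else {
      has <- t_n > 0
      tree_means$sums[, has] <- tree_means$sums[, has] +
        sweep(t_sums[, has, drop = FALSE], 2, t_n[has], "/")
      tree_means$n[has] <- tree_means$n[has] + 1
    }
  }
  if (averaging == "per_tree") {
    sums <- tree_means$sums
    npairs <- tree_means$n
  }
  empty <- npairs == 0
  if (any(empty)) {
    warning("no OOB pair for group(s): ", paste(groups[empty], collapse = ", "),
            "; scores undefined")
  }
  score <- sweep(sums, 2, ifelse(empty, NA_real_, npairs), "/")
  out <- data.frame(
    feature_id = rep(model$feature_ids, times = G),
    class = rep(groups, each = J),
    score = as.vector(score),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ipm_scores", "data.frame")
  out
}
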