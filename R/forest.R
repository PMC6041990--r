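# Random Forest engine with explicit in-bag / out-of-bag bookkeeping.
#
# The forest is grown from scratch rather than delegated to an off-the-shelf
# implementation because downstream rule statistics need guarantees those
# implementations do not give: per-tree in-bag multisets and OOB sets,
# under-sampling applied inside the bootstrap, deterministic tie-breaking at
# splits and leaves, and leaf-level in-bag class counts.  Trees are stored as
# flat parallel arrays so that routing, rule extraction and serialization are
# simple and fast.

#' Gini impurity of a class count vector
#'
#' @param class_counts Non-negative counts, at least one positive.
#' @return `1 - sum(p^2)`, in `[0, 1)`.
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("negative class count")
  total <- sum(class_counts)
  if (total == 0) stop("gini_impurity undefined for all-zero counts")
  p <- class_counts / total
  1 - sum(p * p)
}

#' Draw one bootstrap sample
#'
#' Samples `n` instance indices with replacement (the in-bag multiset); the
#' out-of-bag set is the complement of the drawn support.  Uses the current
#' RNG state.
#'
#' @param n Number of instances.
#' @return List with `in_bag` (integer vector of length `n`, with
#'   repetitions) and `oob` (sorted integer vector).
#' @export
draw_bootstrap <- function(n) {
  stopifnot(n >= 1)
  in_bag <- sample.int(n, n, replace = TRUE)
  list(in_bag = in_bag, oob = setdiff(seq_len(n), in_bag))
}

#' Under-sample an in-bag multiset to the minority class count
#'
#' Randomly deletes occurrences of the over-represented classes until every
#' class present in the multiset matches the smallest class count, the
#' standard in-bag balancing device for heavily skewed gene classes.
#' Deleted occurrences are *not* added to the OOB set.
#'
#' @param in_bag Integer vector of instance indices (with repetitions).
#' @param labels Factor of class labels for the full dataset.
#' @return The balanced in-bag multiset (sorted).
#' @export
undersample_to_minority <- function(in_bag, labels) {
  lab <- labels[in_bag]
  counts <- table(lab)
  present <- counts[counts > 0]
  absent <- names(counts)[counts == 0]
  if (length(absent) > 0) {
    warning("class(es) absent from in-bag sample: ",
            paste(absent, collapse = ", "), "; balancing over present classes")
  }
  m <- min(present)
  keep <- integer(0)
  for (cl in names(present)) {
    pos <- which(as.character(lab) == cl)
    if (length(pos) > m) pos <- sample(pos, m)
    keep <- c(keep, pos)
  }
  sort(in_bag[sort(keep)])
}

# Best (feature, threshold) for one node by weighted child Gini impurity.
# x: numeric matrix restricted to the node's rows; y: integer class codes;
# candidates: column indices to consider; kind: per-column "binary"/"numeric".
# Ties go to the lowest feature index, then the lowest threshold (candidates
# are scanned in increasing order and only strict improvements are kept).
best_split_idx <- function(x, y, candidates, kind, nclass) {
  n <- length(y)
  best <- NULL
  best_imp <- Inf
  eps <- 1e-12
  for (f in sort(candidates)) {
    v <- x[, f]
    if (kind[f] == "binary") {
      thrs <- 0.5
      if (all(v == v[1])) next
    } else {
      uv <- sort(unique(v))
      if (length(uv) < 2) next
      thrs <- (uv[-length(uv)] + uv[-1]) / 2
    }
    for (thr in thrs) {
      left <- v <= thr
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      cl <- tabulate(y[left], nbins = nclass)
      cr <- tabulate(y[!left], nbins = nclass)
      imp <- (nl * gini_impurity(cl) + (n - nl) * gini_impurity(cr)) / n
      if (imp < best_imp - eps) {
        best_imp <- imp
        best <- list(feature = f, threshold = thr, impurity = imp)
      }
    }
  }
  best
}

#' Best split for a node
#'
#' Exhaustively evaluates the candidate features on the given rows and
#' returns the split minimizing weighted child Gini impurity, or `NULL` when
#' no candidate separates the rows.  Binary features split as 0 vs 1
#' (encoded as threshold 0.5); numeric features try midpoints between
#' consecutive distinct observed values.  Equal-impurity ties resolve to the
#' lowest feature index, then the lowest threshold.
#'
#' @param x Numeric feature matrix for the node's rows.
#' @param y Class labels (factor) for the same rows.
#' @param candidates Column indices of the candidate features.
#' @param kind Optional character vector (`"binary"`/`"numeric"`) per column
#'   of `x`; by default columns whose observed values lie in `{0, 1}` are
#'   treated as binary.
#'
#' @return `NULL`, or a list with `feature`, `threshold` and `impurity`
#'   (the weighted child Gini).
#' @export
best_split <- function(x, y, candidates, kind = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two rows to split")
  if (length(candidates) == 0) stop("empty candidate set")
  if (is.null(kind)) {
    kind <- ifelse(apply(x, 2, function(v) all(v %in% c(0, 1))),
                   "binary", "numeric")
  }
  y <- if (is.factor(y)) as.integer(y) else as.integer(as_class_factor(y))
  best_split_idx(x, y, candidates, kind, max(y))
}

# Grow one tree on an in-bag multiset.  Returns flat parallel arrays.
grow_tree <- function(X, y, rows, mtry, min_node_size, kind, nclass) {
  J <- ncol(X)
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0)
  parent <- integer(0); side <- integer(0)
  is_leaf <- logical(0); pred <- integer(0)
  counts <- list()
  new_node <- function(par, sd) {
    id <- length(feature) + 1L
    feature[id] <<- NA_integer_; threshold[id] <<- NA_real_
    left[id] <<- NA_integer_; right[id] <<- NA_integer_
    parent[id] <<- par; side[id] <<- sd
    is_leaf[id] <<- TRUE; pred[id] <<- NA_integer_
    counts[[id]] <<- integer(nclass)
    id
  }
  build <- function(node_rows, par, sd) {
    id <- new_node(par, sd)
    cnt <- tabulate(y[node_rows], nbins = nclass)
    counts[[id]] <<- cnt
    make_leaf <- function() {
      # argmax with ties to the first class in the fixed (O, U, N) order
      pred[id] <<- which.max(cnt)
      id
    }
    if (sum(cnt > 0) <= 1 || length(node_rows) < min_node_size) {
      return(make_leaf())
    }
    cand <- sample.int(J, min(mtry, J))
    sp <- best_split_idx(X[node_rows, , drop = FALSE], y[node_rows],
                         cand, kind, nclass)
    if (is.null(sp) || sp$impurity >= gini_impurity(cnt) - 1e-12) {
      return(make_leaf())
    }
    is_leaf[id] <<- FALSE
    feature[id] <<- sp$feature
    threshold[id] <<- sp$threshold
    go_left <- X[node_rows, sp$feature] <= sp$threshold
    left[id] <<- build(node_rows[go_left], id, 0L)
    right[id] <<- build(node_rows[!go_left], id, 1L)
    id
  }
  build(rows, NA_integer_, NA_integer_)
  list(feature = feature, threshold = threshold, left = left, right = right,
       parent = parent, side = side, is_leaf = is_leaf, pred = pred,
       counts = do.call(rbind, counts))
}

#' Train a Random Forest with explicit in-bag/OOB bookkeeping
#'
#' Each tree draws its own bootstrap sample (recorded as an in-bag index
#' multiset plus the complementary OOB set), optionally balances the in-bag
#' multiset by under-sampling to the minority class count, and grows a CART
#' style tree on the (possibly balanced) multiset using Gini impurity and
#' `mtry` candidate features resampled at every node.  All randomness is
#' driven by one stream per tree derived from `seed + tree index`, so the
#' first `k` trees are identical regardless of `ntree`.
#'
#' @param ds An [annotation_dataset()] (its binary features plus the
#'   `"total"` feature when present form the design matrix).
#' @param ntree Number of trees.
#' @param mtry Number of candidate features sampled at each node.
#' @param undersample Balance each in-bag multiset to the minority class
#'   count before growing (default `FALSE`).  Instances deleted by
#'   under-sampling do not join the OOB set.
#' @param min_node_size Minimum number of in-bag instances a node must hold
#'   to be considered for splitting (default 2, i.e. grow to purity).
#' @param seed Integer seed; fully determines the model.
#'
#' @return An object of class `rf_model`.
#' @export
train_forest <- function(ds, ntree, mtry, undersample = FALSE,
                         min_node_size = 2, seed = 1) {
  stopifnot(inherits(ds, "annotation_dataset"), ntree >= 1)
  X <- design_matrix(ds)
  kind <- unname(feature_kinds(ds))
  J <- ncol(X)
  if (mtry > J) stop("mtry (", mtry, ") exceeds feature count (", J, ")")
  y <- as.integer(ds$labels)
  nclass <- length(CLASS_ORDER)
  n <- nrow(X)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    tree_seed <- derive_seed(seed, t)
    trees[[t]] <- with_seed(tree_seed, {
      bs <- draw_bootstrap(n)
      rows <- bs$in_bag
      if (undersample) rows <- undersample_to_minority(rows, ds$labels)
      tr <- grow_tree(X, y, rows, mtry, min_node_size, kind, nclass)
      tr$in_bag <- bs$in_bag
      tr$train_rows <- rows  # post-undersampling training multiset
      tr$oob <- bs$oob
      tr
    })
  }
  structure(
    list(trees = trees,
         config = list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                       undersample = undersample,
                       min_node_size = as.integer(min_node_size),
                       seed = as.integer(seed)),
         classes = CLASS_ORDER,
         feature_ids = colnames(X),
         feature_kind = stats::setNames(kind, colnames(X))),
    class = "rf_model"
  )
}

#' @export
print.rf_model <- function(x, ...) {
  leaves <- vapply(x$trees, function(t) sum(t$is_leaf), 1L)
  cat(sprintf(
    "rf_model: %d trees (mtry %d, %s under-sampling), %d features, mean %.1f leaves/tree\n",
    x$config$ntree, x$config$mtry,
    if (isTRUE(x$config$undersample)) "with" else "without",
    length(x$feature_ids), mean(leaves)))
  invisible(x)
}

# Route every row of X to a leaf of `tree`; returns leaf node ids.
route_instances <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  repeat {
    active <- which(!tree$is_leaf[node])
    if (length(active) == 0) break
    nd <- node[active]
    v <- X[cbind(active, tree$feature[nd])]
    node[active] <- ifelse(v <= tree$threshold[nd],
                           tree$left[nd], tree$right[nd])
  }
  node
}

# Design matrix for prediction, with columns aligned to the model.
align_newdata <- function(model, newdata) {
  X <- if (inherits(newdata, "annotation_dataset")) {
    design_matrix(newdata)
  } else {
    m <- as.matrix(newdata)
    storage.mode(m) <- "double"
    m
  }
  missing <- setdiff(model$feature_ids, colnames(X))
  if (length(missing) > 0) {
    stop("newdata is missing model feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  X[, model$feature_ids, drop = FALSE]
}

#' Predict with a trained forest
#'
#' Each tree routes the instance to a leaf and votes for that leaf's
#' predicted class; the class probability vector is the vote fraction.
#'
#' @param object An `rf_model`.
#' @param newdata An [annotation_dataset()] or numeric matrix whose columns
#'   cover the model's features.
#' @param type `"prob"` (default; n x 3 matrix of vote fractions over
#'   classes O, U, N) or `"class"` (factor of majority votes, ties to the
#'   earlier class in that order).
#' @param ... Unused.
#' @export
predict.rf_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- align_newdata(object, newdata)
  n <- nrow(X)
  nclass <- length(object$classes)
  votes <- matrix(0, n, nclass, dimnames = list(rownames(X), object$classes))
  for (tree in object$trees) {
    leaf <- route_instances(tree, X)
    p <- tree$pred[leaf]
    votes[cbind(seq_len(n), p)] <- votes[cbind(seq_len(n), p)] + 1
  }
  prob <- votes / length(object$trees)
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}
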