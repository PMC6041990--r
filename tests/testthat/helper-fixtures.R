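# Fixtures and independent oracles used across the test files.
# Oracles deliberately re-derive quantities by brute force (per-instance
# path walking, pair enumeration) so they share no code with the package
# internals they check.

# A small random annotation-style dataset: binary features plus an optional
# numeric total column, labels guaranteed to contain all three classes.
random_small_dataset <- function(n = 30, J = 8, seed = 1, with_total = TRUE) {
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(s); code
  }
  withr_seed(seed, {
    m <- matrix(rbinom(n * J, 1, 0.35), n, J,
                dimnames = list(sprintf("g%03d", seq_len(n)),
                                sprintf("GO:%07d", seq_len(J))))
    lab <- sample(c("O", "U", "N"), n, replace = TRUE,
                  prob = c(0.25, 0.25, 0.5))
    # force all classes present
    lab[1:3] <- c("O", "U", "N")
    ds <- annotation_dataset(m, lab)
    if (with_total) ds <- add_total_feature(ds)
    ds
  })
}

# Walk one instance down a tree node-by-node; returns list(leaf, pos_binary
# features tested positively, usage counts per feature).  Independent of
# route_instances().
walk_instance <- function(tree, xrow, feature_kind) {
  v <- 1L
  pos <- integer(0)
  usage <- integer(length(feature_kind))
  while (!tree$is_leaf[v]) {
    f <- tree$feature[v]
    usage[f] <- usage[f] + 1L
    if (xrow[f] <= tree$threshold[v]) {
      v <- tree$left[v]
    } else {
      if (feature_kind[f] == "binary") pos <- c(pos, f)
      v <- tree$right[v]
    }
  }
  list(leaf = v, pos = unique(pos), usage = usage)
}

# Brute-force COMPACT+FV oracle: for every tree and every OOB instance,
# walk the path and credit each positively tested binary feature once with
# the leaf's predicted class; a hit when the true class matches.
oracle_compact_fv <- function(model, ds) {
  X <- cbind(ds$x, if (!is.null(ds$total)) matrix(ds$total, ncol = 1,
                                                  dimnames = list(NULL, "total")))
  storage.mode(X) <- "double"
  X <- X[, model$feature_ids, drop = FALSE]
  y <- as.integer(factor(as.character(ds$labels), levels = model$classes))
  J <- length(model$feature_ids)
  Cov <- matrix(0, J, 3)
  Hits <- matrix(0, J, 3)
  for (tr in model$trees) {
    for (i in tr$oob) {
      w <- walk_instance(tr, X[i, ], model$feature_kind)
      cls <- tr$pred[w$leaf]
      for (f in w$pos) {
        Cov[f, cls] <- Cov[f, cls] + 1
        if (y[i] == cls) Hits[f, cls] <- Hits[f, cls] + 1
      }
    }
  }
  binary <- which(model$feature_kind == "binary")
  out <- data.frame(
    feature_id = rep(model$feature_ids[binary], each = 3),
    class = rep(model$classes, times = length(binary)),
    cov = as.vector(t(Cov[binary, , drop = FALSE])),
    hits = as.vector(t(Hits[binary, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
  out$prec <- ifelse(out$cov > 0, out$hits / out$cov, NA_real_)
  out
}

# Brute-force IPM oracle (flat mean over (tree, OOB instance) pairs,
# grouped by true class).
oracle_ipm <- function(model, ds) {
  X <- cbind(ds$x, if (!is.null(ds$total)) matrix(ds$total, ncol = 1,
                                                  dimnames = list(NULL, "total")))
  storage.mode(X) <- "double"
  X <- X[, model$feature_ids, drop = FALSE]
  y <- as.character(ds$labels)
  J <- length(model$feature_ids)
  sums <- matrix(0, J, 3, dimnames = list(model$feature_ids, model$classes))
  npairs <- setNames(numeric(3), model$classes)
  for (tr in model$trees) {
    for (i in tr$oob) {
      w <- walk_instance(tr, X[i, ], model$feature_kind)
      s <- sum(w$usage)
      if (s == 0) next
      cl <- y[i]
      sums[, cl] <- sums[, cl] + w$usage / s
      npairs[cl] <- npairs[cl] + 1
    }
  }
  sweep(sums, 2, ifelse(npairs == 0, NA, npairs), "/")
}

# Pairwise AUROC oracle: enumerate all (positive, negative) pairs.
oracle_auroc <- function(scores, positives) {
  pos <- scores[as.logical(positives)]
  neg <- scores[!as.logical(positives)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
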