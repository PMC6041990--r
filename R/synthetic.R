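# Synthetic GO-like data: a layered is-a DAG, annotation datasets with
# planted predictive positive feature values under realistic class
# imbalance, and the fixed worked-example forest used as an exact
# regression fixture for the rule-based importance arithmetic.

#' Generate a layered GO-like ontology
#'
#' Terms are arranged in `dag_depth` layers under a single root; every
#' non-root term draws one parent from the previous layer (plus, with
#' probability 0.3, a second parent from any shallower layer), so the graph
#' is acyclic by construction.  Layer sizes double with depth, mimicking the
#' fan-out of real ontologies.
#'
#' @param n_terms Number of terms (>= `dag_depth`).
#' @param dag_depth Number of layers (>= 1).
#' @param seed Integer seed.
#'
#' @return An [ontology_dag()]; each term's layer is recorded in the
#'   `"layers"` attribute.
#' @export
generate_ontology <- function(n_terms, dag_depth = 6, seed = 1) {
  stopifnot(n_terms >= dag_depth, dag_depth >= 1)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  layer <- integer(n_terms)
  layer[1] <- 1L
  if (n_terms > 1 && dag_depth == 1) stop("dag_depth 1 allows a single term")
  if (n_terms > 1) {
    w <- 2^(seq_len(dag_depth - 1) - 1)
    sizes <- pmax(1L, round((n_terms - 1) * w / sum(w)))
    while (sum(sizes) > n_terms - 1) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    while (sum(sizes) < n_terms - 1) sizes[which.max(sizes)] <- sizes[which.max(sizes)] + 1L
    layer[-1] <- rep(seq_len(dag_depth - 1) + 1L, times = sizes)
  }
  edges <- with_seed(seed, {
    ec <- character(0); ep <- character(0)
    for (i in which(layer > 1)) {
      prev <- which(layer == layer[i] - 1L)
      p1 <- if (length(prev) == 1) prev else sample(prev, 1)
      ps <- p1
      if (stats::runif(1) < 0.3) {
        shallower <- which(layer < layer[i])
        p2 <- if (length(shallower) == 1) shallower else sample(shallower, 1)
        ps <- unique(c(ps, p2))
      }
      ec <- c(ec, rep(terms[i], length(ps)))
      ep <- c(ep, terms[ps])
    }
    data.frame(child = ec, parent = ep, stringsAsFactors = FALSE)
  })
  dag <- ontology_dag(terms, if (nrow(edges) > 0) edges else NULL,
                      names = stats::setNames(
                        sprintf("synthetic term %d (layer %d)",
                                seq_len(n_terms), layer),
                        terms))
  attr(dag, "layers") <- stats::setNames(layer, terms)
  dag
}

#' Specification of a planted synthetic dataset
#'
#' Describes the study conditions the generator emulates: the extreme class
#' imbalance observed for brain ageing expression classes (priors 2.4% /
#' 0.8% / 96.8% for O / U / N), sparse background annotation, and a small
#' set of deep terms whose positive values deterministically imply a
#' minority class.
#'
#' @param n_genes Number of instances (default 2000, desk scale).
#' @param class_priors Named probabilities for O, U, N; must sum to 1.
#' @param planted_rules `NULL` (auto-plant `n_planted` leaf terms per
#'   minority class at generation time) or a list of
#'   `list(features, class, penetrance)` entries.
#' @param n_planted Features auto-planted per minority class (default 3).
#' @param penetrance Probability that a planted rule fires for an instance
#'   of its target class (default 1).
#' @param background_rate Independent per-(gene, term) annotation
#'   probability before closure (default 0.05).
#' @param min_class_count Minimum realized instances per minority class
#'   (default 20), so stratified cross-validation stays feasible at desk
#'   scale.
#'
#' @return List of class `planted_spec`.
#' @export
planted_spec <- function(n_genes = 2000,
                         class_priors = c(O = 0.024, U = 0.008, N = 0.968),
                         planted_rules = NULL,
                         n_planted = 3,
                         penetrance = 1,
                         background_rate = 0.05,
                         min_class_count = 20) {
  stopifnot(abs(sum(class_priors) - 1) < 1e-9,
            penetrance > 0, penetrance <= 1,
            background_rate >= 0, background_rate < 1)
  if (!all(CLASS_ORDER %in% names(class_priors))) {
    stop("class_priors must name O, U and N")
  }
  structure(list(n_genes = n_genes,
                 class_priors = class_priors[CLASS_ORDER],
                 planted_rules = planted_rules,
                 n_planted = n_planted,
                 penetrance = penetrance,
                 background_rate = background_rate,
                 min_class_count = min_class_count),
            class = "planted_spec")
}

#' Generate an annotation dataset with planted predictive feature values
#'
#' Classes are drawn from the prior; minority classes are topped up to
#' `min_class_count` by reassigning majority instances.  Planted rules set
#' their features positive (with the stated penetrance) for instances of
#' the target class; background annotations are drawn independently per
#' (gene, term); all annotations are then closed under is-a ancestry.
#'
#' @param spec A [planted_spec()].
#' @param dag An [ontology_dag()], e.g. from [generate_ontology()].
#' @param seed Integer seed; output is byte-reproducible.
#'
#' @return List with `dataset` (an [annotation_dataset()], all DAG terms as
#'   columns) and `truth` (list: `labels`, `planted` — per-class character
#'   vectors of truly predictive features).
#' @export
generate_dataset <- function(spec, dag, seed = 1) {
  stopifnot(inherits(spec, "planted_spec"), inherits(dag, "ontology_dag"))
  n <- spec$n_genes
  terms <- dag$terms
  Tn <- length(terms)
  rules <- spec$planted_rules
  if (!is.null(rules)) {
    for (r in rules) {
      missing <- setdiff(r$features, terms)
      if (length(missing) > 0) {
        stop("planted feature(s) not in DAG: ", paste(missing, collapse = ", "))
      }
    }
  }
  res <- with_seed(seed, {
    cls <- sample(CLASS_ORDER, n, replace = TRUE, prob = spec$class_priors)
    for (cl in c("O", "U")) {
      deficit <- spec$min_class_count - sum(cls == cl)
      if (deficit > 0) {
        pool <- which(cls == "N")
        cls[sample(pool, deficit)] <- cl
      }
    }
    if (is.null(rules)) {
      # auto-plant: deepest leaf terms (no children), disjoint across classes
      has_child <- terms %in% dag$edges$parent
      layers <- attr(dag, "layers") %||%
        stats::setNames(rep(1L, Tn), terms)
      leaves <- terms[!has_child]
      leaves <- leaves[order(-layers[leaves], leaves)]
      need <- 2 * spec$n_planted
      if (length(leaves) < need) stop("DAG has too few leaf terms to plant")
      picked <- leaves[seq_len(need)]
      rules <- list(
        list(features = picked[seq_len(spec$n_planted)],
             class = "O", penetrance = spec$penetrance),
        list(features = picked[spec$n_planted + seq_len(spec$n_planted)],
             class = "U", penetrance = spec$penetrance)
      )
    }
    B <- matrix(stats::rbinom(n * Tn, 1L, spec$background_rate),
                nrow = n, ncol = Tn)
    fidx <- stats::setNames(seq_len(Tn), terms)
    for (r in rules) {
      tgt <- which(cls == r$class)
      fire <- tgt[stats::runif(length(tgt)) <= r$penetrance]
      B[fire, fidx[r$features]] <- 1L
    }
    list(cls = cls, B = B, rules = rules)
  })
  # closure: reach[t, a] = 1 iff a is t or an ancestor of t
  anc <- ancestor_index_sets(dag)
  reach <- diag(1L, Tn)
  for (t in seq_len(Tn)) reach[t, anc[[t]]] <- 1L
  closed <- (res$B %*% reach) > 0
  m <- matrix(as.integer(closed), nrow = n,
              dimnames = list(sprintf("G%05d", seq_len(n)), terms))
  ord <- order(colnames(m))
  m <- m[, ord, drop = FALSE]
  ds <- annotation_dataset(m, res$cls)
  planted <- split(
    unlist(lapply(res$rules, function(r) r$features), use.names = FALSE),
    unlist(lapply(res$rules, function(r) rep(r$class, length(r$features))))
  )
  list(dataset = ds,
       truth = list(labels = ds$labels, planted = planted,
                    rules = res$rules))
}

#' The worked-example forest fixture
#'
#' A single fictitious tree containing exactly three rules that test
#' GO:0006887 positively and predict class N, with stored OOB class
#' distributions (N:35, U:1), (N:145, O:2, U:3) and (N:7, U:3).  OOB leaf
#' statistics are supplied literally, so [compact_fv()] on this model is an
#' exact, training-free regression fixture:
#' `Prec(GO:0006887, N) = (35+145+7)/(36+150+10) = 0.9541`.
#'
#' @return An `rf_model` with one tree carrying stored OOB counts.
#' @export
worked_example_forest <- function() {
  feats <- c("GO:0006887", "GO:0042221", "GO:0043005", "GO:0043230")
  fi <- stats::setNames(seq_along(feats), feats)
  nn <- 11L
  tr <- list(
    feature = rep(NA_integer_, nn), threshold = rep(NA_real_, nn),
    left = rep(NA_integer_, nn), right = rep(NA_integer_, nn),
    parent = rep(NA_integer_, nn), side = rep(NA_integer_, nn),
    is_leaf = rep(TRUE, nn), pred = rep(NA_integer_, nn)
  )
  split_node <- function(id, f, l, r) {
    tr$feature[id] <<- fi[[f]]; tr$threshold[id] <<- 0.5
    tr$left[id] <<- l; tr$right[id] <<- r
    tr$is_leaf[id] <<- FALSE
    tr$parent[l] <<- id; tr$side[l] <<- 0L
    tr$parent[r] <<- id; tr$side[r] <<- 1L
  }
  split_node(1L, "GO:0043230", 2L, 5L)
  split_node(2L, "GO:0006887", 3L, 4L)   # GO:0043230 = 0 branch
  split_node(5L, "GO:0006887", 6L, 7L)   # GO:0043230 = 1 branch
  split_node(7L, "GO:0043005", 8L, 9L)
  split_node(8L, "GO:0042221", 10L, 11L)
  cls <- stats::setNames(seq_along(CLASS_ORDER), CLASS_ORDER)
  leaf_pred <- c(`3` = "U", `4` = "N", `6` = "O", `9` = "N",
                 `10` = "N", `11` = "O")
  for (id in names(leaf_pred)) tr$pred[as.integer(id)] <- cls[[leaf_pred[[id]]]]
  counts <- matrix(0L, nn, 3, dimnames = list(NULL, CLASS_ORDER))
  counts[cbind(as.integer(names(leaf_pred)), cls[leaf_pred])] <- 1L
  tr$counts <- counts
  oob <- matrix(0, nn, 3, dimnames = list(NULL, CLASS_ORDER))
  oob[9, ] <- c(0, 1, 35)     # rule 1: 43230=1 & 6887=1 & 43005=1 -> N
  oob[10, ] <- c(2, 3, 145)   # rule 2: ... & 43005=0 & 42221=0 -> N
  oob[4, ] <- c(0, 3, 7)      # rule 3: 43230=0 & 6887=1 -> N
  tr$oob_counts <- oob
  tr$in_bag <- integer(0)
  tr$oob <- integer(0)
  structure(
    list(trees = list(tr),
         config = list(ntree = 1L, mtry = 1L, undersample = FALSE,
                       min_node_size = 2L, seed = 0L),
         classes = CLASS_ORDER,
         feature_ids = feats,
         feature_kind = stats::setNames(rep("binary", length(feats)), feats)),
    class = "rf_model"
  )
}
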