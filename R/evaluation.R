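# Predictive-accuracy evaluation: Mann-Whitney AUROC, its class-weighted
# multiclass aggregate, the mtry/ntree parameter grid, and the nested
# (outer x inner) cross-validation protocol with in-bag under-sampling.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the fraction of (positive, negative) pairs in which the positive
#' instance outscores the negative one, crediting ties 0.5 — the rank-sum
#' identity, so ROC-curve construction is unnecessary.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positives Logical (or 0/1) vector marking the positive class.
#'
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positives) {
  positives <- as.logical(positives)
  stopifnot(length(scores) == length(positives))
  npos <- sum(positives)
  nneg <- sum(!positives)
  if (npos == 0 || nneg == 0) {
    stop("auroc undefined: need at least one positive and one negative")
  }
  r <- rank(scores)  # midranks handle ties as 0.5 credit
  (sum(r[positives]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Class-count-weighted average of per-class AUROCs
#'
#' @param aucs Numeric vector of per-class AUROCs (`NA` allowed for classes
#'   undefined in a fold; they are dropped and the weights renormalized).
#' @param weights Non-negative weights, typically class instance counts or
#'   proportions.
#'
#' @return Weighted mean AUROC.
#' @export
weighted_auroc <- function(aucs, weights) {
  stopifnot(length(aucs) == length(weights), all(weights >= 0, na.rm = TRUE))
  ok <- !is.na(aucs) & weights > 0
  if (!any(ok)) stop("no class with a defined AUROC")
  sum(aucs[ok] * weights[ok]) / sum(weights[ok])
}

#' One-vs-rest multiclass AUROC from a probability matrix
#'
#' @param prob Matrix (instances x classes) of class probabilities with
#'   column names matching the class labels.
#' @param labels Factor (or character) of true classes.
#'
#' @return List with `per_class` (named AUROC vector, `NA` where a class
#'   has no positive or no negative instance) and `weighted` (instance-count
#'   weighted average over the defined classes).
#' @export
multiclass_auroc <- function(prob, labels) {
  labels <- as.character(labels)
  classes <- colnames(prob)
  per_class <- stats::setNames(rep(NA_real_, length(classes)), classes)
  counts <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    pos <- labels == cl
    counts[cl] <- sum(pos)
    if (any(pos) && any(!pos)) per_class[cl] <- auroc(prob[, cl], pos)
  }
  list(per_class = per_class,
       weighted = weighted_auroc(per_class, counts))
}

#' Candidate mtry values derived from the feature count
#'
#' The three candidates are `0.5, 1 and 2` times `sqrt(J)`: `floor` for the
#' 0.5 multiplier and round-half-up for the others.  Paired with `ntree`
#' candidates `{100, 200, 300}`.
#'
#' @param J Number of features (>= 4).
#' @return List of class `param_grid` with `mtry` (strictly increasing
#'   integer triple) and `ntree`.
#' @export
mtry_grid <- function(J) {
  stopifnot(J >= 4)
  s <- sqrt(J)
  mtry <- c(floor(0.5 * s), floor(s + 0.5), floor(2 * s + 0.5))
  structure(list(mtry = as.integer(mtry), ntree = c(100L, 200L, 300L)),
            class = "param_grid")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so every fold holds every class (given enough instances).
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Modal parameter pair across outer folds
#'
#' @param selections List (or data.frame) of `(ntree, mtry)` pairs selected
#'   per outer fold.  Ties on frequency break towards larger `ntree`, then
#'   smaller `mtry`.
#' @return Named integer vector `c(ntree, mtry)`.
#' @export
select_final_params <- function(selections) {
  if (is.data.frame(selections)) {
    df <- selections
  } else {
    stopifnot(length(selections) > 0)
    df <- do.call(rbind, lapply(selections, function(p) {
      data.frame(ntree = p[[1]], mtry = p[[2]])
    }))
  }
  if (nrow(df) == 0) stop("no parameter selections supplied")
  key <- paste(df$ntree, df$mtry)
  tab <- table(key)
  cand <- df[!duplicated(key), , drop = FALSE]
  cand$freq <- as.integer(tab[paste(cand$ntree, cand$mtry)])
  cand <- cand[order(-cand$freq, -cand$ntree, cand$mtry), , drop = FALSE]
  c(ntree = as.integer(cand$ntree[1]), mtry = as.integer(cand$mtry[1]))
}

#' Nested cross-validation with inner-loop parameter selection
#'
#' Runs `runs` repetitions of stratified `outer_folds`-fold cross-validation.
#' Within each outer training portion, every `(ntree, mtry)` pair of the
#' grid is scored by stratified `inner_folds`-fold cross-validation
#' (weighted multiclass AUROC); the winning pair (ties to larger `ntree`,
#' then smaller `mtry`) refits on the full training portion and is scored on
#' the held-out fold.  Under-sampling, when enabled, acts only inside tree
#' training — test folds are never rebalanced.
#'
#' @param ds An [annotation_dataset()].
#' @param grid A `param_grid` (default [mtry_grid()] on the dataset's
#'   feature count), or any list with `mtry` and `ntree` integer vectors.
#' @param outer_folds,inner_folds Fold counts (defaults 10 and 5).
#' @param runs Repetitions of the outer loop (default 30).
#' @param undersample Balance each tree's in-bag multiset (default `TRUE`).
#' @param min_node_size Passed to [train_forest()].
#' @param seed Integer seed; the result is fully reproducible.
#'
#' @return Object of class `cv_result`: `per_class_auroc` (mean over
#'   folds x runs where defined), `weighted_auroc`, `selected_params` (one
#'   row per outer fold per run), `fold_auroc`, `runs`, `folds`, `config`.
#' @export
nested_cv <- function(ds, grid = NULL, outer_folds = 10, inner_folds = 5,
                      runs = 30, undersample = TRUE, min_node_size = 2,
                      seed = 1) {
  stopifnot(inherits(ds, "annotation_dataset"))
  J <- ncol(design_matrix(ds))
  grid <- grid %||% mtry_grid(J)
  if (any(grid$mtry > J)) stop("grid mtry exceeds feature count")
  cls_n <- table(ds$labels)
  if (any(cls_n < outer_folds)) {
    stop("class(es) with fewer instances than outer folds: ",
         paste(names(cls_n)[cls_n < outer_folds], collapse = ", "),
         " — folds are stratified by class and need >= 1 instance per fold")
  }
  combos <- expand.grid(ntree = grid$ntree, mtry = grid$mtry)
  sel <- data.frame(run = integer(0), fold = integer(0),
                    ntree = integer(0), mtry = integer(0))
  fold_auc <- numeric(0)
  per_class_acc <- matrix(NA_real_, nrow = 0, ncol = length(CLASS_ORDER),
                          dimnames = list(NULL, CLASS_ORDER))
  for (run in seq_len(runs)) {
    fold <- with_seed(derive_seed(seed, run, 1),
                      stratified_folds(ds$labels, outer_folds))
    for (of in seq_len(outer_folds)) {
      train_idx <- which(fold != of)
      test_idx <- which(fold == of)
      train_ds <- subset_instances(ds, train_idx)
      if (nlevels(droplevels(train_ds$labels)) < length(CLASS_ORDER)) {
        stop("a class vanished from the training portion of outer fold ", of)
      }
      # inner grid search
      inner_fold <- with_seed(derive_seed(seed, run, of, 2),
                              stratified_folds(train_ds$labels, inner_folds))
      combo_auc <- numeric(nrow(combos))
      for (ci in seq_len(nrow(combos))) {
        aucs <- numeric(inner_folds)
        for (inf in seq_len(inner_folds)) {
          itr <- subset_instances(train_ds, which(inner_fold != inf))
          iva <- subset_instances(train_ds, which(inner_fold == inf))
          m <- train_forest(itr, ntree = combos$ntree[ci],
                            mtry = combos$mtry[ci],
                            undersample = undersample,
                            min_node_size = min_node_size,
                            seed = derive_seed(seed, run, of, inf, ci))
          aucs[inf] <- multiclass_auroc(predict(m, iva), iva$labels)$weighted
        }
        combo_auc[ci] <- mean(aucs)
      }
      ord <- order(-combo_auc, -combos$ntree, combos$mtry)
      best <- combos[ord[1], ]
      sel <- rbind(sel, data.frame(run = run, fold = of,
                                   ntree = best$ntree, mtry = best$mtry))
      m <- train_forest(train_ds, ntree = best$ntree, mtry = best$mtry,
                        undersample = undersample,
                        min_node_size = min_node_size,
                        seed = derive_seed(seed, run, of, 99))
      test_ds <- subset_instances(ds, test_idx)
      res <- multiclass_auroc(predict(m, test_ds), test_ds$labels)
      fold_auc <- c(fold_auc, res$weighted)
      per_class_acc <- rbind(per_class_acc, res$per_class)
    }
  }
  structure(
    list(per_class_auroc = colMeans(per_class_acc, na.rm = TRUE),
         weighted_auroc = mean(fold_auc),
         selected_params = sel,
         fold_auroc = fold_auc,
         runs = runs, folds = outer_folds,
         config = list(grid = grid, inner_folds = inner_folds,
                       undersample = undersample,
                       min_node_size = min_node_size, seed = seed,
                       mtry_rounding = "floor for 0.5*sqrt(J); half-up otherwise")),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d run(s) x %d outer folds\n", x$runs, x$folds))
  cat("per-class AUROC:",
      paste(sprintf("%s=%.3f", names(x$per_class_auroc), x$per_class_auroc),
            collapse = "  "), "\n")
  cat(sprintf("weighted AUROC: %.3f\n", x$weighted_auroc))
  fp <- select_final_params(x$selected_params)
  cat(sprintf("modal parameters: ntree=%d mtry=%d\n", fp["ntree"], fp["mtry"]))
  invisible(x)
}
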