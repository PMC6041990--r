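# Forest serialization: a structured JSON text format carrying the full
# split structure, leaf statistics and per-tree in-bag/OOB bookkeeping.
# Round-trips exactly (thresholds are written at full precision).

#' Write / read a forest as JSON
#'
#' @param model An `rf_model`.
#' @param path Output path.
#' @export
write_forest_json <- function(model, path) {
  stopifnot(inherits(model, "rf_model"))
  trees <- lapply(model$trees, function(tr) {
    out <- list(
      feature = tr$feature, threshold = tr$threshold,
      left = tr$left, right = tr$right,
      parent = tr$parent, side = tr$side,
      is_leaf = tr$is_leaf, pred = tr$pred,
      counts = tr$counts,
      in_bag = tr$in_bag, train_rows = tr$train_rows, oob = tr$oob
    )
    if (!is.null(tr$oob_counts)) out$oob_counts <- tr$oob_counts
    out
  })
  obj <- list(format = "compactfv-forest", version = 1L,
              config = model$config, classes = model$classes,
              feature_ids = model$feature_ids,
              feature_kind = unname(model$feature_kind),
              trees = trees)
  jsonlite::write_json(obj, path, digits = NA, na = "null",
                       auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_forest_json
#' @return `read_forest_json()` returns the `rf_model`.
#' @export
read_forest_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "compactfv-forest")) {
    stop("not a forest JSON file: ", path)
  }
  vec <- function(v, mode) {
    if (is.null(v) || length(v) == 0) return(vector(mode, 0))
    v <- unlist(lapply(v, function(x) if (is.null(x)) NA else x))
    storage.mode(v) <- mode
    v
  }
  fix_tree <- function(tr) {
    out <- list(
      feature = vec(tr$feature, "integer"),
      threshold = vec(tr$threshold, "double"),
      left = vec(tr$left, "integer"), right = vec(tr$right, "integer"),
      parent = vec(tr$parent, "integer"), side = vec(tr$side, "integer"),
      is_leaf = vec(tr$is_leaf, "logical"), pred = vec(tr$pred, "integer"),
      counts = matrix(vec(tr$counts, "integer"),
                      ncol = length(obj$classes)),
      in_bag = vec(tr$in_bag, "integer"),
      train_rows = vec(tr$train_rows, "integer"),
      oob = vec(tr$oob, "integer")
    )
    if (!is.null(tr$oob_counts)) {
      out$oob_counts <- matrix(vec(tr$oob_counts, "double"),
                               ncol = length(obj$classes),
                               dimnames = list(NULL, obj$classes))
    }
    out
  }
  trees <- lapply(obj$trees, fix_tree)
  structure(
    list(trees = trees,
         config = list(ntree = as.integer(obj$config$ntree),
                       mtry = as.integer(obj$config$mtry),
                       undersample = as.logical(obj$config$undersample),
                       min_node_size = as.integer(obj$config$min_node_size),
                       seed = as.integer(obj$config$seed)),
         classes = as.character(obj$classes),
         feature_ids = as.character(obj$feature_ids),
         feature_kind = stats::setNames(as.character(obj$feature_kind),
                                        as.character(obj$feature_ids))),
    class = "rf_model"
  )
}
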