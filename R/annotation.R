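# Annotation dataset construction: binary gene x GO-term matrix with
# ancestor closure, minimum-support filtering, and the numeric
# total-annotation feature.

#' Construct an annotation dataset
#'
#' Low-level constructor.  Most users will call [build_annotation_matrix()].
#'
#' @param x Binary integer matrix (instances x features) with dimnames.
#' @param labels Per-instance class labels in `{O, U, N}` (recycled to a
#'   factor with that level order).
#' @param total Optional per-instance numeric total-annotation feature.
#'
#' @return An object of class `annotation_dataset` with elements `x`
#'   (binary matrix), `labels` (factor), `instance_ids`, `feature_ids` and
#'   `total` (numeric vector or `NULL`).
#' @export
annotation_dataset <- function(x, labels, total = NULL) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("annotation matrix entries must be 0 or 1")
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("annotation matrix needs instance and feature dimnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicated instance ids")
  if (anyDuplicated(colnames(x))) stop("duplicated feature ids")
  labels <- as_class_factor(labels)
  if (length(labels) != nrow(x)) stop("labels length must match instance count")
  if (!is.null(total)) {
    total <- as.numeric(total)
    if (length(total) != nrow(x)) stop("total length must match instance count")
    if (any(total < 0)) stop("total annotations must be non-negative")
  }
  structure(
    list(x = x, labels = labels,
         instance_ids = rownames(x), feature_ids = colnames(x), total = total),
    class = "annotation_dataset"
  )
}

#' @export
print.annotation_dataset <- function(x, ...) {
  cat(sprintf("annotation_dataset: %d instances x %d binary features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$total)) "" else " (+ total)"))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.annotation_dataset <- function(x) dim(x$x)

# Numeric design matrix handed to the forest: binary columns plus the
# "total" column when present.
design_matrix <- function(ds) {
  m <- ds$x
  storage.mode(m) <- "double"
  if (!is.null(ds$total)) m <- cbind(m, total = ds$total)
  m
}

feature_kinds <- function(ds) {
  k <- rep("binary", ncol(ds$x))
  names(k) <- colnames(ds$x)
  if (!is.null(ds$total)) k <- c(k, total = "numeric")
  k
}

#' Build the binary annotation matrix from gene-term pairs
#'
#' Each gene's annotation set is closed under is-a ancestry before the
#' matrix is assembled.  Rows are sorted gene ids, columns are sorted term
#' ids (terms that annotate at least one gene after closure), so output is
#' byte-reproducible.  Genes present in `labels` but absent from `pairs`
#' receive an all-zero row.
#'
#' @param pairs Two-column data.frame (gene id, term id); duplicates allowed.
#' @param dag An [ontology_dag()].
#' @param labels Named character vector or two-column data.frame mapping
#'   gene id to class in `{O, U, N}`.
#' @param on_unknown Passed to the closure step: `"skip"` unknown terms with
#'   a warning (default) or `"error"`.
#'
#' @return An [annotation_dataset()] (without the total feature; see
#'   [add_total_feature()]).
#' @export
build_annotation_matrix <- function(pairs, dag, labels,
                                    on_unknown = c("skip", "error")) {
  on_unknown <- match.arg(on_unknown)
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  pairs <- data.frame(gene = as.character(pairs[[1]]),
                      term = as.character(pairs[[2]]),
                      stringsAsFactors = FALSE)
  unlabeled <- setdiff(unique(pairs$gene), names(labels))
  if (length(unlabeled) > 0) {
    stop("gene(s) without class label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  }
  unknown <- setdiff(unique(pairs$term), dag$terms)
  if (length(unknown) > 0) {
    if (on_unknown == "error") {
      stop("annotation term(s) not in ontology: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    warning("skipping ", length(unknown),
            " annotation term(s) not in ontology: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    pairs <- pairs[!(pairs$term %in% unknown), , drop = FALSE]
  }
  genes <- sort(unique(names(labels)))
  anc <- ancestor_index_sets(dag)
  term_idx <- stats::setNames(seq_along(dag$terms), dag$terms)
  by_gene <- split(unname(term_idx[pairs$term]), pairs$gene)
  closed <- lapply(by_gene, function(tt) {
    tt <- unique(tt)
    unique(c(tt, unlist(anc[tt], use.names = FALSE)))
  })
  used <- sort(unique(unlist(closed, use.names = FALSE)))
  feats <- sort(dag$terms[used])
  m <- matrix(0L, nrow = length(genes), ncol = length(feats),
              dimnames = list(genes, feats))
  col_of <- stats::setNames(seq_along(feats), feats)
  for (g in names(closed)) {
    m[g, col_of[dag$terms[closed[[g]]]]] <- 1L
  }
  annotation_dataset(m, labels[genes])
}

#' Drop features with low annotation support
#'
#' Removes binary features annotating fewer than `min_count` instances, the
#' standard guard against GO terms with too little statistical support.
#'
#' @param ds An [annotation_dataset()].
#' @param min_count Minimum number of positive instances (default 10).
#'
#' @return The filtered dataset; instances and the total feature untouched.
#' @export
filter_min_support <- function(ds, min_count = 10) {
  stopifnot(inherits(ds, "annotation_dataset"), min_count >= 1)
  keep <- colSums(ds$x) >= min_count
  out <- ds
  out$x <- ds$x[, keep, drop = FALSE]
  out$feature_ids <- colnames(out$x)
  out
}

#' Append the total-annotation numeric feature
#'
#' Adds a numeric feature named `"total"` holding each instance's number of
#' annotated terms, counted from the current binary matrix.  Call it after
#' ancestor closure and before [filter_min_support()] to count the full
#' closed annotation set (the recommended pipeline order).
#'
#' @param ds An [annotation_dataset()].
#'
#' @return The dataset with `total` populated.
#' @export
add_total_feature <- function(ds) {
  stopifnot(inherits(ds, "annotation_dataset"))
  if (!is.null(ds$total) || "total" %in% colnames(ds$x)) {
    stop("feature 'total' already present")
  }
  ds$total <- as.numeric(rowSums(ds$x))
  ds
}

#' Read annotation pairs from TSV or GAF
#'
#' @param path File path.  For `format = "tsv"`, two tab-separated columns
#'   (gene id, term id), no header.  For `format = "gaf"`, GAF 2.x: comment
#'   lines starting with `!` are skipped and columns 2 (object id) and
#'   5 (GO id) are used.
#' @param format `"tsv"` (default) or `"gaf"`.
#'
#' @return Two-column data.frame `gene`, `term`.
#' @export
read_annotation_pairs <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "gaf") lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    bad <- which(vapply(parts, length, 1L) < 2)
    if (length(bad) > 0) stop("malformed pair line ", bad[[1]])
    data.frame(gene = vapply(parts, `[[`, "", 1),
               term = vapply(parts, `[[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    bad <- which(vapply(parts, length, 1L) < 5)
    if (length(bad) > 0) stop("malformed GAF line ", bad[[1]])
    data.frame(gene = vapply(parts, `[[`, "", 2),
               term = vapply(parts, `[[`, "", 5),
               stringsAsFactors = FALSE)
  }
}

#' Read per-gene class labels from a two-column TSV
#'
#' @param path Tab-separated file: gene id, class in `{O, U, N}`; no header.
#' @return Named character vector of classes.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("labels file needs two tab-separated columns")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write / read a prepared dataset as dense TSV
#'
#' Columns: `gene_id`, `label`, optionally `total`, then one 0/1 column per
#' feature.  Intended for desk-scale datasets; round-trips exactly.
#'
#' @param ds An [annotation_dataset()].
#' @param path Output path.
#' @export
write_dataset_tsv <- function(ds, path) {
  df <- data.frame(gene_id = ds$instance_ids,
                   label = as.character(ds$labels),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(ds$total)) df$total <- ds$total
  df <- cbind(df, as.data.frame(ds$x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @return `read_dataset_tsv()` returns the [annotation_dataset()].
#' @export
read_dataset_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, quote = "")
  has_total <- "total" %in% names(df)[seq_len(min(3, ncol(df)))]
  meta <- c("gene_id", "label", if (has_total) "total")
  featcols <- setdiff(names(df), meta)
  m <- as.matrix(df[, featcols, drop = FALSE])
  rownames(m) <- df$gene_id
  annotation_dataset(m, df$label, total = if (has_total) df$total else NULL)
}

# Subset instances (used by cross-validation); keeps feature set fixed.
subset_instances <- function(ds, idx) {
  out <- ds
  out$x <- ds$x[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]
  out$instance_ids <- ds$instance_ids[idx]
  if (!is.null(ds$total)) out$total <- ds$total[idx]
  out
}
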