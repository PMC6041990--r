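# Ontology handling: OBO (is_a subset) parsing, the is-a DAG, and ancestor
# closure of annotation sets.  Only `is_a:` edges define the hierarchy;
# `relationship:` lines (part_of etc.) are deliberately ignored because a GO
# annotation only implies its is-a ancestors.

#' Construct an is-a ontology DAG
#'
#' @param terms Character vector of term identifiers (no duplicates).
#' @param edges Two-column matrix or data.frame of `(child, parent)` term
#'   identifiers; both endpoints must appear in `terms`.
#' @param names Optional named character vector of human-readable term names
#'   (names are term ids).
#'
#' @return An object of class `ontology_dag` with elements `terms`,
#'   `edges` (data.frame with columns `child`, `parent`) and `term_names`.
#'   Construction fails if the edge set contains a directed cycle.
#' @export
ontology_dag <- function(terms, edges = NULL, names = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicated term identifiers")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(edges[[1]]),
                        parent = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
    missing <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(missing) > 0) {
      stop("edge endpoint(s) not declared as terms: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  dag <- structure(
    list(terms = terms, edges = edges,
         term_names = names %||% stats::setNames(character(0), character(0))),
    class = "ontology_dag"
  )
  check_acyclic(dag)
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d is_a edges\n",
              length(x$terms), nrow(x$edges)))
  invisible(x)
}

# Kahn topological sort over the child -> parent orientation; on failure
# reports one directed cycle in the error message.
check_acyclic <- function(dag) {
  n <- length(dag$terms)
  if (n == 0 || nrow(dag$edges) == 0) return(invisible(TRUE))
  idx <- stats::setNames(seq_len(n), dag$terms)
  child <- unname(idx[dag$edges$child])
  parent <- unname(idx[dag$edges$parent])
  indeg <- tabulate(parent, nbins = n)       # edges arriving at each node
  out_edges <- split(parent, child)          # node -> its parents
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[length(queue)]]
    queue <- queue[-length(queue)]
    seen <- seen + 1L
    for (p in out_edges[[as.character(v)]] %||% integer(0)) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < n) {
    cyc <- find_cycle(dag)
    stop("ontology contains an is_a cycle: ", paste(cyc, collapse = " -> "))
  }
  invisible(TRUE)
}

# Depth-first search for one cycle (used only for the error diagnostic).
find_cycle <- function(dag) {
  parents_of <- split(dag$edges$parent, dag$edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- state[[v]] %||% 0L
    if (st == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == 2L) return()
    state[[v]] <- 1L
    path <<- c(path, v)
    for (p in parents_of[[v]] %||% character(0)) visit(p)
    path <<- path[-length(path)]
    state[[v]] <- 2L
  }
  for (t in dag$terms) {
    visit(t)
    if (!is.null(found)) break
  }
  found %||% character(0)
}

#' Parse an OBO 1.2 ontology restricted to is_a edges
#'
#' Reads `[Term]` stanzas, keeping the `id:`, `name:` and `is_a:` tags.
#' Obsolete terms (`is_obsolete: true`) are dropped together with their
#' edges.  All other stanza types and relationship lines are ignored.
#'
#' @param source Path to an OBO file, or a character vector of lines.
#'
#' @return An [ontology_dag()].
#' @export
parse_obo <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  in_term <- FALSE
  cur <- NULL
  terms <- character(0)
  term_names <- character(0)
  edge_child <- character(0)
  edge_parent <- character(0)
  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$id)) {
      stop("malformed [Term] stanza starting at line ", cur$line, ": missing id")
    }
    if (!cur$obsolete) {
      terms <<- c(terms, cur$id)
      if (!is.na(cur$name)) term_names[cur$id] <<- cur$name
      if (length(cur$is_a) > 0) {
        edge_child <<- c(edge_child, rep(cur$id, length(cur$is_a)))
        edge_parent <<- c(edge_parent, cur$is_a)
      }
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(id = NA_character_, name = NA_character_,
                    is_a = character(0), obsolete = FALSE, line = i)
      }
      next
    }
    if (!in_term) next
    if (startsWith(ln, "id:")) {
      id <- trimws(sub("^id:", "", ln))
      if (id == "") stop("malformed stanza: empty id at line ", i)
      cur$id <- id
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("^is_a:", "", ln))
      tgt <- trimws(sub("!.*$", "", tgt))  # strip trailing comment
      if (tgt == "") stop("malformed is_a line at line ", i)
      cur$is_a <- c(cur$is_a, tgt)
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  flush()
  if (anyDuplicated(terms)) {
    stop("duplicated term id(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  # drop edges whose parent is an obsolete/undeclared term
  keep <- edge_parent %in% terms & edge_child %in% terms
  ontology_dag(terms,
               if (any(keep)) data.frame(child = edge_child[keep],
                                         parent = edge_parent[keep]) else NULL,
               names = term_names)
}

# Per-term ancestor index sets (excluding self), memoised in reverse
# topological order.  Returns a list indexed like dag$terms.
ancestor_index_sets <- function(dag) {
  n <- length(dag$terms)
  idx <- stats::setNames(seq_len(n), dag$terms)
  parents <- vector("list", n)
  if (nrow(dag$edges) > 0) {
    sp <- split(idx[dag$edges$parent], idx[dag$edges$child])
    parents[as.integer(names(sp))] <- lapply(sp, unname)
  }
  anc <- vector("list", n)
  done <- logical(n)
  # iterative DFS to avoid recursion limits on deep chains
  for (start in seq_len(n)) {
    if (done[start]) next
    stack <- list(start)
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      ps <- parents[[v]]
      pend <- if (is.null(ps)) integer(0) else ps[!done[ps]]
      if (length(pend) == 0) {
        acc <- integer(0)
        for (p in ps) acc <- c(acc, p, anc[[p]])
        anc[[v]] <- unique(acc)
        done[v] <- TRUE
        stack[[length(stack)]] <- NULL
      } else {
        stack <- c(stack, as.list(pend))
      }
    }
  }
  anc
}

#' Close a set of terms under is-a ancestry
#'
#' Expands an annotation set to contain every term reachable upwards through
#' `is_a` edges, mirroring the rule that a GO annotation implies all its
#' ancestors.  Idempotent and monotone in its input.
#'
#' @param dag An [ontology_dag()].
#' @param annotated Character vector of annotated term ids.
#' @param on_unknown What to do with terms absent from the DAG: `"skip"`
#'   (default; drops them with a warning — annotation files routinely lag the
#'   ontology release) or `"error"`.
#'
#' @return Character vector: `annotated` plus all ancestors, in sorted order.
#' @export
ancestor_closure <- function(dag, annotated, on_unknown = c("skip", "error")) {
  on_unknown <- match.arg(on_unknown)
  annotated <- unique(as.character(annotated))
  unknown <- setdiff(annotated, dag$terms)
  if (length(unknown) > 0) {
    if (on_unknown == "error") {
      stop("term(s) not in ontology: ", paste(unknown, collapse = ", "))
    }
    warning("skipping ", length(unknown), " term(s) not in ontology: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    annotated <- setdiff(annotated, unknown)
  }
  if (length(annotated) == 0) return(character(0))
  anc <- ancestor_index_sets(dag)
  idx <- match(annotated, dag$terms)
  out <- unique(c(idx, unlist(anc[idx], use.names = FALSE)))
  sort(dag$terms[out])
}
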