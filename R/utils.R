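# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# scripts.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically mix a base seed with one or more small non-negative
# integers, staying inside 32-bit signed range.  Exact doubles up to 2^53
# make the intermediate products safe.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    h <- (h * 48271 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(h)
}

CLASS_ORDER <- c("O", "U", "N")

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_ORDER)
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected O, U or N)")
  }
  factor(labels, levels = CLASS_ORDER)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
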