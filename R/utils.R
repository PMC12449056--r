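# Internal helpers shared across modules.

# Natural ordering of chromosome-style identifiers: numeric component first
# ("chr2" before "chr10"), pure strings after, ties lexicographic.
natural_order <- function(ids) {
  ids <- as.character(ids)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", ids)))
  order(is.na(num), num, ids, na.last = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic lexicographic argmax over the columns of a score matrix whose
# colnames are the class labels (columns must already be in sorted label
# order); exact score ties resolve to the first, i.e. smallest, label.
argmax_class <- function(scores) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  colnames(scores)[max.col(scores, ties.method = "first")]
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  x
}
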