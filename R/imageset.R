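# Bridge between pseudo-sequences and the classifier-facing image
# matrices: every sample's chromosome (and optionally concatenated genome)
# is rendered as a normalized CGR image and flattened into one row.

#' Render a sequence collection as flattened CGR image matrices
#'
#' @param sequences List `sample_id -> named chromosome string vector`
#'   (e.g. `sim$sequences` from [simulate_collection()] or `$seqs` of a
#'   [variants_to_pseudoseqs()] result).
#' @param resolution CGR image side length (default 64 for desk-scale
#'   studies; 224/512/1024 are typical full-scale choices).
#' @param normalize Normalization method, see [cgr_normalize()].
#' @param genome Also render the concatenated genome sequence per sample.
#' @return List of class `cgr_image_set` with `units` (named list
#'   `chromosome -> sample x pixel matrix`), `genome` (matrix or `NULL`),
#'   `resolution` and `normalize`.
#' @export
build_image_set <- function(sequences, resolution = 64L,
                            normalize = "robust", genome = TRUE) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  samples <- names(sequences)
  chroms <- names(sequences[[1L]])
  n_fallback <- 0L
  flat <- function(seq) {
    withCallingHandlers(
      as.vector(cgr_normalize(cgr_matrix(seq, resolution), normalize)),
      warning = function(w) {
        if (grepl("zero IQR", conditionMessage(w))) {
          n_fallback <<- n_fallback + 1L
          invokeRestart("muffleWarning")
        }
      })
  }
  on.exit(if (n_fallback > 0L) {
    warning(sprintf(paste0("%d image(s) had zero IQR under robust scaling ",
                           "and fell back to linear"), n_fallback),
            call. = FALSE)
  }, add = TRUE)
  units <- lapply(chroms, function(ch) {
    m <- t(vapply(samples, function(sid) flat(sequences[[sid]][[ch]]),
                  numeric(resolution^2)))
    rownames(m) <- samples
    m
  })
  names(units) <- chroms
  genome_m <- NULL
  if (genome) {
    genome_m <- t(vapply(samples, function(sid) {
      flat(concat_genome(sequences[[sid]]))
    }, numeric(resolution^2)))
    rownames(genome_m) <- samples
  }
  structure(list(units = units, genome = genome_m,
                 resolution = as.integer(resolution),
                 normalize = normalize),
            class = "cgr_image_set")
}

#' @export
print.cgr_image_set <- function(x, ...) {
  cat(sprintf("cgr_image_set: %d chromosomes%s, %d samples, R=%d, %s\n",
              length(x$units), if (is.null(x$genome)) "" else " + genome",
              nrow(x$units[[1L]]), x$resolution, x$normalize))
  invisible(x)
}
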