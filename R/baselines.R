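# Sequence-similarity baselines the CGR models are compared against:
#   1. pairwise-identity nearest neighbour over position-aligned
#      pseudo-sequences,
#   2. k-mer profile (distinct 21-mers) nearest neighbour with Jaccard
#      similarity,
#   3. a class-weighted support vector machine on the precomputed
#      similarity kernel.

#' Proportion of identical symbols between two aligned pseudo-sequences
#'
#' Sequences must have equal length (positions are orthologous by
#' construction).  Comparison is plain symbol equality, so `N` matches `N`
#' but mismatches every real base; the score is 1 exactly when the
#' sequences are identical.
#'
#' @param a,b Sequence strings of equal length.
#' @return Fraction of matching positions in `[0, 1]`.
#' @export
#' @examples
#' identity_similarity("AAAA", "AAAT")  # 0.75
identity_similarity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("alignment-contract error: sequences differ in length",
         call. = FALSE)
  }
  mean(charToRaw(a) == charToRaw(b))
}

# similarity of every test sequence (rows) to every train sequence (cols)
similarity_matrix <- function(test_seqs, train_seqs,
                              fun = identity_similarity) {
  out <- vapply(train_seqs, function(tr) {
    vapply(test_seqs, fun, numeric(1L), b = tr)
  }, numeric(length(test_seqs)))
  matrix(out, nrow = length(test_seqs),
         dimnames = list(names(test_seqs), names(train_seqs)))
}

# deterministic k-NN vote: similarity ties resolve by training-set order,
# label-count ties by the lexicographically smallest label
nn_vote <- function(sims, labels, k) {
  ord <- order(-sims, seq_along(sims))
  top <- labels[ord[seq_len(k)]]
  tal <- table(top)
  cand <- names(tal)[tal == max(tal)]
  min(cand)
}

#' Nearest-neighbour classification by pairwise sequence identity
#'
#' For each test sequence the `k` most similar training sequences (by
#' [identity_similarity()]) vote; `k = 1` is the default.
#'
#' @param test_seqs,train_seqs Named character vectors of aligned
#'   sequences.
#' @param train_labels Class label per training sequence.
#' @param k Neighbourhood size (must not exceed the training-set size).
#' @return Character vector of predicted labels, named by test sequence.
#' @export
knn_classify <- function(test_seqs, train_seqs, train_labels, k = 1L) {
  if (!length(train_seqs)) stop("empty training set", call. = FALSE)
  stopifnot(length(train_seqs) == length(train_labels),
            k >= 1L, k <= length(train_seqs))
  sims <- similarity_matrix(test_seqs, train_seqs)
  preds <- vapply(seq_len(nrow(sims)), function(i) {
    nn_vote(sims[i, ], train_labels, k)
  }, character(1L))
  stats::setNames(preds, names(test_seqs))
}

#' Distinct k-mer profile of a sequence
#'
#' The set of distinct length-`k` words over `{A,C,G,T}`; windows
#' containing any other symbol are skipped (not expanded), and no
#' reverse-complement canonicalization is applied because pseudo-sequences
#' have a fixed reference orientation.
#'
#' @param seq Sequence string.
#' @param k Word length (default 21).
#' @return Character vector of distinct k-mers (possibly empty).
#' @export
#' @examples
#' kmer_profile("ACGTACGT", k = 4)
kmer_profile <- function(seq, k = 21L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be >= 1", call. = FALSE)
  n <- nchar(seq)
  if (n < k) return(character(0))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- cumsum(!(chars %in% c("A", "C", "G", "T")))
  starts <- seq_len(n - k + 1L)
  ok <- (bad[starts + k - 1L] - c(0L, bad)[starts]) == 0L
  if (!any(ok)) return(character(0))
  unique(substring(toupper(seq), starts[ok], starts[ok] + k - 1L))
}

#' Jaccard similarity of two k-mer profiles
#'
#' `|intersection| / |union|`; two empty profiles give 0 with a warning.
#'
#' @param p,q Character vectors of distinct k-mers.
#' @return Similarity in `[0, 1]`.
#' @export
kmer_similarity <- function(p, q) {
  u <- length(union(p, q))
  if (u == 0L) {
    warning("both k-mer profiles empty; similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  length(intersect(p, q)) / u
}

#' Nearest-neighbour classification by k-mer Jaccard similarity
#'
#' @inheritParams knn_classify
#' @param k Word length for the profiles (default 21).
#' @param k_nn Neighbourhood size for the vote (default 1).
#' @return Character vector of predicted labels, named by test sequence.
#' @export
kmer_nn_classify <- function(test_seqs, train_seqs, train_labels, k = 21L,
                             k_nn = 1L) {
  if (!length(train_seqs)) stop("empty training set", call. = FALSE)
  stopifnot(length(train_seqs) == length(train_labels),
            k_nn >= 1L, k_nn <= length(train_seqs))
  train_prof <- lapply(train_seqs, kmer_profile, k = k)
  test_prof <- lapply(test_seqs, kmer_profile, k = k)
  preds <- vapply(seq_along(test_prof), function(i) {
    sims <- vapply(train_prof, kmer_similarity, numeric(1L),
                   p = test_prof[[i]])
    nn_vote(sims, train_labels, k_nn)
  }, character(1L))
  stats::setNames(preds, names(test_seqs))
}

#' Pairwise k-mer Jaccard similarity kernel
#'
#' @param seqs_a,seqs_b Named character vectors of sequences (rows /
#'   columns of the result).
#' @param k Word length (default 21).
#' @return Numeric `|a| x |b|` similarity matrix in `[0, 1]`.
#' @export
kmer_kernel <- function(seqs_a, seqs_b = seqs_a, k = 21L) {
  pa <- lapply(seqs_a, kmer_profile, k = k)
  pb <- if (identical(seqs_a, seqs_b)) pa else lapply(seqs_b, kmer_profile,
                                                      k = k)
  K <- matrix(0, length(pa), length(pb),
              dimnames = list(names(seqs_a), names(seqs_b)))
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      K[i, j] <- kmer_similarity(pa[[i]], pb[[j]])
    }
  }
  K
}

#' Support vector classification on a precomputed similarity kernel
#'
#' Trains a soft-margin SVM on the train-by-train kernel with
#' inverse-frequency class weighting and predicts from the test-by-train
#' kernel.
#'
#' @param K_train Symmetric train-by-train kernel matrix.
#' @param train_labels Class label per training row.
#' @param K_test Test-by-train kernel matrix (columns aligned with
#'   `K_train`).
#' @param C_reg Soft-margin cost (default 2).
#' @param weights Optional named class weights; default
#'   [class_weights()] of the training counts.
#' @return Character vector of predicted labels for the test rows.
#' @export
kernel_svm_classify <- function(K_train, train_labels, K_test, C_reg = 2,
                                weights = NULL) {
  stopifnot(is.matrix(K_train), nrow(K_train) == ncol(K_train),
            C_reg > 0, ncol(K_test) == ncol(K_train))
  if (max(abs(K_train - t(K_train))) > 1e-8) {
    stop("input error: training kernel is not symmetric", call. = FALSE)
  }
  y <- factor(train_labels)
  if (is.null(weights)) weights <- class_weights(table(y))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(unname(K_train)), y,
                       C = C_reg, class.weights = weights)
  sv <- kernlab::SVindex(fit)
  pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(
    unname(K_test)[, sv, drop = FALSE]))
  stats::setNames(as.character(pred), rownames(K_test))
}
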