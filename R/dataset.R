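# Dataset policy: minimum class size, per-class cap, top-proportion class
# subsetting, and stratified sample-level train/validation/test splitting.
# All operations work on a manifest data.frame with at least the columns
# `sample_id` and `class`; splitting adds a `split` column.  The split
# granularity is the biological sample, never the image, so all chromosome
# images of one sample land in one split and cannot leak across them.

check_manifest <- function(manifest, need_split = FALSE) {
  stopifnot(is.data.frame(manifest))
  need <- c("sample_id", "class", if (need_split) "split")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    stop(sprintf("manifest lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("manifest sample_id values must be unique", call. = FALSE)
  }
  invisible(manifest)
}

#' Drop undersized classes and cap oversized ones
#'
#' Classes with fewer than `min_samples` members are removed (three is the
#' minimum needed to place one sample in each of train, validation and
#' test); classes above `cap_per_class` are down-sampled to the cap,
#' deterministically under `seed`.
#'
#' @param manifest Data frame with `sample_id` and `class` columns.
#' @param min_samples Minimum class size (default 3).
#' @param cap_per_class Maximum class size (default 60; use 15 for a
#'   mildly-imbalanced preset).
#' @param seed Seed controlling which members of an over-cap class are kept.
#' @return A list of class `dataset_filter`: `manifest` (filtered, original
#'   row order), `dropped` (classes removed) and `capped` (classes
#'   down-sampled).
#' @export
filter_and_cap <- function(manifest, min_samples = 3L, cap_per_class = 60L,
                           seed = 1L) {
  check_manifest(manifest)
  if (min_samples > cap_per_class) {
    stop("min_samples must not exceed cap_per_class", call. = FALSE)
  }
  counts <- table(manifest$class)
  dropped <- names(counts)[counts < min_samples]
  keep <- manifest[!(manifest$class %in% dropped), , drop = FALSE]
  counts <- table(keep$class)
  capped <- names(counts)[counts > cap_per_class]
  if (length(capped)) {
    keep_ids <- withr::with_seed(seed, {
      unlist(lapply(split(keep$sample_id, keep$class), function(ids) {
        if (length(ids) > cap_per_class) sample(ids, cap_per_class) else ids
      }), use.names = FALSE)
    })
    keep <- keep[keep$sample_id %in% keep_ids, , drop = FALSE]
  }
  if (!nrow(keep)) stop("empty dataset after filtering", call. = FALSE)
  rownames(keep) <- NULL
  structure(list(manifest = keep, dropped = dropped, capped = capped),
            class = "dataset_filter")
}

#' Keep only the largest fraction of classes
#'
#' Retains the `ceiling(fraction * C)` classes with the most samples
#' (training samples when a `split` column is present), with count ties
#' broken in favour of the lexicographically smaller class label.
#'
#' @param manifest Data frame with `sample_id` and `class` (optionally
#'   `split`).
#' @param fraction Fraction of classes to keep, in (0, 1].
#' @return The manifest restricted to the kept classes.
#' @export
top_proportion <- function(manifest, fraction) {
  check_manifest(manifest)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  base <- if ("split" %in% names(manifest)) {
    manifest[manifest$split == "train", , drop = FALSE]
  } else {
    manifest
  }
  counts <- table(base$class)
  ord <- order(-as.integer(counts), names(counts))
  kept <- names(counts)[ord][seq_len(ceiling(fraction * length(counts)))]
  out <- manifest[manifest$class %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/validation/test split at sample granularity
#'
#' Per class, validation and test sizes are `floor(fraction * n)` with the
#' remainder assigned to train, then bumped so every class has at least one
#' sample in every split.  Assignment within a class is a seeded random
#' shuffle.  Classes with fewer than three samples violate the precondition
#' and raise an error.
#'
#' @param manifest Data frame with `sample_id` and `class`.
#' @param fractions Named numeric vector `c(train=, val=, test=)` summing
#'   to 1.
#' @param seed Seed for the within-class shuffles.
#' @return The manifest with an added `split` column.
#' @export
split_samples <- function(manifest,
                          fractions = c(train = 0.6, val = 0.2, test = 0.2),
                          seed = 1L) {
  check_manifest(manifest)
  stopifnot(all(c("train", "val", "test") %in% names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  counts <- table(manifest$class)
  if (any(counts < 3L)) {
    stop(sprintf("class(es) with fewer than 3 samples cannot be split: %s",
                 paste(names(counts)[counts < 3L], collapse = ", ")),
         call. = FALSE)
  }
  split <- rep(NA_character_, nrow(manifest))
  withr::with_seed(seed, {
    for (cl in sort(names(counts))) {
      rows <- which(manifest$class == cl)
      n <- length(rows)
      n_val <- max(1L, floor(fractions[["val"]] * n))
      n_test <- max(1L, floor(fractions[["test"]] * n))
      n_train <- n - n_val - n_test
      if (n_train < 1L) {
        stop(sprintf("split fractions leave no training sample for class %s",
                     cl), call. = FALSE)
      }
      rows <- sample(rows)
      split[rows[seq_len(n_train)]] <- "train"
      split[rows[n_train + seq_len(n_val)]] <- "val"
      split[rows[n_train + n_val + seq_len(n_test)]] <- "test"
    }
  })
  manifest$split <- split
  manifest
}
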