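# The four training/integration strategies over per-chromosome and
# whole-genome CGR images:
#   chromosome-wise  - one model per chromosome, metrics averaged
#   early integration - one model trained on the pooled chromosome images
#   late integration  - one model per chromosome, majority vote per sample
#   whole genome      - one model on the single genome-level CGR per sample
#
# Images are passed as a named list `unit -> matrix` where each matrix has
# one row per sample (rownames = sample_id) of flattened pixels, alongside a
# manifest with sample_id, class and split columns.

check_image_set <- function(images, manifest) {
  stopifnot(is.list(images), length(images) >= 1L)
  check_manifest(manifest, need_split = TRUE)
  for (u in names(images)) {
    miss <- setdiff(manifest$sample_id, rownames(images[[u]]))
    if (length(miss)) {
      stop(sprintf("unit '%s' lacks images for sample(s): %s", u,
                   paste(utils::head(miss, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

fit_unit_model <- function(images, manifest, unit, classifier, hp, seed) {
  train <- manifest[manifest$split == "train", , drop = FALSE]
  fit <- get_classifier(classifier)
  w <- class_weights(table(train$class))
  fit(images[[unit]][train$sample_id, , drop = FALSE], train$class,
      weights = w, hyperparams = hp, seed = seed)
}

#' Fit one model per chromosome (a model bank)
#'
#' @param images Named list `unit -> sample x pixel matrix`.
#' @param manifest Manifest with `sample_id`, `class`, `split`.
#' @param classifier Registry name of the classifier (default
#'   `"reference"`).
#' @param hp A [hyperparams()] object or `NULL`.
#' @param seed Seed forwarded to each model fit.
#' @return Named list `unit -> fitted model`, class `model_bank`; all
#'   models share one class list.
#' @export
fit_model_bank <- function(images, manifest, classifier = "reference",
                           hp = NULL, seed = 0L) {
  check_image_set(images, manifest)
  bank <- lapply(names(images), function(u) {
    fit_unit_model(images, manifest, u, classifier, hp, seed)
  })
  names(bank) <- names(images)
  cls <- lapply(bank, function(m) m$classes)
  if (length(unique(cls)) != 1L) {
    stop("configuration error: models disagree on the class list",
         call. = FALSE)
  }
  structure(bank, class = "model_bank")
}

#' Chromosome-wise strategy: independent models, averaged metrics
#'
#' Fits one model per unit (chromosome) on its training images and
#' evaluates each on its own test images; reports per-chromosome balanced
#' accuracy and their unweighted arithmetic mean.
#'
#' @inheritParams fit_model_bank
#' @return List with `per_chromosome` (named balanced accuracies),
#'   `mean_ba`, and `bank` (the fitted models).
#' @export
run_chromosome_wise <- function(images, manifest, classifier = "reference",
                                hp = NULL, seed = 0L) {
  bank <- fit_model_bank(images, manifest, classifier, hp, seed)
  test <- manifest[manifest$split == "test", , drop = FALSE]
  classes <- bank[[1L]]$classes
  per <- vapply(names(bank), function(u) {
    pred <- predict(bank[[u]], images[[u]][test$sample_id, , drop = FALSE])
    balanced_accuracy(confusion_matrix(test$class, pred, classes))$balanced_accuracy
  }, numeric(1L))
  list(per_chromosome = per, mean_ba = mean(per), bank = bank)
}

#' Early-integration strategy: one model on pooled chromosome images
#'
#' All per-chromosome training images are pooled (each labelled with its
#' sample's class) to train a single model.  Evaluation is per image by
#' default; `per_sample = TRUE` aggregates each test sample's per-chromosome
#' predictions by the same majority-vote rule used in late integration.
#'
#' @inheritParams fit_model_bank
#' @param per_sample Aggregate test predictions per sample.
#' @return List with `model`, `ba`, and `predictions` (data.frame with one
#'   row per test image, or per test sample when aggregating).
#' @export
run_early_integration <- function(images, manifest, classifier = "reference",
                                  hp = NULL, seed = 0L, per_sample = FALSE) {
  check_image_set(images, manifest)
  train <- manifest[manifest$split == "train", , drop = FALSE]
  test <- manifest[manifest$split == "test", , drop = FALSE]
  pool <- do.call(rbind, lapply(names(images), function(u) {
    images[[u]][train$sample_id, , drop = FALSE]
  }))
  labels <- rep(train$class, times = length(images))
  fit <- get_classifier(classifier)
  model <- fit(pool, labels, weights = class_weights(table(train$class)),
               hyperparams = hp, seed = seed)
  classes <- model$classes

  pred_by_unit <- lapply(names(images), function(u) {
    predict(model, images[[u]][test$sample_id, , drop = FALSE])
  })
  preds <- data.frame(
    sample_id = rep(test$sample_id, times = length(images)),
    unit = rep(names(images), each = nrow(test)),
    truth = rep(test$class, times = length(images)),
    predicted = unlist(pred_by_unit),
    stringsAsFactors = FALSE
  )
  if (per_sample) {
    score_by_unit <- lapply(names(images), function(u) {
      predict_scores(model, images[[u]][test$sample_id, , drop = FALSE])
    })
    agg <- majority_vote(pred_by_unit, score_by_unit, classes)
    preds <- data.frame(sample_id = test$sample_id, truth = test$class,
                        predicted = agg$final, stringsAsFactors = FALSE)
    ba <- balanced_accuracy(confusion_matrix(preds$truth, preds$predicted,
                                             classes))$balanced_accuracy
  } else {
    ba <- balanced_accuracy(confusion_matrix(preds$truth, preds$predicted,
                                             classes))$balanced_accuracy
  }
  list(model = model, ba = ba, predictions = preds)
}

# votes: list(unit -> character vector per sample); scores: list(unit ->
# score matrix per sample).  Returns final class per sample plus tie info.
majority_vote <- function(votes, scores, classes) {
  vm <- do.call(cbind, votes)                      # samples x units
  score_sum <- Reduce(`+`, scores)                 # samples x classes
  n <- nrow(vm)
  final <- character(n)
  tie_broken <- logical(n)
  tally_list <- vector("list", n)
  for (i in seq_len(n)) {
    tal <- table(factor(vm[i, ], levels = classes))
    top <- names(tal)[tal == max(tal)]
    if (length(top) == 1L) {
      final[i] <- top
    } else {
      tie_broken[i] <- TRUE
      mass <- score_sum[i, top]
      top <- top[mass == max(mass)]
      final[i] <- min(top)                         # lexicographic fallback
    }
    tally_list[[i]] <- tal
  }
  list(final = final, tie_broken = tie_broken, tallies = tally_list)
}

#' Late-integration prediction: per-chromosome majority vote
#'
#' Every model in the bank votes its argmax class for the sample; the modal
#' class wins.  Ties are resolved deterministically: first by the largest
#' total score mass for the tied classes summed across all models, then by
#' the lexicographically smallest class label.  The vote record documents
#' the tallies and whether a tie-break fired.
#'
#' @param bank A [fit_model_bank()] result.
#' @param images Named list `unit -> sample x pixel matrix` covering the
#'   samples to predict.
#' @param sample_ids Samples to predict (default: rownames of the first
#'   unit's matrix).
#' @return A data.frame (class `vote_record`) with `sample_id`,
#'   `predicted`, `n_votes`, `tie_broken`; per-chromosome votes in
#'   attribute `votes` (sample x unit matrix) and vote tallies in attribute
#'   `tallies`.
#' @export
predict_late_integration <- function(bank, images,
                                     sample_ids = rownames(images[[1L]])) {
  stopifnot(inherits(bank, "model_bank"))
  units <- names(bank)
  if (!length(sample_ids)) stop("no samples to predict", call. = FALSE)
  miss <- setdiff(units, names(images))
  if (length(miss)) {
    stop(sprintf("no images for unit(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  classes <- bank[[1L]]$classes
  votes <- lapply(units, function(u) {
    predict(bank[[u]], images[[u]][sample_ids, , drop = FALSE])
  })
  scores <- lapply(units, function(u) {
    predict_scores(bank[[u]], images[[u]][sample_ids, , drop = FALSE])
  })
  agg <- majority_vote(votes, scores, classes)
  vm <- do.call(cbind, votes)
  dimnames(vm) <- list(sample_id = sample_ids, unit = units)
  out <- data.frame(sample_id = sample_ids, predicted = agg$final,
                    n_votes = length(units), tie_broken = agg$tie_broken,
                    stringsAsFactors = FALSE)
  attr(out, "votes") <- vm
  attr(out, "tallies") <- agg$tallies
  class(out) <- c("vote_record", class(out))
  out
}

#' Late-integration strategy end to end
#'
#' Fits the per-chromosome model bank on the training split and evaluates
#' the majority vote on the test samples.
#'
#' @inheritParams fit_model_bank
#' @return List with `bank`, `votes` (the test [predict_late_integration()]
#'   record) and `ba`.
#' @export
run_late_integration <- function(images, manifest, classifier = "reference",
                                 hp = NULL, seed = 0L) {
  bank <- fit_model_bank(images, manifest, classifier, hp, seed)
  test <- manifest[manifest$split == "test", , drop = FALSE]
  rec <- predict_late_integration(bank, images, test$sample_id)
  ba <- balanced_accuracy(confusion_matrix(test$class, rec$predicted,
                                           bank[[1L]]$classes))$balanced_accuracy
  list(bank = bank, votes = rec, ba = ba)
}

#' Whole-genome strategy: one model on genome-level CGRs
#'
#' @param genome_images Matrix, one row per sample (rownames = sample_id)
#'   of flattened genome-CGR pixels.
#' @inheritParams fit_model_bank
#' @return List with `model`, `ba` and `predictions`.
#' @export
run_whole_genome <- function(genome_images, manifest,
                             classifier = "reference", hp = NULL,
                             seed = 0L) {
  res <- run_early_integration(list(genome = genome_images), manifest,
                               classifier = classifier, hp = hp, seed = seed)
  list(model = res$model, ba = res$ba, predictions = res$predictions)
}
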