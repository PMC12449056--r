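# Evaluation: per-class recall, balanced accuracy (the unweighted mean of
# per-class recalls, robust to class imbalance) and repeated-run
# aggregation.

#' Confusion matrix over a fixed class list
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class list fixing row/column order (default: sorted union
#'   of observed labels).  A label outside the list is an error.
#' @return Integer `C x C` matrix, rows = true class, columns = predicted.
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
confusion_matrix <- function(y_true, y_pred,
                             classes = sort(unique(c(y_true, y_pred)))) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) {
    stop(sprintf("label(s) outside the class list: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Balanced accuracy from a confusion matrix
#'
#' Per-class recall is `R_c = TP_c / (TP_c + FN_c)` (the diagonal over the
#' row sum) and balanced accuracy is the unweighted mean of the recalls of
#' the classes present in the truth.  Classes with zero test support are
#' excluded from the mean and reported in `excluded`.
#'
#' @param cm Confusion matrix (rows = truth), e.g. from
#'   [confusion_matrix()].
#' @return List with `recall` (named, `NaN` for zero-support classes),
#'   `balanced_accuracy`, and `excluded` (zero-support class names).
#' @export
balanced_accuracy <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  support <- rowSums(cm)
  if (all(support == 0)) {
    stop("undefined metric: no class has test support", call. = FALSE)
  }
  recall <- stats::setNames(diag(cm) / support, rownames(cm))
  present <- support > 0
  list(recall = recall,
       balanced_accuracy = mean(recall[present]),
       excluded = rownames(cm)[!present])
}

#' Balanced accuracy directly from label vectors
#'
#' @inheritParams confusion_matrix
#' @return Scalar balanced accuracy.
#' @export
balanced_accuracy_score <- function(y_true, y_pred,
                                    classes = sort(unique(c(y_true,
                                                            y_pred)))) {
  balanced_accuracy(confusion_matrix(y_true, y_pred,
                                     classes))$balanced_accuracy
}

#' Repeat an experiment across seeds and aggregate
#'
#' Runs `experiment(seed)` for seeds `base_seed .. base_seed + n_runs - 1`
#' and reports the mean and sample standard deviation (n - 1 denominator)
#' of the returned scalar (typically a balanced accuracy).  A failing run
#' aborts with its run index.  With a single run the standard deviation is
#' reported as 0 and flagged undefined.
#'
#' @param experiment Function of one argument (the seed) returning a
#'   scalar.
#' @param n_runs Number of repetitions (default 20).
#' @param base_seed First seed.
#' @return List with `values`, `seeds`, `mean`, `sd`, `sd_defined`.
#' @export
repeated_runs <- function(experiment, n_runs = 20L, base_seed = 1L) {
  stopifnot(n_runs >= 1L)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  values <- vapply(seq_along(seeds), function(i) {
    tryCatch(as.numeric(experiment(seeds[i])),
             error = function(e) {
               stop(sprintf("run %d (seed %d) failed: %s", i, seeds[i],
                            conditionMessage(e)), call. = FALSE)
             })
  }, numeric(1L))
  list(values = values, seeds = seeds, mean = mean(values),
       sd = if (n_runs > 1L) stats::sd(values) else 0,
       sd_defined = n_runs > 1L)
}
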