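# Class-imbalance machinery and the pluggable classifier contract.
#
# Class weights are inverse-frequency: w_c = N / (C * n_c), so rare classes
# weigh more and the identity sum_c w_c * n_c = N always holds.  The
# weighted cross-entropy averages per-sample losses over the minibatch size
# M (not over the summed weights), which keeps the loss insensitive to batch
# size but means it differs from some framework defaults whenever weights
# are non-uniform.

#' Inverse-frequency class weights
#'
#' `w_c = N / (C * n_c)` where `n_c` is the training count of class `c`,
#' `C` the number of classes and `N` the total count.  Uniform counts give
#' all weights 1 and `sum(w_c * n_c) = N` holds for any counts.
#'
#' @param counts Named vector of per-class training counts (all >= 1).
#' @return Named numeric vector of weights with attributes `N` and `C`.
#' @export
#' @examples
#' class_weights(c(a = 1, b = 3))  # 2.0 and 0.667
class_weights <- function(counts) {
  if (is.table(counts)) counts <- stats::setNames(as.integer(counts),
                                                  names(counts))
  stopifnot(!is.null(names(counts)))
  if (any(counts < 1)) {
    stop("undefined weight: every class needs at least one sample",
         call. = FALSE)
  }
  N <- sum(counts)
  C <- length(counts)
  structure(N / (C * counts), N = N, C = C)
}

#' Class-weighted cross-entropy loss
#'
#' For a minibatch of `M` rows of logits, the per-sample loss is
#' `l_m = -w[y_m] * log softmax(x_m)[y_m]` and the batch loss is the plain
#' mean `(1/M) * sum(l_m)`.  Computation is stabilized by row-max
#' subtraction.
#'
#' @param logits Numeric `M x C` matrix of unnormalized scores.
#' @param labels Class of each row: integer indices in `1..C`, or labels
#'   matched against `colnames(logits)` / `names(weights)`.
#' @param weights Per-class weights (default: all 1, the unweighted loss).
#' @return Scalar mean loss, with the per-sample losses in attribute
#'   `per_sample`.
#' @export
weighted_cross_entropy <- function(logits, labels, weights = NULL) {
  stopifnot(is.matrix(logits))
  if (!all(is.finite(logits))) {
    stop("non-finite logits", call. = FALSE)
  }
  C <- ncol(logits)
  if (is.null(weights)) weights <- rep(1, C)
  if (is.character(labels) || is.factor(labels)) {
    lv <- colnames(logits) %||% names(weights)
    stopifnot(!is.null(lv))
    labels <- match(as.character(labels), lv)
  }
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1L & labels <= C), length(labels) == nrow(logits))
  z <- logits - apply(logits, 1L, max)
  logp <- z - log(rowSums(exp(z)))
  w <- unname(weights)[labels]
  l <- -w * logp[cbind(seq_along(labels), labels)]
  structure(mean(l), per_sample = l)
}

#' Model training hyperparameters
#'
#' Defaults follow the study protocol for fine-tuning image classifiers:
#' batch size 16, 200 epochs, learning rate 0.01.  The built-in reference
#' classifier is closed-form and ignores the iterative parameters; they are
#' forwarded to registered plugin models.
#'
#' @param batch_size,epochs,learning_rate Positive training parameters.
#' @param seed Seed forwarded to stochastic trainers.
#' @return A `hyperparams` list.
#' @export
hyperparams <- function(batch_size = 16L, epochs = 200L,
                        learning_rate = 0.01, seed = 0L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "hyperparams")
}

#' Fit the built-in reference classifier (nearest centroid)
#'
#' A deterministic, dependency-light classifier honouring the classifier
#' contract: one centroid per class over flattened normalized images, score
#' = negative Euclidean distance to the centroid.  It stands in for heavy
#' fine-tuned image backbones in tests and small studies; external models
#' implementing the same contract (fit on images/labels/class weights,
#' score vectors over a fixed class list) can be registered with
#' [register_classifier()].
#'
#' @param x Numeric matrix, one row per image (flattened pixels).
#' @param labels Class label per row.
#' @param weights Optional class weights (accepted for contract parity; the
#'   centroid solution does not depend on them).
#' @param hyperparams A [hyperparams()] object (iterative parameters are
#'   ignored by the closed-form fit).
#' @param seed Unused by the deterministic fit; part of the contract.
#' @return An object of class `centroid_classifier` with elements `classes`
#'   and `centroids`.
#' @export
fit_reference_model <- function(x, labels, weights = NULL,
                                hyperparams = NULL, seed = 0L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (any(table(labels) < 1L)) stop("empty class", call. = FALSE)
  centroids <- rowsum(x, labels) / as.vector(table(labels)[sort(unique(labels))])
  centroids <- centroids[classes, , drop = FALSE]
  structure(list(classes = classes, centroids = centroids,
                 p = ncol(x)), class = "centroid_classifier")
}

#' Per-class scores of a fitted classifier
#'
#' @param object A fitted classifier.
#' @param x Matrix of flattened images, one row per case.
#' @param ... Unused.
#' @return Numeric matrix, one row per case, one column per class (columns
#'   in sorted class order); larger is better.
#' @export
predict_scores <- function(object, x, ...) UseMethod("predict_scores")

#' @export
predict_scores.centroid_classifier <- function(object, x, ...) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == object$p)
  cent <- object$centroids
  d2 <- outer(rowSums(x^2), rep(1, nrow(cent))) +
    outer(rep(1, nrow(x)), rowSums(cent^2)) - 2 * tcrossprod(x, cent)
  scores <- -sqrt(pmax(d2, 0))
  colnames(scores) <- object$classes
  rownames(scores) <- rownames(x)
  scores
}

#' @export
predict.centroid_classifier <- function(object, newdata,
                                        type = c("class", "scores"), ...) {
  type <- match.arg(type)
  scores <- predict_scores(object, newdata)
  if (type == "scores") return(scores)
  argmax_class(scores)
}

# ---- classifier plugin registry ---------------------------------------

.classifiers <- new.env(parent = emptyenv())

#' Register a classifier constructor under a name
#'
#' The constructor must have the signature
#' `function(x, labels, weights, hyperparams, seed)` and return a fitted
#' object supporting [predict_scores()] and `predict()`.
#'
#' @param name Registry key, e.g. `"reference"`.
#' @param fit_fun Constructor function.
#' @return Invisibly, `name`.
#' @export
register_classifier <- function(name, fit_fun) {
  stopifnot(is.character(name), is.function(fit_fun))
  assign(name, fit_fun, envir = .classifiers)
  invisible(name)
}

#' Look up a registered classifier constructor
#'
#' @param name Registry key.
#' @return The constructor function.
#' @export
get_classifier <- function(name) {
  if (!exists(name, envir = .classifiers, inherits = FALSE)) {
    stop(sprintf("no classifier registered under '%s' (available: %s)",
                 name, paste(ls(.classifiers), collapse = ", ")),
         call. = FALSE)
  }
  get(name, envir = .classifiers, inherits = FALSE)
}

.onLoad <- function(libname, pkgname) {
  register_classifier("reference", fit_reference_model)
}
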