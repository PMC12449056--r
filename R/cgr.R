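# Chaos game representation (CGR) of DNA-like sequences.
#
# Corner convention (Jeffrey's square): A=(0,0), C=(0,1), G=(1,1), T=(1,0);
# the walk starts at the centre (0.5, 0.5), which itself is not counted, and
# every symbol moves the current point halfway toward its target.  Symbols
# other than A/C/G/T (IUPAC ambiguity codes, N, gaps) step halfway toward
# the centre, so the map stays a contraction and ambiguous stretches collapse
# toward the middle of the square.

CGR_X <- c(A = 0, C = 0, G = 1, T = 1)
CGR_Y <- c(A = 0, C = 1, G = 1, T = 0)

#' Chaos-game trajectory of a sequence
#'
#' @param seq Sequence string (case-insensitive).
#' @return Numeric matrix with columns `x`, `y`; one row per symbol, all
#'   points inside the unit square.  The implicit start point (0.5, 0.5) is
#'   not emitted.
#' @export
#' @examples
#' cgr_trajectory("ACGT")
cgr_trajectory <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  tx <- unname(CGR_X[b])
  ty <- unname(CGR_Y[b])
  tx[is.na(tx)] <- 0.5
  ty[is.na(ty)] <- 0.5
  # p_i = (p_{i-1} + target_i) / 2 is the linear recursion
  # p_i = 0.5 * p_{i-1} + target_i / 2
  x <- as.numeric(stats::filter(tx / 2, 0.5, method = "recursive",
                                init = 0.5))
  y <- as.numeric(stats::filter(ty / 2, 0.5, method = "recursive",
                                init = 0.5))
  cbind(x = x, y = y)
}

#' Bin a CGR trajectory into an R x R count matrix
#'
#' Pixel column is `min(floor(x * R), R - 1)` and pixel row is
#' `min(floor((1 - y) * R), R - 1)` (0-based), so row 1 of the returned
#' matrix is the top of the image and the C (0,1) and G (1,1) corners render
#' at the top.  Each trajectory point increments its pixel by one; the total
#' count equals the trajectory length.
#'
#' @param traj Trajectory matrix from [cgr_trajectory()].
#' @param resolution Image side length R (>= 1).
#' @return Integer `R x R` matrix of class `cgr_matrix` with attribute
#'   `resolution`.
#' @export
cgr_accumulate <- function(traj, resolution) {
  R <- as.integer(resolution)
  if (is.na(R) || R < 1L) stop("invalid resolution: must be >= 1",
                               call. = FALSE)
  stopifnot(is.matrix(traj), ncol(traj) == 2L)
  col0 <- pmin(floor(traj[, 1L] * R), R - 1L)
  row0 <- pmin(floor((1 - traj[, 2L]) * R), R - 1L)
  counts <- matrix(tabulate(row0 + 1L + R * col0, nbins = R * R), nrow = R)
  structure(counts, class = c("cgr_matrix", class(counts)), resolution = R)
}

#' Sequence to CGR count matrix in one step
#'
#' @inheritParams cgr_trajectory
#' @inheritParams cgr_accumulate
#' @return A `cgr_matrix` (see [cgr_accumulate()]).
#' @export
#' @examples
#' m <- cgr_matrix("ACGTACGTTTGA", resolution = 4)
#' sum(m)  # equals nchar of the sequence
cgr_matrix <- function(seq, resolution) {
  cgr_accumulate(cgr_trajectory(seq), resolution)
}

minmax01 <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(array(0, dim = dim(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Normalize a CGR count matrix to a greyscale image in [0, 1]
#'
#' Methods: `"none"` divides by the maximum count (all zeros when the matrix
#' is empty); `"linear"` is min-max scaling; `"log"` applies `log1p` then
#' min-max; `"robust"` centres by the median and scales by the IQR of all
#' pixels (quartiles with linear interpolation), then min-max rescales into
#' [0, 1].  A zero IQR falls back to linear scaling with a warning.
#'
#' @param m A `cgr_matrix` or numeric matrix of counts.
#' @param method One of `"robust"`, `"linear"`, `"log"`, `"none"`.
#' @return A matrix of class `cgr_image` with values in [0, 1] and
#'   attributes `method` (requested) and `method_used` (after any fallback).
#' @export
cgr_normalize <- function(m, method = c("robust", "linear", "log", "none")) {
  method <- match.arg(method)
  x <- unclass(m)
  used <- method
  px <- switch(method,
    none = if (max(x) == 0) array(0, dim = dim(x)) else x / max(x),
    linear = minmax01(x),
    log = minmax01(log1p(x)),
    robust = {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2L] - q[1L]
      if (iqr == 0) {
        warning("zero IQR in robust scaling; falling back to linear",
                call. = FALSE)
        used <- "linear"
        minmax01(x)
      } else {
        minmax01((x - stats::median(x)) / iqr)
      }
    }
  )
  px <- matrix(px, nrow = nrow(x))
  structure(px, class = c("cgr_image", class(px)),
            method = method, method_used = used,
            resolution = attr(m, "resolution") %||% nrow(x))
}

#' Export a normalized CGR image as an 8-bit greyscale PNG
#'
#' Pixel bytes are `round(255 * value)`; PNG is lossless so a read-back
#' reproduces them exactly.
#'
#' @param img A `cgr_image` (or numeric matrix with values in [0, 1]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cgr_png <- function(img, path) {
  px <- unclass(img)
  if (min(px) < 0 || max(px) > 1) {
    stop("image values must lie in [0, 1]; normalize first", call. = FALSE)
  }
  # quantize explicitly so the file contract (byte = round(255 * v)) does
  # not depend on the writer's rounding mode
  png::writePNG(matrix(as.integer(round(px * 255)) / 255, nrow = nrow(px)),
                target = path)
  invisible(path)
}
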