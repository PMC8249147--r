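## Multivariate dynamic time warping. The frame metric is Euclidean across
## channels; the step pattern is the symmetric {(1,0),(0,1),(1,1)} set with no
## slope constraint, so the distance is the unconstrained minimum cumulative
## frame distance over monotone boundary-respecting paths. Unequal lengths are
## supported. An optional Sakoe-Chiba band and an optional path-length
## normalization are exposed for speed and for length-independent kernel
## scaling; both default to off.

#' Euclidean frame distance
#'
#' Distance between two same-length channel vectors (one time frame each);
#' zero iff the frames are equal.
#'
#' @param a,b Numeric vectors of equal length (one value per channel).
#' @return Nonnegative scalar.
#' @export
frame_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_validation("frame dimension mismatch: %d vs %d", length(a), length(b))
  sqrt(sum((a - b)^2))
}

as_signal_values <- function(x) {
  if (inherits(x, "frbain_signal")) return(x$values)
  if (is.vector(x) && is.numeric(x)) return(matrix(x, ncol = 1))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop_validation("expected a signal, numeric vector or numeric matrix")
}

#' Dynamic time warping distance between two signals
#'
#' Computes the minimum cumulative Euclidean frame distance over all monotone
#' warping paths from (1,1) to (N,M) with steps down, right and diagonal, by
#' dynamic programming. Ties in backtracking prefer the diagonal step, so the
#' returned path is deterministic (the distance does not depend on the
#' tie-break).
#'
#' @param x,y Signals ([signal()]), numeric matrices (timepoints x channels)
#'   or numeric vectors (single channel). Channel counts must agree; lengths
#'   may differ.
#' @param normalize If `TRUE`, divide the cumulative distance by the warping
#'   path length.
#' @param band Optional Sakoe-Chiba band half-width (in frames, applied around
#'   the slope-adjusted diagonal); `NULL` disables windowing.
#' @param return_path If `FALSE`, only the distance is computed (two-row DP).
#' @return A list of class `frbain_dtw` with elements `distance` and `path`
#'   (a two-column matrix of 1-based index pairs, or `NULL`).
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))$distance
#' @export
dtw_distance <- function(x, y, normalize = FALSE, band = NULL,
                         return_path = TRUE) {
  xv <- as_signal_values(x)
  yv <- as_signal_values(y)
  if (ncol(xv) != ncol(yv))
    stop_validation("channel count mismatch: %d vs %d", ncol(xv), ncol(yv))
  want_path <- return_path || normalize
  r <- .cpp_dtw(xv, yv, if (is.null(band)) -1L else as.integer(band), want_path)
  if (normalize) r$distance <- r$distance / nrow(r$path)
  if (!return_path) r$path <- NULL
  structure(r, class = "frbain_dtw")
}

#' @export
print.frbain_dtw <- function(x, ...) {
  cat(sprintf("<dtw: distance %.6g%s>\n", x$distance,
              if (is.null(x$path)) "" else sprintf(", path length %d", nrow(x$path))))
  invisible(x)
}

#' Pairwise DTW distance matrix over a dataset
#'
#' Computes `dtw_distance` for every unordered pair of records and mirrors the
#' result; the diagonal is exactly zero.
#'
#' @param dataset A [signal_dataset()].
#' @param subset Optional integer indices of records to include.
#' @inheritParams dtw_distance
#' @return Symmetric numeric matrix with record ids as dimnames.
#' @export
distance_matrix <- function(dataset, subset = NULL, normalize = FALSE,
                            band = NULL) {
  if (!is.null(subset) && length(subset) == 0L)
    stop_validation("empty record subset")
  if (!is.null(subset)) dataset <- dataset_subset(dataset, subset)
  vals <- lapply(dataset$signals, `[[`, "values")
  D <- .cpp_dtw_matrix(vals, if (is.null(band)) -1L else as.integer(band),
                       normalize)
  diag(D) <- 0
  ids <- dataset_ids(dataset)
  dimnames(D) <- list(ids, ids)
  D
}

#' Cross DTW distances between a dataset and a set of reference signals
#'
#' @param dataset A [signal_dataset()].
#' @param refs List of reference signals (e.g. kernel centers).
#' @inheritParams dtw_distance
#' @return Numeric matrix, records in rows and references in columns.
#' @export
cross_distances <- function(dataset, refs, normalize = FALSE, band = NULL) {
  a <- lapply(dataset$signals, `[[`, "values")
  b <- lapply(refs, as_signal_values)
  nca <- ncol(a[[1]]); ncb <- unique(vapply(b, ncol, integer(1)))
  if (length(ncb) != 1L || ncb != nca)
    stop_validation("channel count mismatch between dataset and references")
  out <- .cpp_dtw_cross(a, b, if (is.null(band)) -1L else as.integer(band),
                        normalize)
  rownames(out) <- dataset_ids(dataset)
  out
}

validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop_validation("distance matrix must be square")
  if (any(!is.finite(D)) || any(D < 0))
    stop_validation("distance matrix must be finite and nonnegative")
  if (max(abs(D - t(D))) > 1e-8) stop_validation("distance matrix must be symmetric")
  invisible(D)
}
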