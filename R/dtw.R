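#' @include AllClasses.R
NULL

#' Dynamic time warping distance between two series
#'
#' Minimal cumulative cost over monotone warping paths under the
#' recurrence g(i,j) = d(q_i, c_j) + min(g(i-1,j-1), g(i-1,j), g(i,j-1))
#' with boundary g(1,1) = d(q_1, c_1). The local cost d is the absolute
#' difference |q_i - c_j| (the Euclidean distance between scalar
#' samples); a squared-difference variant is available.
#'
#' @param q,c numeric series (equal length not required).
#' @param squared use squared differences as the local cost.
#' @return the DTW distance (a non-negative scalar)
#' @examples
#' dtwDistance(c(0, 1, 1), c(0, 0, 1))  # 0: warping absorbs the shift
#' dtwDistance(c(0, 0), c(1, 1))        # 2
#' @export
dtwDistance <- function(q, c, squared = FALSE) {
  if (length(q) == 0L || length(c) == 0L) stop("empty series")
  .cpp_dtw(as.numeric(q), as.numeric(c), isTRUE(squared))
}

#' Optimal DTW warping path
#'
#' @inheritParams dtwDistance
#' @return integer matrix with columns (i, j): the aligned index pairs
#'   from (1,1) to (length(q), length(c))
#' @export
dtwPath <- function(q, c, squared = FALSE) {
  if (length(q) == 0L || length(c) == 0L) stop("empty series")
  .cpp_dtw_path(as.numeric(q), as.numeric(c), isTRUE(squared))
}

#' DTW distances between rows of two matrices
#'
#' @param X V x T matrix of series.
#' @param C k x T matrix of series.
#' @param squared use squared local cost.
#' @return V x k matrix of DTW distances
#' @export
dtwDistanceMatrix <- function(X, C, squared = FALSE) {
  .cpp_dtw_matrix(as.matrix(X), as.matrix(C), isTRUE(squared))
}
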