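#' @include AllClasses.R dtw.R
NULL

#' k-means clustering of TACs under dynamic time warping
#'
#' Lloyd-style iterations with DTW as the assignment distance and
#' DTW-barycenter averaging (DBA, bounded inner iterations) as the
#' centroid update; the best of \code{nInit} random restarts by inertia
#' is returned. Deterministic given \code{seed}.
#'
#' @param tacs a normalized \linkS4class{TACMatrix} (or plain matrix of
#'   z-normalized rows).
#' @param k number of centroids (1 <= k <= number of rows).
#' @param seed RNG seed for the restarts (mandatory for reproducibility).
#' @param nInit number of random restarts (default 10).
#' @param maxIter maximum Lloyd iterations per restart (default 50).
#' @param dbaIter inner DBA passes per centroid update (default 10).
#' @param squared use squared local DTW cost.
#' @param update centroid update rule: DBA (default) or cluster medoid.
#' @param initCentroids optional matrix of starting centroids used as an
#'   additional (warm-start) restart.
#' @return list with \code{centroids} (\linkS4class{CentroidSet},
#'   unlabeled), \code{assignment} (\linkS4class{VoxelAssignment}, labels
#'   are centroid row ids) and \code{inertia} (sum of DTW distances of
#'   each series to its centroid)
#' @export
kmeansDTW <- function(tacs, k, seed, nInit = 10, maxIter = 50, dbaIter = 10,
                      squared = FALSE, update = c("dba", "medoid"),
                      initCentroids = NULL) {
  update <- match.arg(update)
  X <- if (is(tacs, "TACMatrix")) {
    if (!isTRUE(tacs@normalized)) stop("TACs must be z-normalized first")
    tacs@values
  } else as.matrix(tacs)
  V <- nrow(X)
  if (k < 1L) stop("k must be at least 1")
  if (V < k) stop("fewer series (", V, ") than clusters (", k, ")")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  starts <- lapply(seq_len(nInit), function(i)
    X[sample.int(V, k), , drop = FALSE])
  if (!is.null(initCentroids))
    starts <- c(starts, list(as.matrix(initCentroids)))
  best <- NULL
  for (C0 in starts) {
    fit <- lloydDTW(X, C0, maxIter = maxIter, dbaIter = dbaIter,
                    squared = squared, update = update)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  cent <- new("CentroidSet", curves = best$centroids,
              semanticLabels = rep(NA_integer_, k),
              meta = list(k = k, seed = seed, nInit = nInit,
                          inertia = best$inertia, iterations = best$iter,
                          update = update, squared = squared))
  assign <- new("VoxelAssignment", labels = as.integer(best$labels),
                distances = best$dist)
  list(centroids = cent, assignment = assign, inertia = best$inertia)
}

lloydDTW <- function(X, C, maxIter, dbaIter, squared, update) {
  V <- nrow(X)
  k <- nrow(C)
  labels <- integer(V)
  for (iter in seq_len(maxIter)) {
    D <- .cpp_dtw_matrix(X, C, squared)
    newLabels <- max.col(-D, ties.method = "first")
    # reseed empty clusters to the farthest point
    for (j in seq_len(k)) {
      if (!any(newLabels == j)) {
        far <- which.max(D[cbind(seq_len(V), newLabels)])
        newLabels[far] <- j
        C[j, ] <- X[far, ]
      }
    }
    if (identical(newLabels, labels)) break
    labels <- newLabels
    for (j in seq_len(k)) {
      rows <- X[labels == j, , drop = FALSE]
      C[j, ] <- if (update == "dba") dbaCentroid(rows, C[j, ], dbaIter,
                                                 squared)
                else medoidCentroid(rows, squared)
    }
  }
  D <- .cpp_dtw_matrix(X, C, squared)
  labels <- max.col(-D, ties.method = "first")
  dist <- D[cbind(seq_len(V), labels)]
  list(centroids = C, labels = labels, dist = dist, inertia = sum(dist),
       iter = iter)
}

# DBA: iteratively align members to the centroid and average the samples
# mapped onto each centroid index; initialized from the Euclidean mean.
dbaCentroid <- function(rows, current, dbaIter, squared) {
  if (nrow(rows) == 0L) return(current)
  cen <- colMeans(rows)
  for (i in seq_len(dbaIter)) {
    nxt <- .cpp_dba_update(rows, cen, squared)
    if (max(abs(nxt - cen)) < 1e-10) { cen <- nxt; break }
    cen <- nxt
  }
  cen
}

medoidCentroid <- function(rows, squared) {
  D <- .cpp_dtw_matrix(rows, rows, squared)
  rows[which.min(rowSums(D)), ]
}

#' SSE-versus-k profile for the elbow method
#'
#' Runs DTW k-means for k = 1..kMax and records, for each k, the sum of
#' squared Euclidean errors between each TAC and the nearest trained
#' centroid (nearest by Euclidean distance, matching the final
#' voxel-assignment rule). Each k is additionally warm-started from the
#' previous k's centroids plus the point farthest from them, which keeps
#' the profile non-increasing in k.
#'
#' @inheritParams kmeansDTW
#' @param kMax largest k scanned (default 8).
#' @return an \linkS4class{ElbowProfile}
#' @export
elbowProfile <- function(tacs, kMax = 8, seed, nInit = 10, maxIter = 50,
                         dbaIter = 10, squared = FALSE) {
  X <- if (is(tacs, "TACMatrix")) {
    if (!isTRUE(tacs@normalized)) stop("TACs must be z-normalized first")
    tacs@values
  } else as.matrix(tacs)
  if (kMax < 2L) stop("kMax must be at least 2")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  sse <- numeric(kMax)
  prev <- NULL
  for (k in seq_len(kMax)) {
    warm <- if (is.null(prev)) NULL else {
      d2 <- euclidSqDist(X, prev)
      rbind(prev, X[which.max(apply(d2, 1L, min)), ])
    }
    fit <- kmeansDTW(X, k, seed = seed + k, nInit = nInit,
                     maxIter = maxIter, dbaIter = dbaIter,
                     squared = squared, initCentroids = warm)
    C <- centroidCurves(fit$centroids)
    sse[k] <- sum(apply(euclidSqDist(X, C), 1L, min))
    prev <- C
  }
  new("ElbowProfile", k = seq_len(kMax), sse = sse)
}

euclidSqDist <- function(X, C) {
  # |x|^2 - 2 x.c + |c|^2, V x k
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

#' Select k at the elbow of the SSE profile
#'
#' The elbow is the k at which the SSE stops decreasing abruptly: the
#' point of maximum deviation below the chord joining the first and
#' last points of the SSE-versus-k curve (the knee-point rule). This is
#' the k ending the run of large drops, after which extra clusters only
#' shave noise.
#'
#' @param profile an \linkS4class{ElbowProfile}
#' @return the selected k (integer)
#' @export
selectElbowK <- function(profile) {
  stopifnot(is(profile, "ElbowProfile"))
  k <- profile@k; sse <- profile@sse
  if (length(sse) < 3L) stop("profile needs at least three k values")
  n <- length(k)
  chord <- sse[1L] + (sse[n] - sse[1L]) * (k - k[1L]) / (k[n] - k[1L])
  k[which.max(chord - sse)]
}

#' Assign TACs to fixed centroids by Euclidean distance
#'
#' The final per-voxel classification uses plain Euclidean distance to
#' the frozen centroid curves (not DTW). Ties are broken toward the
#' lowest semantic label (or lowest row index when unlabeled).
#'
#' @param tacs a normalized \linkS4class{TACMatrix} or matrix.
#' @param centroids a \linkS4class{CentroidSet}; when labeled, returned
#'   labels are semantic labels.
#' @return a \linkS4class{VoxelAssignment}
#' @export
assignToCentroids <- function(tacs, centroids) {
  stopifnot(is(centroids, "CentroidSet"))
  X <- if (is(tacs, "TACMatrix")) {
    if (!isTRUE(tacs@normalized)) stop("TACs must be z-normalized first")
    tacs@values
  } else as.matrix(tacs)
  C <- centroidCurves(centroids)
  if (ncol(X) != ncol(C))
    stop("TAC length (", ncol(X), ") does not match centroid length (",
         ncol(C), ")")
  lab <- semanticLabels(centroids)
  ord <- if (all(is.na(lab))) seq_len(nrow(C)) else order(lab)
  D <- sqrt(pmax(euclidSqDist(X, C[ord, , drop = FALSE]), 0))
  win <- max.col(-D, ties.method = "first")   # first = lowest label
  dist <- D[cbind(seq_len(nrow(X)), win)]
  outLab <- if (all(is.na(lab))) ord[win] else lab[ord][win]
  new("VoxelAssignment", labels = as.integer(outLab), distances = dist)
}

#' Attach semantic labels #1/#2/#3 to a 3-centroid model
#'
#' Fits an ordinary-least-squares slope to the late phase (20--50 min)
#' of each centroid curve and labels #1 = most positive late slope
#' (slowly increasing), #3 = most negative (rapid washout), #2 = the
#' remaining curve. Exact late-slope ties are broken by the early
#' (0--15 min) slope: the flatter early rise wins the lower label.
#'
#' @param centroids a \linkS4class{CentroidSet} with k = 3.
#' @param schedule the \linkS4class{FrameSchedule} the curves live on.
#' @param lateWindow,earlyWindow minutes, the slope windows.
#' @return the labeled \linkS4class{CentroidSet}
#' @export
labelCentroids <- function(centroids, schedule = defaultSchedule(),
                           lateWindow = c(20, 50), earlyWindow = c(0, 15)) {
  stopifnot(is(centroids, "CentroidSet"))
  C <- centroidCurves(centroids)
  if (nrow(C) != 3L)
    stop("semantic labels are only defined for the 3-centroid model")
  late <- apply(C, 1L, curveSlope, schedule = schedule, window = lateWindow)
  early <- apply(C, 1L, curveSlope, schedule = schedule,
                 window = earlyWindow)
  # rank by late slope (desc); ties -> flatter early rise wins #1
  ord <- order(-late, abs(early))
  lab <- integer(3L)
  lab[ord] <- 1:3
  new("CentroidSet", curves = C, semanticLabels = lab,
      meta = c(centroids@meta,
               list(lateSlopes = late, earlySlopes = early)))
}

# OLS slope of a curve over frames whose start time is in [window), per
# hour of frame mid-time.
curveSlope <- function(curve, schedule, window) {
  st <- frameStarts(schedule)
  sel <- which(st >= window[1L] & st < window[2L])
  if (length(sel) < 2L)
    stop("fewer than 2 frames start within [", window[1L], ",",
         window[2L], ")")
  tHours <- frameMids(schedule)[sel] / 60
  unname(coef(lm(curve[sel] ~ tHours))[2L])
}
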