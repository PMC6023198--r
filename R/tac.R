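#' @include AllClasses.R constructors.R
NULL

#' Extract per-voxel time-activity curves under a mask
#'
#' @param img a \linkS4class{DynamicImage}
#' @param mask a \linkS4class{TumorMask} with matching geometry.
#' @return a raw-scale \linkS4class{TACMatrix}, one row per foreground
#'   voxel
#' @export
extractTACs <- function(img, mask) {
  stopifnot(is(img, "DynamicImage"), is(mask, "TumorMask"))
  if (!identical(dim(img@voxels)[1:3], dim(mask@voxels)))
    stop("mask geometry does not match image")
  idx <- which(mask@voxels)
  if (length(idx) == 0L) stop("non-segmentable: empty tumor mask")
  nT <- nFrames(img)
  flat <- matrix(img@voxels, ncol = nT)
  new("TACMatrix", values = flat[idx, , drop = FALSE],
      coords = arrayInd(idx, dim(mask@voxels)),
      normalized = FALSE, nDropped = 0L)
}

#' Rowwise z-normalization of TACs
#'
#' Each curve T becomes (T - mean(T)) / sd(T) with the population SD
#' (denominator n), so every retained row has mean 0 and SD 1.
#' Zero-variance rows cannot be normalized; they are dropped and the
#' count is recorded in the result and reported via a message.
#'
#' @param tacs a raw \linkS4class{TACMatrix}
#' @param tol variance tolerance below which a row counts as constant.
#' @return a normalized \linkS4class{TACMatrix}
#' @export
znormalizeTACs <- function(tacs, tol = 1e-12) {
  stopifnot(is(tacs, "TACMatrix"))
  if (isTRUE(tacs@normalized)) stop("TACs are already normalized")
  x <- tacs@values
  m <- rowMeans(x)
  s <- sqrt(rowMeans(sweep(x, 1L, m)^2))
  keep <- s > tol
  nDrop <- sum(!keep)
  if (all(!keep)) stop("all TACs have zero variance")
  if (nDrop > 0L)
    message(nDrop, " zero-variance TAC(s) dropped before normalization")
  z <- sweep(sweep(x[keep, , drop = FALSE], 1L, m[keep]), 1L, s[keep], `/`)
  new("TACMatrix", values = z, coords = tacs@coords[keep, , drop = FALSE],
      normalized = TRUE, nDropped = as.integer(nDrop))
}

#' z-normalize a single curve (population SD)
#' @param x numeric vector
#' @return normalized vector
#' @export
znormalize <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero-variance series cannot be z-normalized")
  (x - mean(x)) / s
}

#' Mean tumor TAC (raw SUV scale)
#'
#' Mask-average SUV per frame; the tumor-level curve used for the
#' conventional kinetic parameters (TTP, late slope).
#'
#' @param img a \linkS4class{DynamicImage}
#' @param mask a \linkS4class{TumorMask}
#' @return numeric vector of length \code{nFrames(img)}
#' @export
meanTAC <- function(img, mask) {
  tacs <- extractTACs(img, mask)
  colMeans(tacs@values)
}
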