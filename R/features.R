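#' @include AllClasses.R cluster.R tac.R segmentation.R
NULL

#' Centroid proportions of a tumor
#'
#' Percentage of tumor voxels assigned to each of the three semantic
#' centroids.
#'
#' @param assign a \linkS4class{VoxelAssignment} whose labels are
#'   semantic labels 1..3 (see \code{\link{assignToCentroids}} with a
#'   labeled centroid set).
#' @return named numeric: \code{pct_c1}, \code{pct_c2}, \code{pct_c3},
#'   summing to 100 exactly
#' @export
centroidProportions <- function(assign) {
  stopifnot(is(assign, "VoxelAssignment"))
  V <- length(assign@labels)
  if (V == 0L) stop("no voxels assigned")
  if (any(!assign@labels %in% 1:3))
    stop("semantic labels 1..3 required (k = 3 model)")
  counts <- tabulate(assign@labels, nbins = 3L)
  setNames(100 * counts / V, c("pct_c1", "pct_c2", "pct_c3"))
}

#' Tumor SUVmax and SUVmean
#'
#' Maximum and mean SUV over the mask voxels of the late static image.
#' A \linkS4class{DynamicImage} is first reduced to its 40--50 min
#' static image.
#'
#' @param img a \linkS4class{StaticImage} or \linkS4class{DynamicImage}.
#' @param mask a non-empty \linkS4class{TumorMask}.
#' @param window static window when \code{img} is dynamic.
#' @return named numeric: \code{suv_max}, \code{suv_mean}
#' @export
tumorSUV <- function(img, mask, window = c(40, 50)) {
  if (is(img, "DynamicImage")) img <- staticFromDynamic(img, window)
  stopifnot(is(img, "StaticImage"), is(mask, "TumorMask"))
  if (!identical(dim(img@voxels), dim(mask@voxels)))
    stop("mask geometry does not match image")
  vals <- img@voxels[mask@voxels]
  if (length(vals) == 0L) stop("empty tumor mask")
  c(suv_max = max(vals), suv_mean = mean(vals))
}

#' Tumor-to-brain ratios
#'
#' Tumor SUVmax and SUVmean divided by the mean SUV of a contralateral
#' normal-brain reference region.
#'
#' @param suvMax,suvMean tumor SUV statistics.
#' @param refMean mean SUV of the reference region (> 0).
#' @return named numeric: \code{tbr_max}, \code{tbr_mean}
#' @export
tbr <- function(suvMax, suvMean, refMean) {
  if (!is.finite(refMean) || refMean <= 0)
    stop("reference mean SUV must be positive")
  c(tbr_max = unname(suvMax) / refMean, tbr_mean = unname(suvMean) / refMean)
}

#' Time to peak of the tumor mean TAC
#'
#' Minutes from the start of the acquisition to the frame holding the
#' maximum SUV, reported as that frame's start time (first occurrence on
#' ties). On the default 10 x 5 min protocol the possible values are
#' 0, 5, ..., 45 min.
#'
#' @param meanTac tumor mean TAC on the raw SUV scale.
#' @param schedule the acquisition \linkS4class{FrameSchedule}.
#' @return TTP in minutes
#' @export
timeToPeak <- function(meanTac, schedule = defaultSchedule()) {
  if (length(meanTac) != nFrames(schedule))
    stop("TAC length does not match schedule")
  frameStarts(schedule)[which.max(meanTac)]
}

#' Late-phase slope of the tumor mean TAC
#'
#' Ordinary-least-squares slope of SUV against frame mid-time over the
#' late window (default 20--50 min post-injection), expressed in
#' SUV/hour.
#'
#' @param meanTac tumor mean TAC, raw SUV scale.
#' @param schedule the acquisition \linkS4class{FrameSchedule}.
#' @param window minutes; frames starting in [window) are fit.
#' @return slope in SUV/hour
#' @export
lateSlope <- function(meanTac, schedule = defaultSchedule(),
                      window = c(20, 50)) {
  if (length(meanTac) != nFrames(schedule))
    stop("TAC length does not match schedule")
  curveSlope(meanTac, schedule, window)
}

#' Automatic contralateral reference mask
#'
#' Fallback when no reference-region mask is supplied: mirror the tumor
#' mask across the midline of the first axis and erode it once, a crude
#' stand-in for a manually drawn crescent ROI in the unaffected
#' hemisphere. Voxels overlapping the tumor are excluded.
#'
#' @param mask the tumor \linkS4class{TumorMask}.
#' @param erode erosion passes (6-connected), default 1.
#' @return a \linkS4class{TumorMask}-shaped reference mask
#' @export
referenceMaskFromTumor <- function(mask, erode = 1) {
  stopifnot(is(mask, "TumorMask"))
  m <- mask@voxels
  mir <- m[dim(m)[1L]:1L, , , drop = FALSE]
  for (i in seq_len(erode)) mir <- !dilate6(!mir, 1L)
  mir <- mir & !m
  tumorMask(mir, voxelSize = mask@voxelSize,
            params = list(derived = "mirrored tumor mask", erode = erode))
}

#' Assemble one patient's feature record
#'
#' @param patientId identifier.
#' @param proportions named centroid percentages (pct_c1..pct_c3); must
#'   sum to 100 within 0.1 (rounding tolerance).
#' @param suv named \code{suv_max}/\code{suv_mean} (optional).
#' @param tbrValues named \code{tbr_max}/\code{tbr_mean} (optional; NA
#'   when no reference region is available).
#' @param ttp TTP in minutes.
#' @param slope late slope, SUV/hour.
#' @param idh1Mutant logical or NA.
#' @param survival optional named list/vector with pfs_months, pfs_event,
#'   os_months, os_event.
#' @return one-row data.frame
#' @export
buildFeatureRecord <- function(patientId, proportions, suv = NULL,
                               tbrValues = NULL, ttp = NA_real_,
                               slope = NA_real_, idh1Mutant = NA,
                               survival = NULL) {
  s <- sum(proportions)
  if (abs(s - 100) > 0.1)
    stop("centroid proportions sum to ", format(s), ", not 100 (+/- 0.1)")
  rec <- data.frame(
    id = patientId,
    pct_c1 = unname(proportions[["pct_c1"]]),
    pct_c2 = unname(proportions[["pct_c2"]]),
    pct_c3 = unname(proportions[["pct_c3"]]),
    suv_max = if (is.null(suv)) NA_real_ else unname(suv[["suv_max"]]),
    suv_mean = if (is.null(suv)) NA_real_ else unname(suv[["suv_mean"]]),
    tbr_max = if (is.null(tbrValues)) NA_real_
              else unname(tbrValues[["tbr_max"]]),
    tbr_mean = if (is.null(tbrValues)) NA_real_
               else unname(tbrValues[["tbr_mean"]]),
    ttp_min = ttp, slope_suv_h = slope,
    idh1_mutant = idh1Mutant,
    stringsAsFactors = FALSE)
  if (!is.null(survival))
    for (f in c("pfs_months", "pfs_event", "os_months", "os_event"))
      rec[[f]] <- if (is.null(survival[[f]])) NA_real_
                  else as.numeric(survival[[f]])
  rec
}
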