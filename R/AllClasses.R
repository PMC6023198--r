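#' @include fetclust-package.R
NULL

#' Frame timing of a dynamic PET acquisition
#'
#' Start times and durations (minutes) of each frame of a dynamic
#' acquisition. The default clinical protocol is 10 frames of 5 minutes
#' spanning 0--50 min post-injection.
#'
#' @slot start numeric, frame start times in minutes, strictly increasing.
#' @slot duration numeric, frame durations in minutes, all positive.
#' @slot allowGaps logical; when \code{FALSE} (default) frames must be
#'   contiguous (\code{start[i+1] == start[i] + duration[i]}).
#' @exportClass FrameSchedule
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric",
                 allowGaps = "logical"),
  prototype(allowGaps = FALSE))

setValidity("FrameSchedule", function(object) {
  s <- object@start; d <- object@duration
  if (length(s) == 0L) return("schedule must have at least one frame")
  if (length(s) != length(d)) return("start and duration lengths differ")
  if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite timing")
  if (any(d <= 0)) return("durations must be positive")
  if (length(s) > 1L && any(diff(s) <= 0))
    return("start times must be strictly increasing")
  if (!object@allowGaps && length(s) > 1L &&
      any(abs(s[-1L] - (s[-length(s)] + d[-length(d)])) > 1e-8))
    return("frames are not contiguous (set allowGaps = TRUE to permit)")
  TRUE
})

#' 4D dynamic PET image in SUV units
#'
#' @slot voxels 4D numeric array (x, y, z, frame), SUV (g/ml).
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot schedule a \linkS4class{FrameSchedule} whose length equals the
#'   number of frames.
#' @exportClass DynamicImage
setClass("DynamicImage",
  representation(voxels = "array", voxelSize = "numeric",
                 schedule = "FrameSchedule"))

setValidity("DynamicImage", function(object) {
  dm <- dim(object@voxels)
  if (length(dm) != 4L) return("voxels must be a 4D array")
  if (dm[4L] != length(object@schedule@start))
    return("frame count does not match schedule length")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive lengths in mm")
  if (any(!is.finite(object@voxels))) return("non-finite voxel values")
  if (any(object@voxels < 0)) return("SUV values must be non-negative")
  TRUE
})

#' Static (summed late-window) PET image
#'
#' Voxelwise mean SUV over a late time window, conventionally 40--50 min
#' post-injection.
#'
#' @slot voxels 3D numeric array, SUV.
#' @slot voxelSize numeric length-3, mm.
#' @slot window numeric length-2, the time window (minutes) the image
#'   summarises.
#' @exportClass StaticImage
setClass("StaticImage",
  representation(voxels = "array", voxelSize = "numeric",
                 window = "numeric"))

setValidity("StaticImage", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (length(object@window) != 2L || object@window[1L] >= object@window[2L])
    return("window must be (start, end) with start < end")
  TRUE
})

#' Normal-brain uptake template
#'
#' Voxelwise mean and standard deviation of static SUV images from a
#' population of visually normal scans; the denominator of patient
#' Z-score maps.
#'
#' @slot meanVol,sdVol 3D numeric arrays of identical dimensions.
#' @slot voxelSize numeric length-3, mm.
#' @slot nSubjects number of scans averaged (at least 2).
#' @exportClass NormalTemplate
setClass("NormalTemplate",
  representation(meanVol = "array", sdVol = "array", voxelSize = "numeric",
                 nSubjects = "integer"))

setValidity("NormalTemplate", function(object) {
  if (!identical(dim(object@meanVol), dim(object@sdVol)))
    return("mean and SD volumes have different dimensions")
  if (length(dim(object@meanVol)) != 3L) return("volumes must be 3D")
  if (any(object@sdVol < 0)) return("SD volume must be non-negative")
  if (object@nSubjects < 2L) return("template needs at least 2 subjects")
  TRUE
})

#' Binary tumor mask with segmentation provenance
#'
#' @slot voxels 3D logical array.
#' @slot voxelSize numeric length-3, mm.
#' @slot params named list recording the segmentation parameters
#'   (\code{zThreshold}, \code{minClusterVoxels}, \code{dilationIterations},
#'   \code{connectivity}) and a \code{nonSegmentable} flag for empty masks.
#' @exportClass TumorMask
setClass("TumorMask",
  representation(voxels = "array", voxelSize = "numeric", params = "list"))

setValidity("TumorMask", function(object) {
  if (length(dim(object@voxels)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@voxels)) return("mask voxels must be logical")
  TRUE
})

#' Matrix of per-voxel time-activity curves
#'
#' @slot values V x T numeric matrix, one row per tumor voxel.
#' @slot coords V x 3 integer matrix of voxel indices.
#' @slot normalized logical; \code{TRUE} after rowwise z-normalization.
#' @slot nDropped number of zero-variance rows removed at normalization.
#' @exportClass TACMatrix
setClass("TACMatrix",
  representation(values = "matrix", coords = "matrix",
                 normalized = "logical", nDropped = "integer"),
  prototype(normalized = FALSE, nDropped = 0L))

setValidity("TACMatrix", function(object) {
  if (nrow(object@values) != nrow(object@coords))
    return("values and coords row counts differ")
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (any(!is.finite(object@values))) return("non-finite TAC values")
  if (isTRUE(object@normalized) && nrow(object@values) > 0L) {
    m <- rowMeans(object@values)
    s <- sqrt(rowMeans(sweep(object@values, 1L, m)^2))
    if (any(abs(m) > 1e-6) || any(abs(s - 1) > 1e-6))
      return("normalized rows must have mean 0 and SD 1 within 1e-6")
  }
  TRUE
})

#' Learned TAC centroids
#'
#' k centroid curves on the z-normalized scale. For the canonical k = 3
#' model the rows carry semantic labels: #1 slowly increasing, #2 rapid
#' rise then slow decline, #3 rapid rise then rapid decline.
#'
#' @slot curves k x T numeric matrix.
#' @slot semanticLabels integer vector of length k mapping each row to a
#'   semantic label in 1..k, or NA before labeling.
#' @slot meta list of training metadata (k, seed, nInit, inertia).
#' @exportClass CentroidSet
setClass("CentroidSet",
  representation(curves = "matrix", semanticLabels = "integer",
                 meta = "list"))

setValidity("CentroidSet", function(object) {
  k <- nrow(object@curves)
  if (length(object@semanticLabels) != k)
    return("one semantic label (possibly NA) per centroid required")
  lb <- object@semanticLabels
  if (!all(is.na(lb))) {
    if (any(is.na(lb)) || !setequal(lb, seq_len(k)))
      return("semantic labels must be a bijection onto 1..k")
  }
  TRUE
})

#' Assignment of voxels to centroids
#'
#' @slot labels integer vector, winning centroid per voxel (semantic
#'   label when the centroid set is labeled).
#' @slot distances numeric vector, distance to the winning centroid.
#' @exportClass VoxelAssignment
setClass("VoxelAssignment",
  representation(labels = "integer", distances = "numeric"))

setValidity("VoxelAssignment", function(object) {
  if (length(object@labels) != length(object@distances))
    return("labels and distances lengths differ")
  if (length(object@labels) && any(object@labels < 1L))
    return("labels must be positive centroid ids")
  if (length(object@distances) && any(object@distances < -1e-12))
    return("distances must be non-negative")
  TRUE
})

#' SSE-versus-k profile for elbow model selection
#'
#' @slot k integer vector of candidate cluster counts.
#' @slot sse numeric vector, within-cluster sum of squared (Euclidean)
#'   errors at each k.
#' @exportClass ElbowProfile
setClass("ElbowProfile",
  representation(k = "integer", sse = "numeric"))

setValidity("ElbowProfile", function(object) {
  if (length(object@k) != length(object@sse)) return("k and sse lengths differ")
  if (any(object@sse < 0)) return("SSE must be non-negative")
  TRUE
})
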