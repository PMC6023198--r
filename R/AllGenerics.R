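#' @include AllClasses.R
NULL

#' Number of frames
#' @param x a FrameSchedule or DynamicImage
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame start times (minutes)
#' @param x a FrameSchedule or DynamicImage
#' @return numeric vector
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' Frame durations (minutes)
#' @param x a FrameSchedule or DynamicImage
#' @return numeric vector
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' Frame mid-times (minutes)
#' @param x a FrameSchedule or DynamicImage
#' @return numeric vector
#' @export
setGeneric("frameMids", function(x) standardGeneric("frameMids"))

#' Voxel dimensions in mm
#' @param x an image-like object
#' @return numeric length-3
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Raw voxel data
#' @param x an image-like object
#' @return the underlying array / matrix
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Acquisition schedule
#' @param x a DynamicImage
#' @return a FrameSchedule
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' Centroid curves
#' @param x a CentroidSet
#' @return k x T numeric matrix
#' @export
setGeneric("centroidCurves", function(x) standardGeneric("centroidCurves"))

#' Semantic centroid labels
#' @param x a CentroidSet
#' @return integer vector (NA when unlabeled)
#' @export
setGeneric("semanticLabels", function(x) standardGeneric("semanticLabels"))

#' Per-voxel cluster labels
#' @param x a VoxelAssignment
#' @return integer vector
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

# ---- methods -------------------------------------------------------------

#' @rdname nFrames
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))
#' @rdname nFrames
setMethod("nFrames", "DynamicImage", function(x) nFrames(x@schedule))

#' @rdname frameStarts
setMethod("frameStarts", "FrameSchedule", function(x) x@start)
#' @rdname frameStarts
setMethod("frameStarts", "DynamicImage", function(x) x@schedule@start)

#' @rdname frameDurations
setMethod("frameDurations", "FrameSchedule", function(x) x@duration)
#' @rdname frameDurations
setMethod("frameDurations", "DynamicImage", function(x) x@schedule@duration)

#' @rdname frameMids
setMethod("frameMids", "FrameSchedule", function(x) x@start + x@duration / 2)
#' @rdname frameMids
setMethod("frameMids", "DynamicImage", function(x) frameMids(x@schedule))

#' @rdname voxelSize
setMethod("voxelSize", "DynamicImage", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "StaticImage", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "TumorMask", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "NormalTemplate", function(x) x@voxelSize)

#' @rdname voxelData
setMethod("voxelData", "DynamicImage", function(x) x@voxels)
#' @rdname voxelData
setMethod("voxelData", "StaticImage", function(x) x@voxels)
#' @rdname voxelData
setMethod("voxelData", "TumorMask", function(x) x@voxels)
#' @rdname voxelData
setMethod("voxelData", "TACMatrix", function(x) x@values)

#' @rdname schedule
setMethod("schedule", "DynamicImage", function(x) x@schedule)

#' @rdname centroidCurves
setMethod("centroidCurves", "CentroidSet", function(x) x@curves)

#' @rdname semanticLabels
setMethod("semanticLabels", "CentroidSet", function(x) x@semanticLabels)

#' @rdname clusterLabels
setMethod("clusterLabels", "VoxelAssignment", function(x) x@labels)

# ---- show ----------------------------------------------------------------

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %g-%g min\n", nFrames(object),
              object@start[1L],
              object@start[length(object@start)] +
                object@duration[length(object@duration)]))
})

setMethod("show", "DynamicImage", function(object) {
  dm <- dim(object@voxels)
  cat(sprintf("DynamicImage: %dx%dx%d voxels x %d frames, voxel %sx%sx%s mm\n",
              dm[1], dm[2], dm[3], dm[4],
              format(object@voxelSize[1]), format(object@voxelSize[2]),
              format(object@voxelSize[3])))
  show(object@schedule)
})

setMethod("show", "StaticImage", function(object) {
  dm <- dim(object@voxels)
  cat(sprintf("StaticImage: %dx%dx%d voxels, window %g-%g min\n",
              dm[1], dm[2], dm[3], object@window[1], object@window[2]))
})

setMethod("show", "NormalTemplate", function(object) {
  dm <- dim(object@meanVol)
  cat(sprintf("NormalTemplate: %dx%dx%d voxels from %d subjects\n",
              dm[1], dm[2], dm[3], object@nSubjects))
})

setMethod("show", "TumorMask", function(object) {
  cat(sprintf("TumorMask: %d foreground voxels%s\n", sum(object@voxels),
              if (isTRUE(object@params$nonSegmentable)) " (non-segmentable)"
              else ""))
})

setMethod("show", "TACMatrix", function(object) {
  cat(sprintf("TACMatrix: %d voxels x %d frames (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@normalized) "z-normalized" else "raw SUV"))
})

setMethod("show", "CentroidSet", function(object) {
  k <- nrow(object@curves)
  lab <- if (all(is.na(object@semanticLabels))) "unlabeled"
         else paste0("#", object@semanticLabels, collapse = " ")
  cat(sprintf("CentroidSet: k = %d, %d frames, labels: %s\n",
              k, ncol(object@curves), lab))
})

setMethod("show", "VoxelAssignment", function(object) {
  tb <- table(object@labels)
  cat("VoxelAssignment:", length(object@labels), "voxels;",
      paste(sprintf("c%s=%d", names(tb), as.integer(tb)), collapse = " "),
      "\n")
})

setMethod("show", "ElbowProfile", function(object) {
  cat("ElbowProfile: k =", paste(object@k, collapse = ","), "\n")
  cat("  SSE:", paste(signif(object@sse, 4), collapse = ", "), "\n")
})
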