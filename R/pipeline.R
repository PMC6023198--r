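#' @include AllClasses.R segmentation.R tac.R cluster.R features.R
NULL

#' Pipeline configuration with the standard clinical defaults
#'
#' All tunables of the analysis with their standard values: Z-score
#' threshold 2.5, minimum component size 250 voxels, 2 dilation passes,
#' 8 mm FWHM smoothing, k = 3 centroids (elbow scan up to k = 8), 10
#' k-means restarts, static window 40--50 min, late-slope window
#' 20--50 min.
#'
#' @param zThreshold voxel-level Z threshold.
#' @param minClusterVoxels minimum connected-component size.
#' @param dilationIterations mask dilation passes.
#' @param fwhmMm Gaussian smoothing FWHM, mm.
#' @param smoothDynamic also smooth every dynamic frame before TAC
#'   extraction (default TRUE), not only the static image.
#' @param k number of centroids.
#' @param kMax elbow scan upper bound.
#' @param nInit k-means restarts.
#' @param seed RNG seed.
#' @param staticWindow minutes, late static window.
#' @param slopeWindow minutes, late-slope window.
#' @param connectivity component connectivity (6/18/26).
#' @param minGroupFrac cutpoint-scan group-size floor.
#' @return named list of parameters
#' @export
pipelineConfig <- function(zThreshold = 2.5, minClusterVoxels = 250,
                           dilationIterations = 2, fwhmMm = 8,
                           smoothDynamic = TRUE, k = 3, kMax = 8,
                           nInit = 10, seed = 17,
                           staticWindow = c(40, 50),
                           slopeWindow = c(20, 50), connectivity = 18,
                           minGroupFrac = 0.1) {
  list(zThreshold = zThreshold, minClusterVoxels = minClusterVoxels,
       dilationIterations = dilationIterations, fwhmMm = fwhmMm,
       smoothDynamic = smoothDynamic, k = k, kMax = kMax, nInit = nInit,
       seed = seed, staticWindow = staticWindow,
       slopeWindow = slopeWindow, connectivity = connectivity,
       minGroupFrac = minGroupFrac)
}

configFingerprint <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(js) * seq_len(nchar(js))) %% 0xFFFFFFFF)
}

#' Run the full voxel-clustering pipeline on a set of patients
#'
#' For each patient: late static image, 8 mm smoothing, Z-score map
#' against the template, tumor mask (threshold / component filter /
#' dilation); patients with empty masks are recorded as non-segmentable
#' and excluded. Voxel TACs of the remaining patients are z-normalized
#' and pooled to train the k = 3 DTW k-means centroids once (unless
#' frozen centroids are supplied); each patient's voxels are then
#' assigned to the labeled centroids by Euclidean distance and the
#' per-patient feature records are assembled.
#'
#' @param patients named list; each element is a list with an
#'   \code{image} (\linkS4class{DynamicImage}) and optionally
#'   \code{refMask} (reference-region \linkS4class{TumorMask}) and
#'   \code{idh1Mutant}.
#' @param template a \linkS4class{NormalTemplate}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param centroids optional frozen \linkS4class{CentroidSet}; when NULL
#'   the centroids are trained on the pooled tumor voxels.
#' @param outputDir optional directory; when given, features.csv,
#'   centroids.json, per-patient masks and a run log are written there.
#' @return list: \code{features} (data.frame), \code{centroids},
#'   \code{masks}, \code{assignments}, \code{nonSegmentable} (ids),
#'   \code{errors} (named list), \code{config}
#' @export
runPipeline <- function(patients, template, config = pipelineConfig(),
                        centroids = NULL, outputDir = NULL) {
  if (is.null(names(patients)))
    names(patients) <- as.character(seq_along(patients))
  masks <- list(); tacsZ <- list(); nonSeg <- character(0)
  errors <- list()
  for (id in names(patients)) {
    res <- tryCatch({
      p <- patients[[id]]
      img <- p$image
      static <- staticFromDynamic(img, config$staticWindow)
      sm <- smoothGaussian(static@voxels, config$fwhmMm, img@voxelSize)
      z <- zscoreMap(staticImage(sm, img@voxelSize, config$staticWindow),
                     template)
      mask <- makeTumorMask(z, config$zThreshold, config$minClusterVoxels,
                            config$dilationIterations,
                            config$connectivity, img@voxelSize)
      if (isTRUE(mask@params$nonSegmentable)) {
        nonSeg <- c(nonSeg, id)
      } else {
        workImg <- img
        if (isTRUE(config$smoothDynamic)) {
          vox <- img@voxels
          for (f in seq_len(nFrames(img)))
            vox[, , , f] <- smoothGaussian(vox[, , , f], config$fwhmMm,
                                           img@voxelSize)
          workImg <- dynamicImage(vox, img@voxelSize, img@schedule)
        }
        masks[[id]] <- mask
        tacsZ[[id]] <- znormalizeTACs(extractTACs(workImg, mask))
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[id]] <- res
  }
  if (length(tacsZ) == 0L)
    stop("no segmentable patients")
  if (is.null(centroids)) {
    pooled <- do.call(rbind, lapply(tacsZ, voxelData))
    fit <- kmeansDTW(pooled, config$k, seed = config$seed,
                     nInit = config$nInit)
    centroids <- labelCentroids(fit$centroids)
  }
  feats <- list(); assigns <- list()
  for (id in names(tacsZ)) {
    p <- patients[[id]]
    asg <- assignToCentroids(tacsZ[[id]], centroids)
    assigns[[id]] <- asg
    img <- p$image
    mask <- masks[[id]]
    suv <- tumorSUV(img, mask, config$staticWindow)
    refMask <- if (!is.null(p$refMask)) p$refMask
               else referenceMaskFromTumor(mask)
    tbrVals <- NULL
    if (any(refMask@voxels)) {
      refMean <- tumorSUV(img, refMask, config$staticWindow)[["suv_mean"]]
      if (refMean > 0) tbrVals <- tbr(suv[["suv_max"]], suv[["suv_mean"]],
                                      refMean)
    }
    mt <- meanTAC(img, mask)
    feats[[id]] <- buildFeatureRecord(
      id, centroidProportions(asg), suv = suv, tbrValues = tbrVals,
      ttp = timeToPeak(mt, img@schedule),
      slope = lateSlope(mt, img@schedule, config$slopeWindow),
      idh1Mutant = if (is.null(p$idh1Mutant)) NA else p$idh1Mutant)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  out <- list(features = features, centroids = centroids, masks = masks,
              assignments = assigns, nonSegmentable = nonSeg,
              errors = errors, config = config)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(features, file.path(outputDir, "features.csv"),
              row.names = FALSE)
    writeCentroids(centroids, file.path(outputDir, "centroids.json"))
    for (id in names(masks))
      writeMask(masks[[id]], file.path(outputDir,
                                       paste0("mask_", id, ".nii.gz")))
    jsonlite::write_json(
      list(config = config, configFingerprint = configFingerprint(config),
           nonSegmentable = nonSeg,
           errors = errors,
           nPatients = length(patients),
           nSegmented = length(masks)),
      file.path(outputDir, "run_log.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  }
  out
}
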