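#' @include AllClasses.R constructors.R
NULL

# Frame-timing sidecar: {"FrameTimesStart":[...],"FrameDuration":[...]} in
# minutes. NIfTI-1 has no standard slot for per-frame timing, so the
# sidecar is authoritative (BIDS-like convention).

#' Read a 4D dynamic PET volume with its frame-timing sidecar
#'
#' @param pathNifti path to a 4D NIfTI-1 file in SUV units.
#' @param pathSidecar path to a JSON sidecar declaring
#'   \code{FrameTimesStart} and \code{FrameDuration} in minutes.
#' @return a \linkS4class{DynamicImage}; voxel size is taken from the
#'   NIfTI header.
#' @export
readDynamic <- function(pathNifti, pathSidecar) {
  img <- RNifti::readNifti(pathNifti)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop("expected 4D NIfTI, got ", length(dim(arr)), "D")
  side <- jsonlite::read_json(pathSidecar, simplifyVector = TRUE)
  if (is.null(side$FrameTimesStart) || is.null(side$FrameDuration))
    stop("sidecar must declare FrameTimesStart and FrameDuration")
  sched <- frameSchedule(side$FrameTimesStart,
                         side$FrameDuration,
                         allowGaps = isTRUE(side$AllowGaps))
  if (nFrames(sched) != dim(arr)[4L])
    stop("frame-count mismatch: image has ", dim(arr)[4L],
         " frames, sidecar declares ", nFrames(sched))
  vs <- RNifti::pixdim(img)[1:3]
  dynamicImage(arr, voxelSize = vs, schedule = sched)
}

#' Write a dynamic PET volume and its frame-timing sidecar
#'
#' @param img a \linkS4class{DynamicImage}
#' @param pathNifti output NIfTI path (.nii or .nii.gz).
#' @param pathSidecar output JSON sidecar path.
#' @return invisibly, the NIfTI path
#' @export
writeDynamic <- function(img, pathNifti, pathSidecar) {
  stopifnot(is(img, "DynamicImage"))
  nii <- RNifti::asNifti(img@voxels)
  RNifti::pixdim(nii) <- c(img@voxelSize, frameDurations(img)[1L])
  RNifti::writeNifti(nii, pathNifti)
  jsonlite::write_json(
    list(FrameTimesStart = frameStarts(img),
         FrameDuration = frameDurations(img)),
    pathSidecar, digits = NA)
  invisible(pathNifti)
}

#' Read / write a 3D volume (template component, static image)
#'
#' @param path NIfTI path.
#' @return \code{readVolume}: list with \code{voxels} (3D array) and
#'   \code{voxelSize} (mm).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected 3D NIfTI, got ", length(dim(arr)), "D")
  list(voxels = arr, voxelSize = RNifti::pixdim(img)[1:3])
}

#' @rdname readVolume
#' @param voxels 3D numeric array.
#' @param voxelSize voxel edge lengths in mm.
#' @export
writeVolume <- function(voxels, path, voxelSize = c(2, 2, 2)) {
  nii <- RNifti::asNifti(voxels)
  RNifti::pixdim(nii) <- voxelSize
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a tumor mask with provenance
#'
#' The mask is written as a 0/1 NIfTI volume; segmentation parameters are
#' stored in a JSON sidecar next to the volume (same path with a .json
#' extension) so they survive the round trip.
#'
#' @param mask a \linkS4class{TumorMask}
#' @param path output NIfTI path.
#' @return invisibly, the path
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "TumorMask"))
  arr <- array(as.integer(mask@voxels), dim = dim(mask@voxels))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- mask@voxelSize
  RNifti::writeNifti(nii, path, datatype = "uint8")
  jsonlite::write_json(mask@params, maskSidecarPath(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a tumor mask written by \code{writeMask}
#'
#' @param path NIfTI path; the provenance sidecar is picked up when
#'   present.
#' @return a \linkS4class{TumorMask}
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected 3D mask")
  params <- list()
  sp <- maskSidecarPath(path)
  if (file.exists(sp))
    params <- jsonlite::read_json(sp, simplifyVector = TRUE)
  tumorMask(arr != 0, voxelSize = RNifti::pixdim(img)[1:3], params = params)
}

maskSidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a cohort feature table
#'
#' Expects the columns \code{id}, \code{histology}, \code{idh1} (coded
#' "+"/"-"), \code{who_grade}, the three centroid percentages
#' \code{pct_c1}, \code{pct_c2}, \code{pct_c3}, \code{suv_max},
#' \code{suv_mean}, \code{tbr_max}, \code{tbr_mean}, \code{ttp_min} and
#' \code{slope_suv_h}; optional survival columns \code{pfs_months},
#' \code{pfs_event}, \code{os_months}, \code{os_event}. A logical
#' \code{idh1_mutant} column is derived on load.
#'
#' @param path CSV path (RFC 4180, header row).
#' @return a validated data.frame, one row per patient
#' @export
readCohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("cohort table is empty")
  validateCohort(df)
}

validateCohort <- function(df) {
  need <- c("id", "idh1", "pct_c1", "pct_c2", "pct_c3",
            "suv_max", "suv_mean", "tbr_max", "tbr_mean",
            "ttp_min", "slope_suv_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing cohort columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate patient ids")
  for (col in c("pct_c1", "pct_c2", "pct_c3")) {
    v <- df[[col]]
    if (!is.numeric(v)) stop("non-numeric percentage column ", col)
    if (any(!is.finite(v)) || any(v < 0 | v > 100))
      stop("percentage outside [0,100] in column ", col)
  }
  if (!all(df$idh1 %in% c("+", "-", NA)))
    stop("idh1 must be coded '+' or '-'")
  df$idh1_mutant <- df$idh1 == "+"
  df
}

#' The packaged 37-patient glioma cohort
#'
#' Histopathological and PET features (centroid percentages, SUV, TBR,
#' TTP, late slope, IDH1 status) for the 37 segmentable patients of the
#' reference glioma cohort.
#'
#' @return a data.frame with 37 rows
#' @examples
#' co <- fetCohort()
#' table(co$idh1)
#' @export
fetCohort <- function() {
  readCohort(system.file("extdata", "fet_cohort.csv", package = "fetclust",
                         mustWork = TRUE))
}

#' Write / read centroid sets as JSON
#'
#' @param centroids a \linkS4class{CentroidSet}
#' @param path JSON path.
#' @return \code{readCentroids}: a \linkS4class{CentroidSet}
#' @export
writeCentroids <- function(centroids, path) {
  stopifnot(is(centroids, "CentroidSet"))
  jsonlite::write_json(
    list(curves = centroids@curves,
         semanticLabels = centroids@semanticLabels,
         meta = centroids@meta),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeCentroids
#' @export
readCentroids <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CentroidSet", curves = as.matrix(obj$curves),
      semanticLabels = as.integer(obj$semanticLabels),
      meta = as.list(obj$meta))
}
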