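#' @include AllClasses.R
NULL

#' Construct a frame schedule
#'
#' @param start frame start times in minutes.
#' @param duration frame durations in minutes; a scalar is recycled.
#' @param allowGaps permit non-contiguous frames.
#' @return a \linkS4class{FrameSchedule}
#' @examples
#' defaultSchedule()          # 10 x 5 min, 0-50 min
#' frameSchedule(c(0, 5, 10), 5)
#' @export
frameSchedule <- function(start, duration, allowGaps = FALSE) {
  new("FrameSchedule", start = as.numeric(start),
      duration = rep_len(as.numeric(duration), length(start)),
      allowGaps = isTRUE(allowGaps))
}

#' @rdname frameSchedule
#' @export
defaultSchedule <- function() frameSchedule(seq(0, 45, by = 5), 5)

#' Construct a dynamic PET image
#'
#' @param voxels 4D numeric array (x, y, z, frame) in SUV.
#' @param voxelSize voxel edge lengths in mm (length 3).
#' @param schedule a \linkS4class{FrameSchedule} matching the 4th
#'   dimension.
#' @return a \linkS4class{DynamicImage}
#' @export
dynamicImage <- function(voxels, voxelSize = c(2, 2, 2),
                         schedule = defaultSchedule()) {
  new("DynamicImage", voxels = voxels, voxelSize = as.numeric(voxelSize),
      schedule = schedule)
}

#' Construct a static PET image
#'
#' @param voxels 3D numeric array in SUV.
#' @param voxelSize voxel edge lengths in mm.
#' @param window the time window (minutes) the image summarises.
#' @return a \linkS4class{StaticImage}
#' @export
staticImage <- function(voxels, voxelSize = c(2, 2, 2), window = c(40, 50)) {
  new("StaticImage", voxels = voxels, voxelSize = as.numeric(voxelSize),
      window = as.numeric(window))
}

#' Construct a tumor mask
#'
#' @param voxels 3D logical array.
#' @param voxelSize voxel edge lengths in mm.
#' @param params provenance parameter list.
#' @return a \linkS4class{TumorMask}
#' @export
tumorMask <- function(voxels, voxelSize = c(2, 2, 2), params = list()) {
  storage.mode(voxels) <- "logical"
  new("TumorMask", voxels = voxels, voxelSize = as.numeric(voxelSize),
      params = params)
}

#' Volume of a mask in millilitres
#' @param mask a \linkS4class{TumorMask}
#' @return volume in mL
#' @export
maskVolumeMl <- function(mask) {
  stopifnot(is(mask, "TumorMask"))
  sum(mask@voxels) * prod(mask@voxelSize) / 1000
}
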