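#' @include AllClasses.R constructors.R
NULL

#' Late-window static image from a dynamic acquisition
#'
#' Voxelwise mean SUV over the frames whose start time falls in the
#' window (default 40--50 min post-injection). The mean, rather than the
#' literal sum, keeps the image in SUV units; Z-score maps and ratios are
#' unaffected by this scale choice.
#'
#' @param img a \linkS4class{DynamicImage}
#' @param window numeric (start, end) minutes; frames with
#'   \code{start >= window[1]} and \code{start < window[2]} are averaged.
#' @return a \linkS4class{StaticImage}
#' @export
staticFromDynamic <- function(img, window = c(40, 50)) {
  stopifnot(is(img, "DynamicImage"))
  sel <- which(frameStarts(img) >= window[1L] & frameStarts(img) < window[2L])
  if (length(sel) == 0L)
    stop("no frames start within [", window[1L], ",", window[2L], ")")
  vox <- img@voxels[, , , sel, drop = FALSE]
  m <- apply(vox, 1:3, mean)
  staticImage(m, voxelSize = img@voxelSize, window = window)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2))
#' per axis, converted to voxel units by the voxel size. Boundaries are
#' handled by reflection, so constant volumes are unchanged and total
#' intensity is conserved away from the edges.
#'
#' @param vol 3D numeric array.
#' @param fwhmMm full width at half maximum of the kernel, mm.
#' @param voxelSizeMm voxel edge lengths, mm (length 3 or scalar).
#' @return smoothed 3D array
#' @export
smoothGaussian <- function(vol, fwhmMm = 8, voxelSizeMm = c(2, 2, 2)) {
  if (!is.numeric(fwhmMm) || length(fwhmMm) != 1L || fwhmMm <= 0)
    stop("FWHM must be a positive scalar (mm)")
  stopifnot(length(dim(vol)) == 3L)
  voxelSizeMm <- rep_len(voxelSizeMm, 3L)
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
  out <- vol
  for (ax in 1:3) out <- convolveAxisGaussian(out, sigmaVox[ax], ax)
  out
}

#' @rdname smoothGaussian
#' @export
fwhmToSigma <- function(fwhmMm, voxelSizeMm = 1) {
  fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
}

# 1D Gaussian convolution along axis `ax` with reflecting boundaries.
convolveAxisGaussian <- function(vol, sigma, ax) {
  n <- dim(vol)[ax]
  if (sigma <= 0 || n == 1L) return(vol)
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  perm <- c(ax, setdiff(1:3, ax))
  x <- aperm(vol, perm)
  dmx <- dim(x)
  dim(x) <- c(dmx[1L], prod(dmx[-1L]))
  # reflect indices: ... 3 2 | 1 2 ... n | n-1 n-2 ...
  reflect <- function(i) {
    i <- abs(i - 1L) %% (2L * (n - 1L))
    ifelse(i >= n, 2L * (n - 1L) - i, i) + 1L
  }
  out <- matrix(0, nrow(x), ncol(x))
  base <- seq_len(n)
  for (o in -r:r)
    out <- out + kern[o + r + 1L] * x[reflect(base + o), , drop = FALSE]
  dim(out) <- dmx
  aperm(out, order(perm))
}

#' Build a normal-brain template from static images
#'
#' Voxelwise mean and sample standard deviation (denominator n - 1)
#' across a population of static images of visually normal uptake.
#'
#' @param statics list of \linkS4class{StaticImage} (or 3D arrays) with
#'   identical geometry; at least 2.
#' @return a \linkS4class{NormalTemplate}
#' @export
buildTemplate <- function(statics) {
  vols <- lapply(statics, function(s) if (is(s, "StaticImage")) s@voxels else s)
  if (length(vols) < 2L) stop("template needs at least 2 subjects")
  dm <- dim(vols[[1L]])
  if (!all(vapply(vols, function(v) identical(dim(v), dm), logical(1))))
    stop("geometry mismatch across template subjects")
  vs <- if (is(statics[[1L]], "StaticImage")) statics[[1L]]@voxelSize
        else c(2, 2, 2)
  stack <- array(unlist(vols, use.names = FALSE), dim = c(dm, length(vols)))
  mu <- apply(stack, 1:3, mean)
  sdv <- apply(stack, 1:3, sd)
  new("NormalTemplate", meanVol = mu, sdVol = sdv, voxelSize = vs,
      nSubjects = length(vols))
}

#' Voxelwise Z-score map of a patient static image against the template
#'
#' Z = (static - template mean) / max(template SD, epsilon). The SD
#' floor prevents division blow-ups where the normal population is
#' near-constant; by default it is the 5th percentile of the nonzero
#' template SDs.
#'
#' @param static a \linkS4class{StaticImage}
#' @param tmpl a \linkS4class{NormalTemplate} with matching geometry.
#' @param epsilon SD floor; \code{NULL} for the default.
#' @return 3D numeric array of Z scores
#' @export
zscoreMap <- function(static, tmpl, epsilon = NULL) {
  stopifnot(is(static, "StaticImage"), is(tmpl, "NormalTemplate"))
  if (!identical(dim(static@voxels), dim(tmpl@meanVol)))
    stop("geometry mismatch between static image and template")
  sdv <- tmpl@sdVol
  if (is.null(epsilon)) {
    nz <- sdv[sdv > 0]
    epsilon <- if (length(nz)) unname(quantile(nz, 0.05)) else 1e-6
  }
  (static@voxels - tmpl@meanVol) / pmax(sdv, epsilon)
}

#' Tumor mask from a Z-score map
#'
#' Thresholds the Z map (Z > threshold), labels connected components,
#' drops components smaller than the minimum cluster size, and
#' binary-dilates the union with the 3x3x3 connectivity-1 (6-connected
#' cross) structuring element. An empty result is legal and flagged
#' \code{nonSegmentable}.
#'
#' @param z 3D numeric Z-score array.
#' @param zThreshold voxel-level threshold (default 2.5).
#' @param minClusterVoxels minimum connected-component size retained
#'   (default 250 voxels).
#' @param dilationIterations dilation passes after component filtering
#'   (default 2).
#' @param connectivity neighbourhood used to form components: 6, 18
#'   (default) or 26.
#' @param voxelSizeMm voxel size recorded in the mask, mm.
#' @return a \linkS4class{TumorMask}
#' @export
makeTumorMask <- function(z, zThreshold = 2.5, minClusterVoxels = 250,
                          dilationIterations = 2, connectivity = 18,
                          voxelSizeMm = c(2, 2, 2)) {
  stopifnot(length(dim(z)) == 3L, all(is.finite(z)))
  fg <- z > zThreshold
  keep <- array(FALSE, dim = dim(fg))
  if (any(fg)) {
    lab <- labelComponents(fg, connectivity = connectivity)
    sizes <- tabulate(lab[lab > 0L])
    big <- which(sizes >= minClusterVoxels)
    if (length(big)) keep <- array(lab %in% big, dim = dim(fg))
  }
  if (any(keep) && dilationIterations > 0)
    keep <- dilate6(keep, dilationIterations)
  tumorMask(keep, voxelSize = voxelSizeMm,
            params = list(zThreshold = zThreshold,
                          minClusterVoxels = minClusterVoxels,
                          dilationIterations = dilationIterations,
                          connectivity = connectivity,
                          nonSegmentable = !any(keep)))
}

#' Label connected components of a 3D logical array
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return integer array; 0 = background, components numbered from 1
#' @export
labelComponents <- function(mask, connectivity = 18) {
  stopifnot(length(dim(mask)) == 3L)
  offs <- neighborOffsets(connectivity)
  dm <- dim(mask)
  lab <- array(0L, dim = dm)
  todo <- which(mask)
  if (length(todo) == 0L) return(lab)
  inMask <- mask
  nextLab <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- arrayInd(seed, dm)
    lab[seed] <- nextLab
    while (nrow(frontier) > 0L) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        sweep(frontier, 2L, offs[i, ], `+`)))
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= dm[1L] &
            cand[, 2L] >= 1L & cand[, 2L] <= dm[2L] &
            cand[, 3L] >= 1L & cand[, 3L] <= dm[3L]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) break
      lin <- cand[, 1L] + dm[1L] * (cand[, 2L] - 1L) +
        dm[1L] * dm[2L] * (cand[, 3L] - 1L)
      fresh <- !duplicated(lin) & inMask[lin] & lab[lin] == 0L
      if (!any(fresh)) break
      lab[lin[fresh]] <- nextLab
      frontier <- cand[fresh, , drop = FALSE]
    }
  }
  lab
}

neighborOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  maxd <- switch(as.character(connectivity),
                 "6" = 1L, "18" = 2L, "26" = 3L,
                 stop("connectivity must be 6, 18 or 26"))
  g[d > 0 & d <= maxd, , drop = FALSE]
}

# Binary dilation with the 6-connected cross (3x3x3, connectivity 1),
# iterated `iterations` times.
dilate6 <- function(mask, iterations = 1) {
  dm <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    # shift +/- 1 along each axis
    out[-1, , ] <- out[-1, , ] | mask[-dm[1L], , ]
    out[-dm[1L], , ] <- out[-dm[1L], , ] | mask[-1, , ]
    out[, -1, ] <- out[, -1, ] | mask[, -dm[2L], ]
    out[, -dm[2L], ] <- out[, -dm[2L], ] | mask[, -1, ]
    out[, , -1] <- out[, , -1] | mask[, , -dm[3L]]
    out[, , -dm[3L]] <- out[, , -dm[3L]] | mask[, , -1]
    mask <- out
  }
  mask
}
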