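#' @include AllClasses.R constructors.R segmentation.R
NULL

#' Default TAC archetype parameters
#'
#' Three kinetic archetypes on the dynamic frame grid, matching the
#' canonical uptake-curve taxonomy: #1 slowly and steadily increasing
#' uptake, #2 rapid rise followed by a slow decline, #3 rapid rise
#' followed by a rapid washout. Each curve is
#' amp * (1 - exp(-t / rise)) * exp(-decay * t) on frame mid-times, a
#' smooth rise-and-clear shape whose peak time and late slope are set by
#' \code{rise} and \code{decay} (minutes and 1/minutes).
#'
#' @return list of per-archetype parameter lists
#' @export
archetypeDefaults <- function() {
  list(
    a1 = list(amp = 2.0, rise = 25, decay = 0),
    a2 = list(amp = 2.5, rise = 5, decay = 0.008),
    a3 = list(amp = 3.0, rise = 3, decay = 0.030)
  )
}

#' Generate the three archetype TAC curves
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param params parameter list as \code{\link{archetypeDefaults}}.
#' @return 3 x T matrix of raw-scale curves (rows = archetypes 1..3)
#' @export
makeArchetypeCurves <- function(schedule = defaultSchedule(),
                                params = archetypeDefaults()) {
  t <- frameMids(schedule)
  curves <- t(vapply(params, function(p)
    p$amp * (1 - exp(-t / p$rise)) * exp(-p$decay * t),
    numeric(length(t))))
  rownames(curves) <- names(params)
  if (any(curves < 0)) stop("archetype curves must be non-negative")
  sl <- apply(curves, 1L, curveSlope, schedule = schedule,
              window = c(20, 50))
  if (!(sl[1L] > 0)) stop("archetype 1 must have a positive late slope")
  if (!(sl[2L] < 0 && sl[3L] < sl[2L]))
    stop("archetypes 2 and 3 must decline, 3 faster than 2")
  curves
}

#' Simulate noisy voxel TACs from the three archetypes
#'
#' @param nPer voxels drawn per archetype (scalar or length 3).
#' @param noiseSd Gaussian noise SD on the SUV scale (default 0.2).
#' @param schedule frame schedule.
#' @param params archetype parameters.
#' @param seed RNG seed (mandatory).
#' @return list: \code{tacs} (V x T matrix, raw scale) and
#'   \code{labels} (true archetype per row)
#' @export
simulateArchetypeTACs <- function(nPer = 100, noiseSd = 0.2,
                                  schedule = defaultSchedule(),
                                  params = archetypeDefaults(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  nPer <- rep_len(nPer, 3L)
  curves <- makeArchetypeCurves(schedule, params)
  labels <- rep(1:3, nPer)
  tacs <- curves[labels, , drop = FALSE] +
    matrix(rnorm(sum(nPer) * ncol(curves), 0, noiseSd),
           nrow = sum(nPer))
  list(tacs = tacs, labels = labels)
}

#' Phantom specification
#'
#' @param dim grid size (3 integers).
#' @param voxelSize voxel edge lengths, mm.
#' @param background background SUV level.
#' @param noiseSd per-frame Gaussian noise SD (SUV).
#' @param lesionCenter ellipsoid centre in voxel coordinates.
#' @param lesionRadiiMm ellipsoid semi-axes in mm.
#' @param weights mixture weights over the three archetypes for lesion
#'   voxels (non-negative, summing to 1).
#' @param params archetype parameters.
#' @param seed RNG seed (mandatory).
#' @return a validated spec list for \code{\link{simulatePhantom}}
#' @export
phantomSpec <- function(dim = c(32, 32, 32), voxelSize = c(2, 2, 2),
                        background = 1.0, noiseSd = 0.2,
                        lesionCenter = NULL, lesionRadiiMm = c(12, 12, 12),
                        weights = c(0.6, 0.25, 0.15),
                        params = archetypeDefaults(), seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(lesionCenter)) lesionCenter <- round(dim * 0.55)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  rVox <- lesionRadiiMm / voxelSize
  if (any(lesionCenter - rVox < 1) || any(lesionCenter + rVox > dim))
    stop("lesion extends outside the grid")
  list(dim = dim, voxelSize = voxelSize, background = background,
       noiseSd = noiseSd, lesionCenter = lesionCenter,
       lesionRadiiMm = lesionRadiiMm, weights = weights, params = params,
       seed = seed)
}

#' Simulate a 4D dynamic PET phantom with ground truth
#'
#' Background voxels follow a flat TAC at the background SUV level plus
#' Gaussian noise; lesion voxels draw one of the three archetype curves
#' (per the mixture weights) added on top of the background. Returns
#' the image and the voxelwise true archetype labels (0 = background).
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list: \code{image} (\linkS4class{DynamicImage}),
#'   \code{truth} (3D integer array), \code{curves} (archetype matrix)
#' @export
simulatePhantom <- function(spec) {
  set.seed(spec$seed)
  dm <- spec$dim
  sched <- defaultSchedule()
  nT <- nFrames(sched)
  curves <- makeArchetypeCurves(sched, spec$params)
  nVox <- prod(dm)
  flat <- matrix(rnorm(nVox * nT, spec$background, spec$noiseSd),
                 nrow = nVox)
  # ellipsoid lesion
  cx <- spec$lesionCenter; r <- spec$lesionRadiiMm / spec$voxelSize
  gx <- (seq_len(dm[1L]) - cx[1L]) / r[1L]
  gy <- (seq_len(dm[2L]) - cx[2L]) / r[2L]
  gz <- (seq_len(dm[3L]) - cx[3L]) / r[3L]
  d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  lesion <- which(d2 <= 1)
  truth <- array(0L, dim = dm)
  if (length(lesion)) {
    # Kinetic subregions are spatially coherent (as in real tumors):
    # the lesion is split into contiguous angular sectors around the x
    # axis with volumes proportional to the mixture weights (sectors,
    # unlike slabs, also expose boundary surface proportional to their
    # volume).
    co <- arrayInd(lesion, dm)
    theta <- atan2(co[, 3L] - cx[3L], co[, 2L] - cx[2L])
    ord <- order(theta, co[, 1L], co[, 2L], co[, 3L])
    nL <- length(lesion)
    bounds <- round(cumsum(spec$weights) * nL)
    lab <- integer(nL)
    lab[ord] <- rep(1:3, times = diff(c(0L, bounds)))
    truth[lesion] <- lab
    flat[lesion, ] <- flat[lesion, ] + curves[lab, , drop = FALSE]
  }
  flat[flat < 0] <- 0   # SUV cannot be negative
  img <- dynamicImage(array(flat, dim = c(dm, nT)),
                      voxelSize = spec$voxelSize, schedule = sched)
  list(image = img, truth = truth, curves = curves)
}

#' Simulate static normal brains for template construction
#'
#' Flat background plus noise, reduced to the late static window the
#' segmentation template is built from.
#'
#' @param n number of subjects.
#' @param dim grid size.
#' @param background background SUV.
#' @param noiseSd per-frame noise SD (SUV).
#' @param voxelSize mm.
#' @param seed RNG seed.
#' @return list of \linkS4class{StaticImage}
#' @export
simulateNormalStatics <- function(n = 41, dim = c(32, 32, 32),
                                  background = 1.0, noiseSd = 0.2,
                                  voxelSize = c(2, 2, 2), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  nLate <- 2L   # frames starting in [40, 50) on the default schedule
  lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(dim) * nLate, background, noiseSd),
               dim = c(dim, nLate))
    staticImage(apply(v, 1:3, mean), voxelSize = voxelSize,
                window = c(40, 50))
  })
}

#' Simulate a patient cohort with IDH1-linked structure
#'
#' Per patient: IDH1 status is Bernoulli; centroid proportions are drawn
#' from a logistic-normal composition whose mean depends on IDH1 status
#' (mutants enriched in centroid #1, wild-types in #3); TBR, TTP and
#' slope have IDH1-dependent location shifts; PFS and OS are exponential
#' with a hazard benefit for patients with pct_c1 > 90; censoring is
#' independent exponential calibrated to the requested censoring
#' fraction.
#'
#' @param nPatients cohort size (default 37).
#' @param idhFraction probability of IDH1 mutation (default 17/37).
#' @param effect named effect multipliers, each >= 0; 0 switches the
#'   corresponding association off: \code{composition} (IDH1 shift of
#'   the composition mean), \code{conventional} (IDH1 shift of
#'   TBR/TTP/slope), \code{survivalHR} (hazard ratio of the
#'   pct_c1 <= 90 group versus > 90; 1 = no benefit).
#' @param censoringRate expected fraction censored (in [0, 1)).
#' @param seed RNG seed (mandatory).
#' @return cohort data.frame in the \code{\link{readCohort}} layout with
#'   survival columns
#' @export
simulateCohort <- function(nPatients = 37, idhFraction = 17 / 37,
                           effect = list(composition = 1,
                                         conventional = 1,
                                         survivalHR = 3),
                           censoringRate = 0.3, seed) {
  if (missing(seed)) stop("seed is required")
  if (nPatients < 2) stop("need at least 2 patients")
  if (idhFraction <= 0 || idhFraction >= 1)
    stop("idhFraction must be in (0,1)")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoringRate must be in [0,1)")
  set.seed(seed)
  mut <- rbinom(nPatients, 1L, idhFraction) == 1L
  ce <- effect$composition
  # additive log-ratio means (c1, c2 vs c3 baseline); mutants sit high
  # on centroid #1 (about half above 90%), wild-types spread widely
  mu1 <- ifelse(mut, 3.0 * ce, 0)
  mu2 <- ifelse(mut, 0.5, 0.5 + 0.3 * ce)
  y1 <- rnorm(nPatients, mu1, 2.0)
  y2 <- rnorm(nPatients, mu2, 1.2)
  den <- exp(y1) + exp(y2) + 1
  p1 <- exp(y1) / den; p2 <- exp(y2) / den; p3 <- 1 / den
  ke <- effect$conventional
  tbrMax <- pmax(rnorm(nPatients, 3.3 - 0.6 * ke * mut, 0.8), 1.05)
  tbrMean <- pmax(rnorm(nPatients, 2.3 - 0.4 * ke * mut, 0.5), 1.0)
  suvMean <- pmax(rnorm(nPatients, 1.8 - 0.2 * ke * mut, 0.4), 0.5)
  suvMax <- suvMean * tbrMax / tbrMean
  starts <- frameStarts(defaultSchedule())
  ttpShift <- 3 * ke * (2 * mut - 1)             # mutants peak later
  ttpIdx <- pmin(pmax(round(rnorm(nPatients, 5.5 + ttpShift, 2.2)), 1),
                 length(starts))
  ttp <- starts[ttpIdx]
  slope <- rnorm(nPatients, -0.5 + 0.65 * ke * mut, 0.45)
  hr <- effect$survivalHR
  lowRisk <- 100 * p1 > 90
  ratePFS <- log(2) / 8 * ifelse(lowRisk, 1 / hr, 1)   # median 8 mo high-risk
  rateOS <- log(2) / 18 * ifelse(lowRisk, 1 / hr, 1)
  tPFS <- rexp(nPatients, ratePFS)
  tOS <- pmax(rexp(nPatients, rateOS), tPFS)
  censor <- function(tEvent, rateEvent) {
    if (censoringRate == 0)
      return(list(time = tEvent, event = rep(1L, nPatients)))
    rc <- mean(rateEvent) * censoringRate / (1 - censoringRate)
    tc <- rexp(nPatients, rc)
    list(time = pmin(tEvent, tc), event = as.integer(tEvent <= tc))
  }
  pfs <- censor(tPFS, ratePFS)
  os <- censor(tOS, rateOS)
  df <- data.frame(
    id = seq_len(nPatients),
    histology = "simulated glioma",
    mib1 = NA_real_,
    idh1 = ifelse(mut, "+", "-"),
    who_grade = NA_character_,
    pct_c1 = 100 * p1, pct_c2 = 100 * p2, pct_c3 = 100 * p3,
    suv_max = suvMax, suv_mean = suvMean,
    tbr_max = tbrMax, tbr_mean = tbrMean,
    ttp_min = ttp, slope_suv_h = slope,
    pfs_months = pfs$time, pfs_event = pfs$event,
    os_months = os$time, os_event = os$event,
    stringsAsFactors = FALSE)
  validateCohort(df)
}
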