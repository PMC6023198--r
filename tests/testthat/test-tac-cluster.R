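test_that("TAC extraction returns one row per mask voxel", {
  set.seed(3)
  img <- dynamicImage(array(abs(rnorm(5 * 5 * 5 * 10)), c(5, 5, 5, 10)))
  mv <- array(FALSE, c(5, 5, 5)); mv[c(1, 30, 125)] <- TRUE
  tacs <- extractTACs(img, tumorMask(mv))
  expect_equal(dim(voxelData(tacs)), c(3L, 10L))
  expect_false(tacs@normalized)
  # rows match the image values at the recorded coordinates
  for (r in 1:3) {
    co <- tacs@coords[r, ]
    expect_equal(voxelData(tacs)[r, ], img@voxels[co[1], co[2], co[3], ])
  }
  expect_error(extractTACs(img, tumorMask(array(FALSE, c(5, 5, 5)))),
               "non-segmentable")
  expect_error(extractTACs(img, tumorMask(array(TRUE, c(4, 4, 4)))),
               "geometry")
})

test_that("z-normalization uses the population SD and drops flat rows", {
  expect_equal(znormalize(c(1, 2, 3)),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)

  X <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(2, 0, 2, 0))
  tacs <- new("TACMatrix", values = X,
              coords = cbind(1:3, 1L, 1L), normalized = FALSE)
  expect_message(z <- znormalizeTACs(tacs), "1 zero-variance")
  expect_equal(nrow(voxelData(z)), 2L)
  expect_equal(z@nDropped, 1L)
  expect_true(z@normalized)

  allFlat <- new("TACMatrix", values = matrix(1, 2, 5),
                 coords = cbind(1:2, 1L, 1L), normalized = FALSE)
  expect_error(znormalizeTACs(allFlat), "zero variance")
})

test_that("z-normalized rows have mean 0 and SD 1 to 1e-9, idempotently", {
  set.seed(7)
  X <- matrix(rnorm(50 * 10, sd = runif(50, 0.5, 4)), 50, 10)
  Z <- znormRows(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(Z^2)) - 1)), 1e-9)
  expect_equal(znormRows(Z), Z, tolerance = 1e-9)   # idempotence
})

test_that("DTW matches hand-computed values and basic identities", {
  expect_equal(dtwDistance(c(0, 1, 1), c(0, 0, 1)), 0)
  expect_equal(dtwDistance(c(0, 0), c(1, 1)), 2)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(dtwDistance(x, x), 0)
    expect_equal(dtwDistance(x, y), dtwDistance(y, x))
    expect_lte(dtwDistance(x, y), sum(abs(x - y)) + 1e-12)
  }
  expect_error(dtwDistance(numeric(0), 1:3), "empty")
})

test_that("DTW agrees with an independent shortest-path solver", {
  library(igraph)
  set.seed(13)
  for (i in 1:100) {
    q <- rnorm(10); c <- rnorm(10)
    expect_equal(dtwDistance(q, c), dtwRefShortestPath(q, c),
                 tolerance = 1e-9)
  }
})

test_that("the warping path is a valid monotone alignment", {
  set.seed(17)
  q <- rnorm(8); c <- rnorm(8)
  p <- dtwPath(q, c)
  expect_equal(p[1, ], c(1L, 1L))
  expect_equal(p[nrow(p), ], c(8L, 8L))
  steps <- diff(p)
  expect_true(all(steps >= 0 & steps <= 1))
  expect_true(all(rowSums(steps) >= 1))
  expect_equal(sum(abs(q[p[, 1]] - c[p[, 2]])), dtwDistance(q, c))
})

test_that("DTW k-means handles degenerate and labeled cases", {
  one <- matrix(rep(c(1, -1, 0.5, -0.5), each = 6), nrow = 6)
  oneZ <- znormRows(one)
  fit1 <- kmeansDTW(oneZ, 1, seed = 1)
  expect_equal(fit1$inertia, 0)
  expect_equal(centroidCurves(fit1$centroids)[1, ], oneZ[1, ],
               ignore_attr = TRUE)

  set.seed(5)
  Z <- znormRows(matrix(rnorm(6 * 8), 6, 8))
  fitV <- kmeansDTW(Z, 6, seed = 2)
  expect_equal(fitV$inertia, 0, tolerance = 1e-12)
  expect_error(kmeansDTW(Z, 7, seed = 3), "fewer series")
})

test_that("DTW k-means recovers the three archetype populations", {
  sim <- simulateArchetypeTACs(nPer = 100, noiseSd = 0.2, seed = 101)
  Z <- znormRows(sim$tacs)
  fit <- kmeansDTW(Z, 3, seed = 7)
  expect_gte(adjustedRand(clusterLabels(fit$assignment), sim$labels), 0.9)
  # reproducibility under a fixed seed
  fit2 <- kmeansDTW(Z, 3, seed = 7)
  expect_identical(centroidCurves(fit$centroids),
                   centroidCurves(fit2$centroids))
  expect_identical(clusterLabels(fit$assignment),
                   clusterLabels(fit2$assignment))
})

test_that("the SSE profile decreases and the elbow lands at 3 archetypes", {
  sim <- simulateArchetypeTACs(nPer = 100, noiseSd = 0.2, seed = 103)
  Z <- znormRows(sim$tacs)
  ep <- elbowProfile(Z, kMax = 8, seed = 29)
  expect_true(all(diff(ep@sse) <= 1e-6))
  expect_equal(selectElbowK(ep), 3L)
  expect_lt(ep@sse[3], 0.3 * ep@sse[1])   # pronounced elbow

  # single-archetype data: no comparable elbow structure
  sim1 <- simulateArchetypeTACs(nPer = c(150, 0, 0), noiseSd = 0.2,
                                seed = 105)
  Z1 <- znormRows(sim1$tacs)
  ep1 <- elbowProfile(Z1, kMax = 6, seed = 31)
  expect_true(all(diff(ep1@sse) <= 1e-6))
  expect_gt(ep1@sse[3], 0.5 * ep1@sse[1])  # splitting noise buys little
})

test_that("final assignment is Euclidean with ties toward label #1", {
  curves <- znormRows(makeArchetypeCurves())
  cent <- labelCentroids(new("CentroidSet", curves = curves,
                             semanticLabels = rep(NA_integer_, 3),
                             meta = list()))
  # a TAC exactly equal to a centroid gets that label at distance 0
  i2 <- which(semanticLabels(cent) == 2L)
  asg <- assignToCentroids(matrix(curves[i2, ], 1), cent)
  expect_equal(clusterLabels(asg), 2L)
  expect_equal(asg@distances, 0)

  # exact distance tie between #1 and #3 -> broken toward #1: build
  # centroids with c3 = -c1 and c2 far away, and probe with a curve
  # orthogonal to c1 (hence equidistant from c1 and -c1)
  c1 <- znormalize(1:10)
  zig <- znormalize(rep(c(1, -1), 5))
  x <- zig - sum(zig * c1) / sum(c1 * c1) * c1     # Gram-Schmidt
  centT <- new("CentroidSet",
               curves = rbind(c1, c1 + 10, -c1),
               semanticLabels = 1:3, meta = list())
  d <- unname(sqrt(rowSums(sweep(centroidCurves(centT), 2, x)^2)))
  expect_equal(d[1], d[3])                         # genuine tie
  expect_gt(d[2], d[1])
  asgT <- assignToCentroids(matrix(x, 1), centT)
  expect_equal(clusterLabels(asgT), 1L)

  expect_error(assignToCentroids(matrix(0, 1, 5), cent), "length")
})

test_that("assignment to frozen centroids is accurate on noisy archetypes", {
  curves <- znormRows(makeArchetypeCurves())
  cent <- labelCentroids(new("CentroidSet", curves = curves,
                             semanticLabels = rep(NA_integer_, 3),
                             meta = list()))
  sim <- simulateArchetypeTACs(nPer = 200, noiseSd = 0.2, seed = 107)
  asg <- assignToCentroids(znormRows(sim$tacs), cent)
  # centroid rows were generated in archetype order, so semantic labels
  # should match generating labels
  expect_gte(mean(clusterLabels(asg) == sim$labels), 0.95)
})

test_that("semantic labeling orders centroids by late slope", {
  sched <- defaultSchedule()
  tH <- frameMids(sched) / 60
  mk <- function(lateSlope, early = 1)
    znormalize(early * pmin(tH, 0.3) + lateSlope * tH)
  curves <- rbind(mk(-0.1), mk(0.5), mk(-0.9))
  cent <- labelCentroids(new("CentroidSet", curves = curves,
                             semanticLabels = rep(NA_integer_, 3),
                             meta = list()), sched)
  expect_equal(semanticLabels(cent), c(2L, 1L, 3L))

  # the synthetic archetypes label in their natural order
  arch <- labelCentroids(new("CentroidSet",
                             curves = znormRows(makeArchetypeCurves()),
                             semanticLabels = rep(NA_integer_, 3),
                             meta = list()))
  expect_equal(semanticLabels(arch), 1:3)

  two <- new("CentroidSet", curves = curves[1:2, ],
             semanticLabels = rep(NA_integer_, 2), meta = list())
  expect_error(labelCentroids(two), "3-centroid")
})
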