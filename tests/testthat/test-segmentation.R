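test_that("static image is the mean of the late frames", {
  vox <- array(0, c(3, 3, 3, 10))
  for (f in 1:10) vox[, , , f] <- f
  img <- dynamicImage(vox)
  st <- staticFromDynamic(img)              # frames starting at 40 and 45
  expect_equal(st@voxels, array(9.5, c(3, 3, 3)))

  same <- dynamicImage(array(2, c(3, 3, 3, 10)))
  expect_equal(staticFromDynamic(same)@voxels, array(2, c(3, 3, 3)))

  expect_error(staticFromDynamic(img, c(50, 60)), "no frames")
})

test_that("Gaussian smoothing preserves constants and total intensity", {
  const <- array(3.7, c(12, 12, 12))
  expect_equal(smoothGaussian(const, 8, c(2, 2, 2)), const,
               tolerance = 1e-12)

  imp <- array(0, c(31, 31, 31))
  imp[16, 16, 16] <- 1
  sm <- smoothGaussian(imp, 8, c(2, 2, 2))
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(fwhmToSigma(8, 2), 8 / (2 * sqrt(2 * log(2))) / 2)
  expect_equal(fwhmToSigma(8, 2), 1.6986, tolerance = 1e-4)
  expect_error(smoothGaussian(const, -1), "positive")
})

test_that("template construction gives voxelwise mean and sample SD", {
  v <- array(2, c(4, 4, 4))
  t2 <- buildTemplate(list(v, v))
  expect_equal(t2@meanVol, v)
  expect_equal(max(abs(t2@sdVol)), 0)

  vols <- lapply(1:3, function(i) array(i, c(4, 4, 4)))
  t3 <- buildTemplate(vols)
  expect_equal(t3@meanVol, array(2, c(4, 4, 4)))
  expect_equal(t3@sdVol, array(1, c(4, 4, 4)))

  expect_error(buildTemplate(list(v)), "at least 2")
  expect_error(buildTemplate(list(v, array(1, c(5, 5, 5)))), "mismatch")
})

test_that("template mean from simulated normals concentrates at truth", {
  tmpl <- testTemplate(dim = c(16, 16, 16), n = 41, seed = 21)
  # static noise SD is noiseSd/sqrt(2 late frames); the mean over 41
  # subjects should sit within a few standard errors of the background
  se <- 0.2 / sqrt(2) / sqrt(41)
  expect_lt(abs(mean(tmpl@meanVol) - 1.0), 4 * se)
})

test_that("Z-score maps are (static - mean)/SD with an SD floor", {
  mu <- array(1, c(4, 4, 4))
  sdv <- array(0.5, c(4, 4, 4))
  tmpl <- new("NormalTemplate", meanVol = mu, sdVol = sdv,
              voxelSize = c(2, 2, 2), nSubjects = 10L)
  st <- staticImage(array(3, c(4, 4, 4)))
  expect_equal(zscoreMap(st, tmpl), array(4, c(4, 4, 4)))
  expect_equal(zscoreMap(staticImage(mu), tmpl), array(0, c(4, 4, 4)))
  expect_error(zscoreMap(staticImage(array(1, c(5, 5, 5))), tmpl),
               "mismatch")
})

test_that("phantom lesions at +4 SD show up as Z near 4", {
  tmpl <- testTemplate(dim = c(24, 24, 24), n = 41, seed = 31)
  sdTypical <- median(tmpl@sdVol[tmpl@sdVol > 0])
  st <- array(1.0, c(24, 24, 24))
  lesion <- as.matrix(expand.grid(10:14, 10:14, 10:14))
  st[lesion] <- 1.0 + 4 * sdTypical
  z <- zscoreMap(staticImage(st), tmpl)
  expect_equal(mean(z[lesion]), 4, tolerance = 0.35)
})

test_that("mask construction filters components and dilates", {
  z <- array(0, c(30, 30, 20))
  z[1:10, 1:10, 1:3] <- 5          # 300-voxel blob
  z[20:29, 20:29, 10] <- 5         # 100-voxel blob
  m <- makeTumorMask(z, dilationIterations = 0)
  expect_true(all(m@voxels[1:10, 1:10, 1:3]))
  expect_false(any(m@voxels[20:29, 20:29, 10]))

  empty <- makeTumorMask(array(0, c(8, 8, 8)))
  expect_equal(sum(empty@voxels), 0)
  expect_true(empty@params$nonSegmentable)

  cube6 <- array(0, c(20, 20, 20)); cube6[7:12, 7:12, 7:12] <- 3
  expect_equal(sum(makeTumorMask(cube6)@voxels), 0)   # 216 < 250
  cube7 <- array(0, c(20, 20, 20)); cube7[7:13, 7:13, 7:13] <- 3
  expect_gt(sum(makeTumorMask(cube7, dilationIterations = 0)@voxels), 0)
})

test_that("dilation is monotone and composes", {
  z <- array(0, c(24, 24, 24)); z[8:15, 8:15, 8:15] <- 5
  m0 <- makeTumorMask(z, dilationIterations = 0)
  m1 <- makeTumorMask(z, dilationIterations = 1)
  m2 <- makeTumorMask(z, dilationIterations = 2)
  expect_true(all(m0@voxels <= m1@voxels))
  expect_true(all(m1@voxels <= m2@voxels))
  # two single passes equal one double pass
  twice <- makeTumorMask(z, dilationIterations = 0)@voxels
  for (i in 1:2) twice <- fetclust:::dilate6(twice, 1)
  expect_identical(m2@voxels, twice)
})

test_that("the mask is invariant to a shared intensity offset", {
  tmpl <- testTemplate(dim = c(24, 24, 24), n = 11, seed = 41)
  st <- array(1, c(24, 24, 24)); st[6:16, 6:16, 6:16] <- 2.5
  z1 <- zscoreMap(staticImage(st), tmpl)
  shifted <- new("NormalTemplate", meanVol = tmpl@meanVol + 5,
                 sdVol = tmpl@sdVol, voxelSize = tmpl@voxelSize,
                 nSubjects = tmpl@nSubjects)
  z2 <- zscoreMap(staticImage(st + 5), shifted)
  expect_identical(makeTumorMask(z1)@voxels, makeTumorMask(z2)@voxels)
})

test_that("phantom lesions are recovered with high Dice overlap", {
  tmpl <- testTemplate(seed = 11)
  # representative lesion (7.4 mL) at moderate (~6 SD) contrast, and the
  # small-lesion (2 mL) case at the default high contrast; overlap is
  # scored on the component mask, before the deliberately generous
  # dilation step (whose output is a strict superset)
  cases <- list(list(radii = 12, ampScale = 0.5),
                list(radii = 8, ampScale = 1.0))
  for (cs in cases) {
    par <- archetypeDefaults()
    for (i in 1:3) par[[i]]$amp <- par[[i]]$amp * cs$ampScale
    ph <- simulatePhantom(phantomSpec(lesionRadiiMm = rep(cs$radii, 3),
                                      weights = c(1, 0, 0), params = par,
                                      seed = 5))
    sm <- smoothGaussian(staticFromDynamic(ph$image)@voxels, 8, c(2, 2, 2))
    z <- zscoreMap(staticImage(sm), tmpl)
    m <- makeTumorMask(z, dilationIterations = 0)
    expect_gte(diceOverlap(m@voxels, ph$truth > 0), 0.7)
    md <- makeTumorMask(z, dilationIterations = 2)
    expect_true(all(m@voxels <= md@voxels))
  }
})
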