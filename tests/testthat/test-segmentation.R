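test_that("a uniform bright field is one granule with zero porosity", {
  img <- Micrograph(matrix(0.8, 60, 60), pixelSize = 0.1)
  seg <- segmentMicrograph(img, segmentationParams(threshold = 0.5))
  fin <- classifyVoids(img, seg)
  expect_equal(max(granuleLabels(fin)), 1)
  expect_false(any(poreMask(fin)))
  expect_equal(porosity(fin), 0)
})

test_that("constant images and missing calibration are rejected", {
  img <- Micrograph(matrix(0.5, 40, 40), pixelSize = 0.1)
  expect_error(segmentMicrograph(img), "no structure detected")
  expect_error(Micrograph(matrix(0.5, 4, 4)), "pixelSize")
  expect_error(Micrograph(matrix(0.5, 4, 4), pixelSize = NA), "pixelSize")
})

test_that("two disjoint bright squares segment into two granules with exact pixel counts", {
  px <- matrix(0.05, 100, 100)
  px[5:44, 5:44] <- 0.9
  px[60:79, 60:79] <- 0.9
  img <- Micrograph(px, pixelSize = 1)
  seg <- segmentMicrograph(img, segmentationParams(blurSigma = 0))
  s <- measureGranules(seg, 1)
  expect_equal(nrow(s), 2)
  expect_equal(sort(s$area_um2), c(400, 1600))
})

test_that("segmentation is a complete partition of the image", {
  for (seed in 1:4) {
    sim <- simulateMicrograph(seed = seed, targetPorosity = 2 + seed,
                              width = 192, height = 192)
    seg <- segmentMicrograph(sim$micrograph)
    fin <- classifyVoids(sim$micrograph, seg)
    total <- sum(granuleLabels(fin) > 0) + sum(poreMask(fin)) +
      sum(shadowMask(fin)) + sum(backgroundMask(fin))
    expect_equal(total, length(pixels(sim$micrograph)))
    expect_true(validObject(fin))
  }
})

test_that("programmed porosity is recovered on seeded synthetic micrographs", {
  sim <- simulateMicrograph(seed = 21, targetPorosity = 5)
  seg <- segmentMicrograph(sim$micrograph)
  fin <- classifyVoids(sim$micrograph, seg)
  expect_lt(abs(porosity(fin) - sim$truth$realizedPorosity), 1.0)
  expect_lt(abs(porosity(fin) - 5.0), 1.0)
})

test_that("no voids means both final masks are empty", {
  img <- Micrograph(matrix(0.8, 30, 30), pixelSize = 0.1)
  seg <- segmentMicrograph(img, segmentationParams(threshold = 0.5))
  fin <- classifyVoids(img, seg)
  expect_false(any(poreMask(fin)))
  expect_false(any(shadowMask(fin)))
})

test_that("a monotone ramp above the pore ceiling is a shadow, a deep dark void a pore", {
  ## crafted field: granule slab, a dark pore trench, and a shadow band
  ## ramping from the granule edge
  px <- matrix(0.8, 60, 80)
  px[, 30:34] <- 0.12                        # deep dark trench, no ramp
  for (k in 0:7) px[, 50 + k] <- 0.70 - 0.03 * k  # ramp 0.70 -> 0.49
  img <- Micrograph(px, pixelSize = 0.1)
  gran <- matrix(1L, 60, 80)
  gran[, 30:34] <- 0L
  gran[, 50:57] <- 0L
  prov <- SegmentationLabels(gran)           # provisional: all voids pore
  fin <- classifyVoids(img, prov)
  expect_true(all(shadowMask(fin)[, 50:57]))
  expect_true(all(poreMask(fin)[, 30:34]))
  expect_false(any(shadowMask(fin)[, 30:34]))
})

test_that("generated shadows are discriminated from pores by ground truth", {
  sim <- simulateMicrograph(seed = 9, targetPorosity = 5)
  seg <- segmentMicrograph(sim$micrograph)
  fin <- classifyVoids(sim$micrograph, seg)
  ## porosity from pores only stays near truth even with shadows present
  expect_lt(abs(porosity(fin) - sim$truth$realizedPorosity), 1.0)
  ## recovered shadow pixels overwhelmingly lie on true shadow ground truth
  rec <- shadowMask(fin)
  if (sum(rec) > 0)
    expect_gt(sum(rec & sim$truth$shadow) / sum(rec), 0.8)
})

test_that("unknown segmentation parameters are rejected", {
  expect_error(segmentationParams(threshold = c(1, 2)), "threshold")
  expect_error(do.call(segmentationParams, list(bogus = 1)), "bogus|unused")
  expect_error(voidParams(rampRho = 0), "rampRho")
})
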