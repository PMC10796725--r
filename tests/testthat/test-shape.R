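test_that("equivalent diameter reproduces the published variety values", {
  # printed mean areas -> printed estimated diameters, 2-decimal reporting
  expect_equal(roundHalfUp(equivalentDiameter(43.02)), 7.40)
  expect_equal(roundHalfUp(equivalentDiameter(26.69)), 5.83)
  expect_equal(roundHalfUp(equivalentDiameter(89.17)), 10.66)
  expect_equal(roundHalfUp(equivalentDiameter(93.41)), 10.91)
  expect_equal(equivalentDiameter(pi), 2)
})

test_that("equivalent diameter is strictly increasing and inverts the disc area", {
  a <- sort(runif(50, 0.1, 200))
  d <- equivalentDiameter(a)
  expect_true(all(diff(d) > 0))
  expect_equal(pi * (d / 2)^2, a)
  expect_error(equivalentDiameter(0), "positive")
  expect_error(equivalentDiameter(-3), "positive")
  expect_error(equivalentDiameter(NA_real_), "positive")
})

test_that("rasterized reference shapes give the analytic descriptors", {
  disc <- measureGranules(maskLabels(rasterDisc(50)), 0.02)
  expect_lt(disc$eccentricity, 0.10)
  expect_gt(disc$circularity, 0.90)

  ell <- measureGranules(maskLabels(rasterEllipse(80, 40)), 0.02)
  expect_equal(ell$eccentricity, sqrt(1 - 1 / 4), tolerance = 0.03 / 0.866)

  sq <- measureGranules(maskLabels(rasterSquare(60)), 0.02)
  expect_equal(sq$circularity, pi / 4, tolerance = 0.05 / (pi / 4))
  expect_equal(sq$eccentricity, 0, tolerance = 1e-8)
})

test_that("area is the pixel count scaled by the squared calibration", {
  m <- matrix(0L, 100, 100)
  m[5:44, 5:44] <- 1L
  m[60:79, 60:79] <- 2L
  s <- measureGranules(SegmentationLabels(m), 1)
  expect_equal(nrow(s), 2)
  expect_equal(sort(s$area_um2), c(400, 1600))
  s2 <- measureGranules(SegmentationLabels(m), 0.5)
  expect_equal(sort(s2$area_um2), c(100, 400))
})

test_that("descriptors are scale-equivariant in the calibration", {
  mask <- rasterDisc(20) | rasterEllipse(15, 8, n = 51)
  lab <- maskLabels(mask)
  s1 <- measureGranules(lab, 0.1)
  s2 <- measureGranules(lab, 0.2)
  expect_equal(s2$area_um2, 4 * s1$area_um2)
  expect_equal(s2$perimeter_um, 2 * s1$perimeter_um)
  expect_equal(s2$equivalent_diameter_um, 2 * s1$equivalent_diameter_um)
  expect_equal(s2$eccentricity, s1$eccentricity)
  expect_equal(s2$circularity, s1$circularity)
})

test_that("moments and areas agree with the EBImage region-feature oracle", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 90
    m <- matrix(FALSE, n, n)
    for (k in 1:3) {
      r <- sample(6:14, 1)
      ci <- sample(25:65, 1); cj <- sample(25:65, 1)
      m <- m | outer(seq_len(n), seq_len(n),
                     function(i, j) (i - ci)^2 + (j - cj)^2 <= r^2)
    }
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(m * 1)))
    storage.mode(lab) <- "integer"
    mine <- measureGranules(SegmentationLabels(lab), 1)
    mom <- EBImage::computeFeatures.moment(t(lab))
    shp <- EBImage::computeFeatures.shape(t(lab))
    expect_equal(mine$eccentricity, unname(mom[, "m.eccentricity"]),
                 tolerance = 1e-6)
    expect_equal(mine$area_um2, unname(shp[, "s.area"]))
  }
})

test_that("border-touching granules are flagged", {
  m <- matrix(0L, 30, 30)
  m[1:6, 10:15] <- 1L          # touches top border
  m[15:20, 15:20] <- 2L        # interior
  s <- measureGranules(SegmentationLabels(m), 1)
  expect_equal(s$touches_border, c(TRUE, FALSE))
})

test_that("zero granules give an empty table, not an error", {
  s <- measureGranules(SegmentationLabels(matrix(0L, 10, 10)), 1)
  expect_s3_class(s, "data.frame")
  expect_equal(nrow(s), 0)
})
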