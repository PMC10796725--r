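test_that("porosity is the pore share of the analysed area", {
  gran <- matrix(0L, 100, 10)               # 1000 px
  gran[1:90, ] <- 1L                        # 900 granule px
  pore <- matrix(FALSE, 100, 10); pore[91:95, ] <- TRUE   # 50 px
  shad <- matrix(FALSE, 100, 10); shad[96:100, ] <- TRUE  # 50 px
  lab <- SegmentationLabels(gran, pore = pore, shadow = shad)
  expect_equal(porosity(lab), 5.0)
  fs <- fieldSummary(measureGranules(lab, 1), lab)
  expect_equal(fs$porosity_pct, 5.0)
})

test_that("single-granule fields get sd 0; border granules are excluded from shape stats", {
  gran <- matrix(0L, 50, 50)
  gran[20:29, 20:29] <- 1L
  lab <- SegmentationLabels(gran)
  fs <- fieldSummary(measureGranules(lab, 1), lab)
  expect_equal(fs$sd_area_um2, 0)
  expect_equal(fs$mean_area_um2, 100)

  gran2 <- gran
  gran2[1:10, 1:10] <- 2L                  # touches the border, 100 px
  lab2 <- SegmentationLabels(gran2)
  fs2 <- fieldSummary(measureGranules(lab2, 1), lab2)
  expect_equal(fs2$n_granules, 2)
  expect_equal(fs2$mean_area_um2, 100)     # border granule not in the mean
  ## but its pixels stay in the porosity denominator
  expect_equal(fs2$porosity_pct, 100 * sum(poreMask(lab2)) / 2500)
})

test_that("compact fields report porosity but no shape statistics", {
  gran <- matrix(1L, 80, 80)
  gran[, 1:2] <- 0L                        # thin void strip: granule > 95%
  lab <- SegmentationLabels(gran)
  fs <- fieldSummary(measureGranules(lab, 1), lab)
  expect_true(fs$compact)
  expect_true(is.na(fs$mean_area_um2))
  expect_false(is.na(fs$porosity_pct))
})

test_that("chalky-fraction weighting combines region means as specified", {
  f <- data.frame(grain_id = c("g1", "g1"),
                  region_tag = c("chalky", "crystalline"),
                  porosity_pct = c(6, 2))
  expect_equal(aggregateVariety(f, 50)$mean_porosity_pct, 4.0)
  f2 <- data.frame(grain_id = c("g1", "g1"),
                   region_tag = c("chalky", "crystalline"),
                   porosity_pct = c(6, 1))
  expect_equal(aggregateVariety(f2, 10)$mean_porosity_pct, 1.5)
  ## zero chalky fraction: exactly the crystalline mean
  expect_equal(aggregateVariety(f, 0)$mean_porosity_pct, 2.0)
})

test_that("region/weight mismatches are rejected", {
  f <- data.frame(grain_id = "g1", region_tag = "crystalline",
                  porosity_pct = 3)
  expect_error(aggregateVariety(f, 25), "region/weight mismatch")
  f2 <- data.frame(grain_id = "g1", region_tag = "chalky",
                   porosity_pct = 3)
  expect_error(aggregateVariety(f2, 0), "region/weight mismatch")
})

test_that("aggregation averages fields within grains, then grains, and propagates sd", {
  f <- data.frame(
    grain_id = c("g1", "g1", "g2", "g1", "g2"),
    region_tag = c("chalky", "chalky", "chalky",
                   "crystalline", "crystalline"),
    porosity_pct = c(5, 7, 4, 2, 0),
    mean_area_um2 = c(30, 34, 40, 60, 80))
  out <- aggregateVariety(f, 40)
  ## chalky grain means: g1 = 6, g2 = 4 -> mean 5, sd sqrt(2)
  ## crystalline grain means: g1 = 2, g2 = 0 -> mean 1, sd sqrt(2)
  expect_equal(out$mean_porosity_pct, 0.4 * 5 + 0.6 * 1)
  expect_equal(out$grain_sd_porosity_pct,
               sqrt(0.4^2 * 2 + 0.6^2 * 2))
  expect_equal(out$mean_area_um2, 0.4 * 36 + 0.6 * 70)
  expect_equal(out$estimated_diameter_um,
               equivalentDiameter(0.4 * 36 + 0.6 * 70))
  expect_equal(out$n_grains, 2)
  expect_equal(out$n_fields, 5)
})
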