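test_that("tanhContrast matches its closed form and preserves ordering", {
  img <- matrix(c(0, 60, 120, 255), 2, 2)
  out <- tanhContrast(img, m = 2, b = 0.4)
  # closed-form oracle for the whole chain
  x1 <- img / 255
  z <- tanh(2 * (x1 - 0.4) + 0.5)
  expect_equal(out, (z - min(z)) / (max(z) - min(z)) * 255)
  # the image minimum maps through tanh(-0.3) before renormalization
  expect_equal(tanh(2 * (0 - 0.4) + 0.5), -0.2913126, tolerance = 1e-6)
  # min-max endpoints are preserved exactly
  two <- tanhContrast(matrix(c(0, 255), 1, 2))
  expect_equal(sort(as.vector(two)), c(0, 255))
  # idempotence on an already two-valued extreme image
  expect_equal(sort(as.vector(tanhContrast(two))), c(0, 255))
  # monotone on random images
  set.seed(8)
  r <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(order(tanhContrast(r)), order(r))
  expect_warning(z0 <- tanhContrast(matrix(5, 3, 3)), "constant")
  expect_true(all(z0 == 0))
})

test_that("labelRegions joins diagonal neighbours (8-connectivity)", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- TRUE        # touching only diagonally
  expect_equal(max(labelRegions(m)), 1L)
  m[5, 5] <- TRUE                   # separate component
  expect_equal(max(labelRegions(m)), 2L)
  expect_equal(max(labelRegions(matrix(FALSE, 4, 4))), 0L)
})

test_that("regionMetrics agrees with brute-force moments and sums", {
  # 2 x 50 bar: highly eccentric
  bar <- matrix(FALSE, 60, 60); bar[30:31, 6:55] <- TRUE
  met <- regionMetrics(labelRegions(bar), matrix(1, 60, 60))
  px <- which(bar, arr.ind = TRUE)
  expect_equal(met$eccentricity, eccOracle(px))
  expect_gt(met$eccentricity, 0.99)
  # disk: near-zero eccentricity
  dk <- matrix(FALSE, 41, 41)
  dk[as.matrix(diskPixels(c(21, 21), 5, 41, 41))] <- TRUE
  raw <- matrix(runif(41 * 41, 0, 255), 41, 41)
  metD <- regionMetrics(labelRegions(dk), raw)
  expect_lt(metD$eccentricity, 0.2)
  # intensity conservation against the label mask
  expect_equal(metD$summed_intensity, sum(raw[dk]))
  expect_equal(metD$area, sum(dk))
  expect_equal(metD$centroid_row, 21); expect_equal(metD$centroid_col, 21)
})

test_that("detectInclusions keeps compact mid-sized regions only", {
  sc <- renderScene(101, 101,
                    inclusions = list(list(center = c(51, 51), radius = 5,
                                           intensity = 220)),
                    background = 10)
  kept <- detectInclusions(sc$red)
  expect_equal(nrow(kept), 1L)
  expect_lt(kept$eccentricity, 0.2)
  expect_gte(kept$area, 69); expect_lte(kept$area, 89)
  # raw-intensity sum over the region
  expect_gt(kept$summed_intensity, 69 * 200)
  # a 2 x 50 bar is found but rejected by the eccentricity filter
  img <- matrix(10, 80, 80); img[40:41, 11:60] <- 220
  keptBar <- detectInclusions(img)
  expect_equal(nrow(keptBar), 0L)
  expect_equal(nrow(attr(keptBar, "allRegions")), 1L)
  expect_gte(attr(keptBar, "allRegions")$eccentricity, 0.8)
  # area bounds are inclusive: 2x2 (area 4) kept, single pixel rejected
  sq <- matrix(10, 40, 40); sq[20:21, 20:21] <- 220
  expect_equal(nrow(detectInclusions(sq, method = "fixed", level = 100)), 1L)
  one <- matrix(10, 40, 40); one[20, 20] <- 220
  expect_equal(nrow(detectInclusions(one, method = "fixed", level = 100)), 0L)
  # empty image gives an empty table, not an error
  expect_equal(nrow(detectInclusions(matrix(10, 30, 30),
                                     method = "fixed", level = 100)), 0L)
})

test_that("every reported inclusion satisfies the filter predicates", {
  for (s in 1:10) {
    sc <- randomScene(nInclusions = 4, nNeurites = 0, nNuclei = 0,
                      seed = 100 + s)
    kept <- detectInclusions(sc$red)
    expect_true(all(kept$eccentricity < 0.8))
    expect_true(all(kept$area >= 4 & kept$area <= 1000))
  }
})

test_that("detectNuclei counts well-separated nuclei and merges overlaps", {
  sc <- renderScene(120, 120,
                    nuclei = list(list(center = c(30, 30), radius = 8),
                                  list(center = c(30, 90), radius = 8),
                                  list(center = c(90, 60), radius = 8)))
  nuc <- detectNuclei(tanhContrast(sc$blue))
  expect_equal(nuc$count, 3L)
  expect_equal(dim(nuc$centroids), c(3L, 2L))
  # empty channel
  expect_equal(detectNuclei(matrix(10, 60, 60), method = "fixed",
                            level = 100)$count, 0L)
  # two overlapping disks merge into one region (no watershed)
  sc2 <- renderScene(80, 80,
                     nuclei = list(list(center = c(40, 36), radius = 8),
                                   list(center = c(40, 46), radius = 8)))
  expect_equal(detectNuclei(tanhContrast(sc2$blue))$count, 1L)
})

test_that("skeletonization preserves 1-px curves and thins thick bars", {
  ln <- matrix(FALSE, 30, 220); ln[15, 10:210] <- TRUE
  expect_equal(skeletonize(ln), ln)        # already thin: fixed point
  bar <- matrix(FALSE, 40, 120); bar[18:23, 11:110] <- TRUE
  sk <- skeletonize(bar)
  expect_lte(max(table(which(sk, arr.ind = TRUE)[, 2])), 1)  # 1-px wide
  expect_gt(sum(sk), 90)                   # spans most of the bar length
})

test_that("skeleton length tracks Euclidean truth on lines at 0 and 45 degrees", {
  horiz <- matrix(FALSE, 20, 220); horiz[10, 10:210] <- TRUE
  expect_equal(skeletonLength(horiz), 200)
  expect_equal(skeletonLength(horiz, "pixel"), 201)
  diag45 <- matrix(FALSE, 120, 120); diag45[cbind(10:110, 10:110)] <- TRUE
  expect_equal(skeletonLength(diag45), 100 * sqrt(2))
  expect_equal(skeletonLength(matrix(FALSE, 5, 5)), 0)
})

test_that("measureNeurites divides skeleton length by the nucleus count", {
  sc <- renderScene(100, 260,
                    nuclei = list(list(center = c(20, 60), radius = 8),
                                  list(center = c(80, 180), radius = 8)),
                    neurites = list(rbind(c(50, 10), c(50, 210))))
  nuc <- detectNuclei(tanhContrast(sc$blue))
  expect_equal(nuc$count, 2L)
  res <- measureNeurites(tanhContrast(sc$red), nuc)
  expect_equal(res$length_per_nucleus, 100)
  # nuclei overlapping the line remove covered pixels from the length
  sc2 <- renderScene(100, 260,
                     nuclei = list(list(center = c(50, 60), radius = 8),
                                   list(center = c(50, 180), radius = 8)),
                     neurites = list(rbind(c(50, 10), c(50, 210))))
  nuc2 <- detectNuclei(tanhContrast(sc2$blue))
  res2 <- measureNeurites(tanhContrast(sc2$red), nuc2)
  expect_lt(res2$total_length, 200)
  # no neurites: zero length, zero ratio
  res0 <- measureNeurites(matrix(10, 100, 100),
                          list(mask = matrix(FALSE, 100, 100), count = 2L),
                          method = "fixed", level = 100)
  expect_equal(res0$total_length, 0)
  expect_equal(res0$length_per_nucleus, 0)
  # zero nuclei leaves the ratio undefined
  expect_warning(resNA <- measureNeurites(
    matrix(10, 50, 50), list(mask = matrix(FALSE, 50, 50), count = 0L),
    method = "fixed", level = 100), "nuclei")
  expect_true(is.na(resNA$length_per_nucleus))
})

test_that("percent of inclusion-positive cells follows the proximity rule", {
  nuc <- list(count = 4L,
              centroids = rbind(c(10, 10), c(10, 90), c(90, 10), c(90, 90)))
  inc1 <- data.frame(centroid_row = 12, centroid_col = 11)
  expect_equal(percentInclusionPositiveCells(inc1, nuc), 25)
  expect_equal(percentInclusionPositiveCells(inc1[0, , drop = FALSE], nuc), 0)
  incAll <- data.frame(centroid_row = c(10, 10, 90, 90),
                       centroid_col = c(10, 90, 10, 90))
  expect_equal(percentInclusionPositiveCells(incAll, nuc), 100)
  expect_error(percentInclusionPositiveCells(inc1, list(count = 0L)),
               "nuclei")
})

test_that("scenes round-trip through PNG channel files", {
  sc <- randomScene(seed = 17)
  pre <- tempfile()
  paths <- writeScene(sc, pre)
  red <- readImageChannel(paths[1])
  expect_equal(dim(red), dim(sc$red))
  expect_lt(max(abs(red - sc$red)), 0.51)   # 8-bit quantization only
  truth <- jsonlite::read_json(paths[3])
  expect_equal(truth$n_inclusions, sc$truth$n_inclusions)
})
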