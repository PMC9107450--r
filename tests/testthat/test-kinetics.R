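test_that("computeThreshold is pooled baseline mean + k sample SDs", {
  # zero-variance pool: threshold equals the mean
  flat <- matrix(100, nrow = 4, ncol = 30)
  rownames(flat) <- paste0("W", 1:4)
  expect_equal(computeThreshold(flat), 100)
  # alternating 98/102 pool: oracle = direct mean + 25 * sample SD
  alt <- matrix(rep(c(98, 102), length.out = 30 * 4), nrow = 4, ncol = 30)
  rownames(alt) <- paste0("W", 1:4)
  pool <- as.vector(alt[, 1:10])
  expect_equal(computeThreshold(alt), mean(pool) + 25 * sd(pool))
  expect_equal(mean(pool), 100)
  # k = 0 gives the pooled mean
  expect_equal(computeThreshold(alt, kSD = 0), mean(pool))
  expect_error(computeThreshold(matrix(1, 1, 5), nBaseline = 10), "cycles")
})

test_that("analyzeWell scores crossing time, PAR and MaxFL on the grid", {
  tm <- seq(0, by = 0.5, length.out = 120)
  thr <- 50000
  crv <- simulateCurve(0, 2 * thr, 1, 20, noiseSd = 0)
  wk <- analyzeWell(crv$fluorescence, tm, thr)
  expect_equal(wk$t_cross_h, 20)         # midpoint crossing lands on-grid
  expect_equal(wk$PAR_per_h, 0.05)
  expect_true(wk$positive)
  expect_false(wk$invalid_baseline)
  # flat series below threshold
  wk0 <- analyzeWell(rep(100, 120), tm, thr)
  expect_false(wk0$positive)
  expect_equal(wk0$PAR_per_h, 0)
  expect_equal(wk0$MaxFL_AU, 100)
  # MaxFL is the arithmetic mean of the last 10 cycles
  series <- c(rep(0, 110), 1:10)
  expect_equal(analyzeWell(series, tm, thr)$MaxFL_AU, 5.5)
  # above threshold at the first cycle: invalid baseline
  wkInv <- analyzeWell(rep(thr + 1, 120), tm, thr)
  expect_true(wkInv$invalid_baseline)
  expect_false(wkInv$positive)
})

test_that("interpolated crossing falls between the bracketing grid points", {
  tm <- seq(0, by = 0.5, length.out = 120)
  crv <- simulateCurve(0, 1e5, 0.9, 20.13, noiseSd = 0)
  thr <- 5e4
  onGrid <- analyzeWell(crv$fluorescence, tm, thr)$t_cross_h
  interp <- analyzeWell(crv$fluorescence, tm, thr,
                        interpolate = TRUE)$t_cross_h
  expect_lte(interp, onGrid)
  expect_gte(interp, onGrid - 0.5)
  expect_equal(interp, 20.13, tolerance = 0.01)  # near-linear at midpoint
})

test_that("aggregateSample averages replicates and applies the positivity rule", {
  mk <- function(par, pos, invalid = FALSE)
    data.frame(threshold = 1, t_cross_h = ifelse(pos, 1 / par, NA),
               PAR_per_h = par, MaxFL_AU = 100, positive = pos,
               invalid_baseline = invalid)
  w <- rbind(mk(0.05, TRUE), mk(0.04, TRUE), mk(0, FALSE))
  agg <- aggregateSample(w)
  expect_equal(agg$PAR_mean, 0.03)
  expect_true(agg$positive)              # 2/3 >= 0.5
  # all flat: negative sample with PAR 0
  aggNeg <- aggregateSample(rbind(mk(0, FALSE), mk(0, FALSE), mk(0, FALSE)))
  expect_equal(aggNeg$PAR_mean, 0)
  expect_false(aggNeg$positive)
  # 1/3 positive is below the default half rule
  expect_false(aggregateSample(rbind(mk(0.1, TRUE), mk(0, FALSE),
                                     mk(0, FALSE)))$positive)
  # exactly half counts as positive
  expect_true(aggregateSample(rbind(mk(0.1, TRUE), mk(0, FALSE)))$positive)
  # invalid-baseline wells are excluded, all-invalid is unevaluable
  expect_warning(agg2 <- aggregateSample(rbind(mk(0.05, TRUE),
                                               mk(0.2, TRUE, TRUE))),
                 "invalid")
  expect_equal(agg2$n_replicates, 1L)
  expect_warning(aggU <- aggregateSample(mk(0.2, TRUE, TRUE)))
  expect_true(aggU$unevaluable)
  # excluding negatives from the PAR mean is available as an option
  expect_equal(aggregateSample(w, negativePAR = "exclude")$PAR_mean, 0.045)
})

test_that("scoring is scale-equivariant and monotone in curve parameters", {
  pl <- simulatePlate(list(pos = posPreset(), neg = negPreset()),
                      samplesPerGroup = 3, seed = 21)
  k1 <- scorePlate(pl)
  scaled <- PlateRun(wellFluorescence(pl) * 3.7, plateTimes(pl),
                     plateLayout(pl))
  k2 <- scorePlate(scaled)
  expect_equal(plateThreshold(k2), plateThreshold(k1) * 3.7)
  expect_equal(wellKinetics(k2)$MaxFL_AU, wellKinetics(k1)$MaxFL_AU * 3.7)
  expect_equal(wellKinetics(k2)$t_cross_h, wellKinetics(k1)$t_cross_h)
  expect_equal(wellKinetics(k2)$PAR_per_h, wellKinetics(k1)$PAR_per_h)
  expect_equal(wellKinetics(k2)$positive, wellKinetics(k1)$positive)
  # earlier t50 never lowers PAR; larger amplitude never lowers MaxFL
  tm <- seq(0, by = 0.5, length.out = 120)
  thr <- 30000
  par_at <- function(t50) analyzeWell(
    simulateCurve(10000, 150000, 0.8, t50, 0)$fluorescence, tm,
    thr)$PAR_per_h
  t50s <- seq(40, 5, by = -5)
  expect_true(all(diff(vapply(t50s, par_at, numeric(1))) >= 0))
  maxfl_at <- function(a) analyzeWell(
    simulateCurve(10000, a, 0.8, 20, 0)$fluorescence, tm, thr)$MaxFL_AU
  expect_true(all(diff(vapply(seq(0, 2e5, 5e4), maxfl_at,
                              numeric(1))) >= 0))
})

test_that("grid crossing matches the analytic logistic inversion", {
  tm <- seq(0, by = 0.5, length.out = 120)
  set.seed(77)
  for (i in 1:10) {
    b <- runif(1, 0, 2e4); a <- runif(1, 5e4, 2e5)
    k <- runif(1, 0.3, 1.5); t50 <- runif(1, 5, 45)
    thr <- b + runif(1, 0.1, 0.8) * a
    crv <- simulateCurve(b, a, k, t50, noiseSd = 0)
    tc <- analyzeWell(crv$fluorescence, tm, thr)$t_cross_h
    exact <- logisticCrossingTime(b, a, k, t50, thr)
    expect_equal(tc, ceiling(exact / 0.5) * 0.5)
  }
})

test_that("CV% matches its closed form and flags undefined means", {
  expect_equal(cvPercent(c(90, 110)), 100 * sd(c(90, 110)) / 100)
  expect_equal(cvPercent(c(90, 110)), 14.1421356, tolerance = 1e-6)
  expect_equal(cvPercent(c(7, 7, 7)), 0)
  expect_warning(cv0 <- cvPercent(c(-1, 1)), "zero")
  expect_true(is.na(cv0))
  expect_error(cvPercent(5), "at least 2")
})

test_that("near-zero negative controls show larger CV than positives", {
  # emulates background-subtracted MaxFL hovering near zero in negatives
  pl <- simulatePlate(list(pos = posPreset(),
                           neg = negPreset(baseline = c(150, 60),
                                           noiseSd = 120)),
                      samplesPerGroup = 4, seed = 31)
  k <- scorePlate(pl)
  cvs <- batchCV(k, "intra", "MaxFL")
  lay <- sampleResults(k)
  cvNeg <- cvs$cv_percent[grepl("^neg", cvs$sample_id)]
  cvPos <- cvs$cv_percent[grepl("^pos", cvs$sample_id)]
  expect_gt(min(cvNeg), max(cvPos))
})

test_that("inter-batch CV pools per-plate sample means", {
  pl <- simulatePlate(list(pos = posPreset()), samplesPerGroup = 40,
                      allowMultiplate = TRUE, seed = 13)
  k <- scorePlate(pl)
  expect_equal(sort(unique(wellKinetics(k)$batch)), c(1L, 2L))
  intra <- batchCV(k, "intra", "PAR")
  expect_true(all(intra$cv_percent >= 0, na.rm = TRUE))
  # samples sit on a single plate here, so inter-batch CV is undefined
  inter <- batchCV(k, "inter", "PAR")
  expect_true(all(is.na(inter$cv_percent)))
})

test_that("malformed plate exports fail loudly with the offending name", {
  pl <- simulatePlate(groupPresets()["LBD_E4neg"], 2, seed = 5)
  cur <- tempfile(); lay <- tempfile()
  writePlateRun(pl, cur, lay)
  # layout missing a well
  l <- read.csv(lay)
  write.csv(l[-1, ], lay2 <- tempfile(), row.names = FALSE)
  expect_error(readPlateRun(cur, lay2), l$well[1])
  # duplicated time column
  d <- read.csv(cur, check.names = FALSE)
  d2 <- cbind(d, `t_0.0` = d[["t_0.0"]])
  write.csv(d2, cur2 <- tempfile(), row.names = FALSE)
  expect_error(readPlateRun(cur2, lay), "duplicated")
  # non-numeric cell names well and column
  d3 <- d; d3[2, "t_1.5"] <- "oops"
  write.csv(d3, cur3 <- tempfile(), row.names = FALSE)
  expect_error(readPlateRun(cur3, lay), "t_1.5")
})
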