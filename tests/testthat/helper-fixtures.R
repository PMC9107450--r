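## Shared fixture builders for the test suite.

## A deterministic two-preset plate: seeded positives vs flat negatives.
posPreset <- function(amplitude = c(150000, 20000), t50 = c(25, 5)) {
  list(baseline = c(10000, 400), amplitude = amplitude,
       rateK = c(0.8, 0.1), t50 = t50, noiseSd = 800, positiveFraction = 1)
}

negPreset <- function(baseline = c(10000, 400), noiseSd = 800) {
  list(baseline = baseline, amplitude = c(0, 0), rateK = c(0.8, 0),
       t50 = c(30, 0), noiseSd = noiseSd, positiveFraction = 0)
}

## The seeded AD-sample plate of the positivity benchmark: 19 seeding and
## 24 flat biological samples, triplicate wells (129 wells, two plates).
adPositivityPlate <- function(seed) {
  simulatePlate(list(AD = posPreset(), AD2 = negPreset()),
                samplesPerGroup = c(19L, 24L), replicatesPerSample = 3L,
                allowMultiplate = TRUE, seed = seed)
}

## Brute-force eccentricity oracle from raw second central moments of a
## pixel set (rows = (row, col)), with the 1/12 unit-pixel correction.
eccOracle <- function(px) {
  r <- px[, 1] - mean(px[, 1]); c <- px[, 2] - mean(px[, 2])
  u20 <- mean(r^2) + 1/12; u02 <- mean(c^2) + 1/12; u11 <- mean(r * c)
  common <- sqrt((u20 - u02)^2 + 4 * u11^2)
  sqrt(1 - (u20 + u02 - common) / (u20 + u02 + common))
}

## Rasterization oracle: pixel centres within `radius` of `center`.
diskPixels <- function(center, radius, nrow = 101, ncol = 101) {
  g <- expand.grid(row = seq_len(nrow), col = seq_len(ncol))
  g[(g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2, ]
}
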