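## Synthetic-data generators: ThT kinetic curves, plate layouts and ordinal
## cohorts with known ground truth.  Scenes live in scene.R.

#' Simulate one ThT fluorescence kinetic curve
#'
#' Logistic (sigmoidal) aggregation curve on a regular cycle grid, emulating
#' an RT-QuIC plate-reader export (default 120 cycles of 30 min = 60 h):
#' \deqn{F(t) = baseline + amplitude / (1 + e^{-k (t - t_{50})}) + \epsilon,}
#' with \eqn{\epsilon \sim N(0, noiseSd^2)}.  A flat negative control is
#' \code{amplitude = 0}.
#'
#' @param baseline baseline fluorescence, AU.
#' @param amplitude plateau rise above baseline, AU (>= 0).
#' @param rateK logistic growth rate, 1/h.
#' @param t50 time of half-maximal rise, h.
#' @param noiseSd additive Gaussian noise SD, AU (>= 0).
#' @param nCycles number of reading cycles (>= 20; threshold and MaxFL each
#'   need ten cycles).
#' @param cyclePeriod time between cycles, h.
#' @param seed optional RNG seed for reproducibility.
#' @return data.frame with columns \code{time} (h) and \code{fluorescence}
#'   (AU), \code{nCycles} rows.
#' @examples
#' crv <- simulateCurve(10000, 150000, 0.8, 20, noiseSd = 0)
#' crv$fluorescence[crv$time == 20] - 10000  # half of amplitude
#' @export
simulateCurve <- function(baseline, amplitude, rateK, t50, noiseSd = 0,
                          nCycles = 120L, cyclePeriod = 0.5, seed = NULL) {
  for (nm in c("baseline", "amplitude", "rateK", "t50", "noiseSd"))
    assertFiniteScalar(get(nm), nm)
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (nCycles < 20L) stop("'nCycles' must be >= 20")
  if (cyclePeriod <= 0) stop("'cyclePeriod' must be > 0")
  tm <- (seq_len(nCycles) - 1L) * cyclePeriod
  f <- baseline + amplitude * plogis(rateK * (tm - t50))
  if (noiseSd > 0)
    f <- f + withSeed(seed, rnorm(nCycles, 0, noiseSd))
  data.frame(time = tm, fluorescence = f)
}

#' Analytic threshold-crossing time of a noiseless logistic curve
#'
#' Inverts the curve model of [simulateCurve()]: the exact time at which
#' \eqn{F(t) = threshold}, or \code{NA} if the curve never reaches it.
#' Independent oracle for grid-based crossing detection.
#'
#' @inheritParams simulateCurve
#' @param threshold fluorescence threshold, AU.
#' @return crossing time in hours, or \code{NA_real_}.
#' @export
logisticCrossingTime <- function(baseline, amplitude, rateK, t50, threshold) {
  rise <- threshold - baseline
  if (rise <= 0) return(0)                      # already at threshold
  if (amplitude <= rise) return(NA_real_)       # plateau below threshold
  t50 - log(amplitude / rise - 1) / rateK
}

#' Built-in study-group curve presets
#'
#' Parameter distributions for the diagnostic groups crossed with APOE4
#' carrier status.  Presets encode the qualitative structure of the assay:
#' control curves are flat; AD+LB seeds earlier (smaller t50) and higher
#' (larger amplitude) than AD; within AD+LB and LBD, APOE4 carriers reach a
#' larger plateau than non-carriers.  \code{positiveFraction} is the
#' probability that a biological sample in the group is a seeder at all
#' (AD samples seed in only a minority of cases).
#'
#' Each preset is a list with elements \code{baseline}, \code{amplitude},
#' \code{rateK}, \code{t50} (each \code{c(mean, sd)}), \code{noiseSd} and
#' \code{positiveFraction}.
#'
#' @return named list of presets; names like \code{"AD+LB_E4pos"}.
#' @export
groupPresets <- function() {
  p <- function(baseline, amplitude, rateK, t50, noiseSd, posFrac)
    list(baseline = baseline, amplitude = amplitude, rateK = rateK,
         t50 = t50, noiseSd = noiseSd, positiveFraction = posFrac)
  flat <- c(0, 0)
  list(
    control_E4neg = p(c(10000, 400), flat, c(0.8, 0), c(30, 0), 800, 0),
    control_E4pos = p(c(10000, 400), flat, c(0.8, 0), c(30, 0), 800, 0),
    AD_E4neg      = p(c(10000, 400), c(60000, 15000),  c(0.6, 0.1), c(32, 5), 800, 19/43),
    AD_E4pos      = p(c(10000, 400), c(70000, 15000),  c(0.6, 0.1), c(30, 5), 800, 19/43),
    `AD+LB_E4neg` = p(c(10000, 400), c(120000, 20000), c(0.8, 0.1), c(16, 4), 800, 45/47),
    `AD+LB_E4pos` = p(c(10000, 400), c(170000, 20000), c(0.8, 0.1), c(14, 4), 800, 1),
    LBD_E4neg     = p(c(10000, 400), c(110000, 20000), c(0.8, 0.1), c(18, 4), 800, 0.9),
    LBD_E4pos     = p(c(10000, 400), c(150000, 20000), c(0.8, 0.1), c(17, 4), 800, 0.9)
  )
}

## Draw one biological sample's curve parameters from a preset.
drawSampleSpec <- function(preset) {
  seeded <- runif(1) < preset$positiveFraction
  amp <- if (seeded) max(0, rnorm(1, preset$amplitude[1], preset$amplitude[2])) else 0
  list(baseline = rnorm(1, preset$baseline[1], preset$baseline[2]),
       amplitude = amp,
       rateK = max(0.05, rnorm(1, preset$rateK[1], preset$rateK[2])),
       t50 = max(1, rnorm(1, preset$t50[1], preset$t50[2])),
       noiseSd = preset$noiseSd)
}

#' Simulate a multi-group RT-QuIC plate with per-well ground truth
#'
#' Draws per-sample curve parameters from group presets, replicates each
#' sample across wells (shared kinetic parameters, independent noise), and
#' assembles a [PlateRun-class].  Brain samples run in triplicate by default.
#' More than 96 wells requires \code{allowMultiplate = TRUE}; wells then
#' spill onto additional batches (plates) of 96.
#'
#' @param presets named list of presets as from [groupPresets()] (a subset is
#'   fine); names become group labels.
#' @param samplesPerGroup integer, samples per group; recycled across
#'   presets, so \code{c(19, 24)} with two presets gives unequal groups.
#' @param replicatesPerSample wells per biological sample.
#' @param nCycles,cyclePeriod curve grid, as in [simulateCurve()].
#' @param allowMultiplate allow more than 96 wells (split across batches).
#' @param seed RNG seed.
#' @return a [PlateRun-class]; \code{metadata(x)$truth} is a data.frame with
#'   one row per well recording the generating curve parameters.
#' @export
simulatePlate <- function(presets, samplesPerGroup, replicatesPerSample = 3L,
                          nCycles = 120L, cyclePeriod = 0.5,
                          allowMultiplate = FALSE, seed = NULL) {
  if (!length(presets)) stop("at least one preset is required")
  if (is.null(names(presets)) || any(!nzchar(names(presets))))
    stop("'presets' must be a named list")
  samplesPerGroup <- rep_len(as.integer(samplesPerGroup), length(presets))
  nWells <- sum(samplesPerGroup) * replicatesPerSample
  if (nWells > 96L && !allowMultiplate)
    stop("requested ", nWells, " wells but a plate holds 96; ",
         "set allowMultiplate = TRUE to span several plates")
  withSeed(seed, {
    rows <- LETTERS[1:8]
    wellName <- function(i) {
      plate <- (i - 1L) %/% 96L + 1L
      j <- (i - 1L) %% 96L
      sprintf("P%d_%s%02d", plate, rows[j %/% 12L + 1L], j %% 12L + 1L)
    }
    fluor <- matrix(NA_real_, nWells, nCycles)
    layout <- truth <- vector("list", nWells)
    w <- 0L
    for (g in seq_along(presets)) {
      for (s in seq_len(samplesPerGroup[g])) {
        spec <- drawSampleSpec(presets[[g]])
        sid <- sprintf("%s_s%02d", names(presets)[g], s)
        for (r in seq_len(replicatesPerSample)) {
          w <- w + 1L
          crv <- simulateCurve(spec$baseline, spec$amplitude, spec$rateK,
                               spec$t50, spec$noiseSd, nCycles, cyclePeriod)
          fluor[w, ] <- crv$fluorescence
          layout[[w]] <- data.frame(
            well = wellName(w), sample_id = sid, group = names(presets)[g],
            replicate = r, batch = (w - 1L) %/% 96L + 1L,
            stringsAsFactors = FALSE)
          truth[[w]] <- data.frame(
            well = wellName(w), sample_id = sid, group = names(presets)[g],
            baseline = spec$baseline, amplitude = spec$amplitude,
            rateK = spec$rateK, t50 = spec$t50, noiseSd = spec$noiseSd,
            stringsAsFactors = FALSE)
        }
      }
    }
    layout <- do.call(rbind, layout)
    rownames(fluor) <- layout$well
    PlateRun(fluor, (seq_len(nCycles) - 1L) * cyclePeriod, layout,
             truth = do.call(rbind, truth))
  })
}

#' Write / read a PlateRun as wide CSV + layout CSV
#'
#' The wide export has a first column \code{well} followed by hour-stamped
#' columns \code{t_0.0, t_0.5, ...}; the layout file has columns
#' \code{well,sample_id,group,replicate,batch}.
#'
#' @param x a [PlateRun-class]
#' @param curvesPath,layoutPath output file paths
#' @return invisibly, the two paths.
#' @export
writePlateRun <- function(x, curvesPath, layoutPath) {
  fl <- wellFluorescence(x)
  out <- data.frame(well = rownames(fl), fl, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[-1] <- sprintf("t_%.1f", plateTimes(x))
  write.csv(out, curvesPath, row.names = FALSE)
  write.csv(plateLayout(x), layoutPath, row.names = FALSE)
  invisible(c(curvesPath, layoutPath))
}

#' Simulate an ordinal cohort from a cumulative-logit model
#'
#' Generates per-case covariates on the ranges typical of an autopsy AD
#' cohort (age at death 55-100 y, binary sex, CAA 0-4, Braak concentrated in
#' stages IV-VI, Thal mostly 4-5, APOE4 allele count 0-2) plus any
#' standard-normal predictors named in \code{trueBeta} that are not
#' covariates, then draws an ordinal outcome \code{y} from
#' \deqn{P(Y \le j \mid x) = \mathrm{logistic}(\alpha_j - \beta^T x)}
#' with strictly increasing cutpoints \eqn{\alpha_j}.
#'
#' @param nCases number of cases.
#' @param trueBeta named numeric vector of true coefficients; names matching
#'   generated covariate columns use those columns, other names create new
#'   N(0,1) predictor columns.
#' @param cutpoints strictly increasing numeric vector; K = length + 1
#'   outcome levels.
#' @param seed RNG seed.
#' @return data.frame of covariates, predictors and integer outcome
#'   \code{y} in 1..K, with attributes \code{trueBeta} and \code{cutpoints}.
#' @export
simulateCohort <- function(nCases, trueBeta = c(analyte = 0.8),
                           cutpoints = c(-1, 0, 1), seed = NULL) {
  if (is.null(names(trueBeta)) || any(!nzchar(names(trueBeta))))
    stop("'trueBeta' must be a named vector")
  if (any(!is.finite(cutpoints)) || any(diff(cutpoints) <= 0))
    stop("'cutpoints' must be finite and strictly increasing")
  withSeed(seed, {
    d <- data.frame(
      id = sprintf("case%04d", seq_len(nCases)),
      age_at_death = runif(nCases, 55, 100),
      sex = rbinom(nCases, 1, 0.5),
      caa_score = sample(0:4, nCases, replace = TRUE,
                         prob = c(0.15, 0.2, 0.25, 0.25, 0.15)),
      braak = sample(0:6, nCases, replace = TRUE,
                     prob = c(0.01, 0.02, 0.04, 0.08, 0.2, 0.3, 0.35)),
      thal = sample(0:5, nCases, replace = TRUE,
                    prob = c(0.02, 0.03, 0.05, 0.15, 0.35, 0.4)),
      apoe4_count = sample(0:2, nCases, replace = TRUE,
                           prob = c(0.35, 0.5, 0.15)),
      stringsAsFactors = FALSE)
    for (nm in setdiff(names(trueBeta), colnames(d)))
      d[[nm]] <- rnorm(nCases)
    eta <- as.matrix(d[names(trueBeta)]) %*% trueBeta
    u <- runif(nCases)
    d$y <- 1L + vapply(seq_len(nCases), function(i)
      sum(u[i] > plogis(cutpoints - eta[i])), integer(1))
    attr(d, "trueBeta") <- trueBeta
    attr(d, "cutpoints") <- cutpoints
    d
  })
}
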