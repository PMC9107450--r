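## RT-QuIC curve scoring: plate threshold, crossing time, protein
## aggregation rate (PAR), plateau fluorescence (MaxFL), replicate
## aggregation and batch CV%.

#' Read an RT-QuIC plate export
#'
#' Loads a wide curves CSV (first column \code{well}, then hour-stamped
#' columns \code{t_0.0, t_0.5, ...}) plus its companion layout CSV
#' (\code{well,sample_id,group,replicate[,batch]}) into a
#' [PlateRun-class].  Malformed inputs fail loudly, naming the offending
#' well or column.
#'
#' @param curvesPath path to the wide curves CSV.
#' @param layoutPath path to the layout CSV.
#' @return a [PlateRun-class].
#' @export
readPlateRun <- function(curvesPath, layoutPath) {
  cur <- read.csv(curvesPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(cur)[1] != "well")
    stop("curves file must have 'well' as its first column")
  tcols <- colnames(cur)[-1]
  bad <- tcols[!grepl("^t_", tcols)]
  if (length(bad))
    stop("non time-stamped column(s) in curves file: ",
         paste(bad, collapse = ", "))
  tm <- suppressWarnings(as.numeric(sub("^t_", "", tcols)))
  if (anyNA(tm))
    stop("unparseable time column(s): ",
         paste(tcols[is.na(tm)], collapse = ", "))
  if (anyDuplicated(tm))
    stop("duplicated time column(s): ",
         paste(tcols[duplicated(tm)], collapse = ", "))
  fl <- as.matrix(cur[, -1, drop = FALSE])
  suppressWarnings(storage.mode(fl) <- "double")
  if (anyNA(fl)) {
    i <- which(is.na(fl), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing reading for well '", cur$well[i[1]],
         "', column '", tcols[i[2]], "'")
  }
  dimnames(fl) <- list(cur$well, NULL)
  lay <- read.csv(layoutPath, stringsAsFactors = FALSE)
  PlateRun(fl, tm, lay)
}

#' Plate-level fluorescence threshold
#'
#' The positivity threshold is the mean of the pooled first
#' \code{nBaseline} cycle readings of every well on the plate, plus
#' \code{kSD} sample standard deviations of that same pool (default: first
#' 10 cycles, 25 SD).  One value per plate; a zero-variance pool is legal
#' (threshold = mean).
#'
#' @param plate a [PlateRun-class] or a numeric matrix (wells x cycles).
#' @param nBaseline number of initial cycles pooled.
#' @param kSD standard-deviation multiplier.
#' @return threshold in AU (single number).
#' @export
computeThreshold <- function(plate, nBaseline = 10L, kSD = 25) {
  fl <- if (is(plate, "PlateRun")) wellFluorescence(plate) else as.matrix(plate)
  if (ncol(fl) < nBaseline)
    stop("wells have fewer than ", nBaseline, " cycles")
  pool <- as.vector(fl[, seq_len(nBaseline), drop = FALSE])
  if (length(pool) < 2L)
    stop("need at least 2 pooled baseline readings")
  mean(pool) + kSD * sd(pool)
}

#' Score one well's kinetic curve
#'
#' Finds the earliest grid time at which fluorescence reaches the
#' threshold (no interpolation by default; the 0.5 h cycle is the assay's
#' native resolution), and derives the protein aggregation rate
#' PAR = 1 / t_cross (1/h; 0 for non-crossing wells) and MaxFL, the mean
#' fluorescence of the last \code{tailCycles} readings.  A well already at
#' or above threshold at the first cycle is flagged as an invalid-baseline
#' artifact.
#'
#' @param fluorescence numeric vector of readings, AU.
#' @param time matching time grid, h.
#' @param threshold threshold from [computeThreshold()], AU.
#' @param tailCycles cycles averaged for MaxFL.
#' @param interpolate if TRUE, linearly interpolate the crossing time
#'   between the bracketing grid points instead of snapping up to the grid.
#' @return one-row data.frame: \code{threshold, t_cross_h, PAR_per_h,
#'   MaxFL_AU, positive, invalid_baseline}.
#' @export
analyzeWell <- function(fluorescence, time, threshold, tailCycles = 10L,
                        interpolate = FALSE) {
  stopifnot(length(fluorescence) == length(time))
  if (length(fluorescence) < tailCycles)
    stop("need at least ", tailCycles, " cycles for MaxFL")
  maxfl <- mean(tail(fluorescence, tailCycles))
  i <- which(fluorescence >= threshold)[1]
  invalid <- isTRUE(i == 1L)
  tcross <- NA_real_
  if (!is.na(i) && !invalid) {
    tcross <- time[i]
    if (interpolate && fluorescence[i] > threshold) {
      f0 <- fluorescence[i - 1L]; f1 <- fluorescence[i]
      tcross <- time[i - 1L] + (threshold - f0) / (f1 - f0) *
        (time[i] - time[i - 1L])
    }
  }
  positive <- !is.na(tcross)
  data.frame(threshold = threshold,
             t_cross_h = tcross,
             PAR_per_h = if (positive) 1 / tcross else 0,
             MaxFL_AU = maxfl,
             positive = positive,
             invalid_baseline = invalid)
}

#' Aggregate replicate wells into a biological-sample result
#'
#' Sample-level PAR and MaxFL are arithmetic means over valid replicate
#' wells (invalid-baseline wells are dropped with a warning); non-crossing
#' wells contribute PAR = 0 unless \code{negativePAR = "exclude"}.  A
#' sample is positive when the fraction of positive valid replicates is at
#' least \code{minPositiveFraction} (a tie at exactly half counts as
#' positive).  A sample whose wells are all invalid is marked unevaluable.
#'
#' @param wells data.frame of [analyzeWell()] rows for one sample.
#' @param minPositiveFraction replicate fraction required for positivity.
#' @param negativePAR how non-crossing wells enter the PAR mean:
#'   \code{"zero"} (default) or \code{"exclude"}.
#' @return one-row data.frame: \code{PAR_mean, MaxFL_mean, n_replicates,
#'   n_positive_replicates, positive, unevaluable}.
#' @export
aggregateSample <- function(wells, minPositiveFraction = 0.5,
                            negativePAR = c("zero", "exclude")) {
  negativePAR <- match.arg(negativePAR)
  if (nrow(wells) < 1L) stop("at least one well is required")
  nInvalid <- sum(wells$invalid_baseline)
  if (nInvalid > 0)
    warning(nInvalid, " invalid-baseline well(s) excluded from aggregation")
  valid <- wells[!wells$invalid_baseline, , drop = FALSE]
  if (nrow(valid) == 0L)
    return(data.frame(PAR_mean = NA_real_, MaxFL_mean = NA_real_,
                      n_replicates = 0L, n_positive_replicates = 0L,
                      positive = NA, unevaluable = TRUE))
  par <- valid$PAR_per_h
  if (negativePAR == "exclude") par <- par[valid$positive]
  nPos <- sum(valid$positive)
  data.frame(PAR_mean = if (length(par)) mean(par) else 0,
             MaxFL_mean = mean(valid$MaxFL_AU),
             n_replicates = nrow(valid),
             n_positive_replicates = nPos,
             positive = nPos / nrow(valid) >= minPositiveFraction,
             unevaluable = FALSE)
}

#' Score a whole RT-QuIC plate run
#'
#' End-to-end scoring: one threshold per batch (plate) from
#' [computeThreshold()], per-well kinetics from [analyzeWell()], and
#' per-sample replicate aggregation from [aggregateSample()].
#'
#' @param plate a [PlateRun-class].
#' @inheritParams computeThreshold
#' @inheritParams analyzeWell
#' @inheritParams aggregateSample
#' @return a [PlateKinetics-class].
#' @examples
#' pl <- simulatePlate(groupPresets()[c("AD+LB_E4pos", "control_E4neg")],
#'                     samplesPerGroup = 4, seed = 1)
#' scorePlate(pl)
#' @export
scorePlate <- function(plate, nBaseline = 10L, kSD = 25, tailCycles = 10L,
                       interpolate = FALSE, minPositiveFraction = 0.5,
                       negativePAR = c("zero", "exclude")) {
  stopifnot(is(plate, "PlateRun"))
  negativePAR <- match.arg(negativePAR)
  fl <- wellFluorescence(plate)
  tm <- plateTimes(plate)
  lay <- plateLayout(plate)
  thr <- vapply(split(seq_len(nrow(fl)), lay$batch), function(idx)
    computeThreshold(fl[idx, , drop = FALSE], nBaseline, kSD), numeric(1))
  wk <- do.call(rbind, lapply(seq_len(nrow(fl)), function(i)
    analyzeWell(fl[i, ], tm, thr[[as.character(lay$batch[i])]],
                tailCycles, interpolate)))
  wk <- cbind(lay[c("well", "sample_id", "group", "replicate", "batch")], wk)
  samples <- do.call(rbind, lapply(split(wk, wk$sample_id), function(w) {
    agg <- suppressWarnings(
      aggregateSample(w, minPositiveFraction, negativePAR))
    cbind(data.frame(sample_id = w$sample_id[1], group = w$group[1],
                     stringsAsFactors = FALSE), agg)
  }))
  rownames(samples) <- NULL
  new("PlateKinetics", threshold = thr,
      wells = S4Vectors::DataFrame(wk),
      samples = S4Vectors::DataFrame(samples),
      params = list(nBaseline = nBaseline, kSD = kSD,
                    tailCycles = tailCycles, interpolate = interpolate,
                    minPositiveFraction = minPositiveFraction,
                    negativePAR = negativePAR))
}

#' Percent coefficient of variation
#'
#' CV\% = 100 * sample SD / mean.  Used for intra-batch (replicate wells
#' within one run) and inter-batch (per-run sample means across runs)
#' reproducibility of PAR and MaxFL.  A zero mean leaves the CV undefined
#' (returned as NA with a warning) - negative controls hover near zero and
#' show inflated CV for that reason.
#'
#' @param values numeric vector (>= 2 values).
#' @return CV in percent, or NA.
#' @export
cvPercent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values for a CV")
  m <- mean(values)
  if (m == 0) {
    warning("mean is zero; CV% undefined")
    return(NA_real_)
  }
  100 * sd(values) / m
}

#' Batch reproducibility (CV%) of scored RT-QuIC statistics
#'
#' Intra-batch scope pools replicate wells of each sample within a batch;
#' inter-batch scope pools the per-batch sample means across batches (only
#' meaningful when samples were run on several plates).
#'
#' @param kin a [PlateKinetics-class] (or the [wellKinetics()] data.frame).
#' @param scope \code{"intra"} or \code{"inter"}.
#' @param statistic \code{"PAR"} or \code{"MaxFL"}.
#' @return data.frame with one CV per sample (intra) or per sample across
#'   batches (inter): columns \code{sample_id, scope, statistic, n,
#'   cv_percent}.
#' @export
batchCV <- function(kin, scope = c("intra", "inter"),
                    statistic = c("PAR", "MaxFL")) {
  scope <- match.arg(scope)
  statistic <- match.arg(statistic)
  wk <- if (is(kin, "PlateKinetics")) wellKinetics(kin) else as.data.frame(kin)
  col <- if (statistic == "PAR") "PAR_per_h" else "MaxFL_AU"
  wk <- wk[!wk$invalid_baseline, , drop = FALSE]
  cvOf <- function(v) {
    if (length(v) < 2L) return(NA_real_)
    suppressWarnings(cvPercent(v))
  }
  if (scope == "intra") {
    grp <- split(wk, interaction(wk$sample_id, wk$batch, drop = TRUE))
    out <- do.call(rbind, lapply(grp, function(w)
      data.frame(sample_id = w$sample_id[1], scope = "intra",
                 statistic = statistic, n = nrow(w),
                 cv_percent = cvOf(w[[col]]), stringsAsFactors = FALSE)))
  } else {
    means <- aggregate(wk[[col]], list(sample_id = wk$sample_id,
                                       batch = wk$batch), mean)
    grp <- split(means, means$sample_id)
    out <- do.call(rbind, lapply(grp, function(m)
      data.frame(sample_id = m$sample_id[1], scope = "inter",
                 statistic = statistic, n = nrow(m),
                 cv_percent = cvOf(m$x), stringsAsFactors = FALSE)))
  }
  rownames(out) <- NULL
  out
}
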