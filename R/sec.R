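## Size-exclusion chromatography fraction profiling: percent-of-total,
## peak fractions and molecular-weight calibration.

#' Percent of total signal per SEC fraction
#'
#' Converts raw per-fraction analyte amounts into percent of the summed
#' signal over the collected range (the denominator the elution profiles
#' are plotted against).  Invariant to rescaling the raw amounts.
#'
#' @param amounts non-negative numeric vector of per-fraction amounts.
#' @return numeric vector summing to 100.
#' @export
percentOfTotal <- function(amounts) {
  if (any(!is.finite(amounts)) || any(amounts < 0))
    stop("amounts must be finite and non-negative")
  total <- sum(amounts)
  if (total <= 0) stop("all-zero profile: percent of total undefined")
  100 * amounts / total
}

#' Local-maximum peak fractions of an elution profile
#'
#' A fraction is a peak when its amount strictly exceeds every neighbor
#' within \code{window} positions on both sides.  A flat plateau is
#' reported once, at its lowest fraction index; profile endpoints are
#' never peaks.
#'
#' @param amounts numeric vector of per-fraction amounts.
#' @param fractions optional fraction indices (default along the vector).
#' @param window neighborhood half-width, fractions.
#' @return integer vector of peak fraction indices (possibly empty).
#' @export
peakFractions <- function(amounts, fractions = seq_along(amounts),
                          window = 1L) {
  n <- length(amounts)
  if (n < 3L) stop("need at least 3 fractions")
  stopifnot(length(fractions) == n, window >= 1L)
  runs <- rle(amounts)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer()
  for (k in seq_along(runs$values)) {
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n) next          # touches an endpoint
    left <- amounts[max(1L, s - window):(s - 1L)]
    right <- amounts[(e + 1L):min(n, e + window)]
    if (all(runs$values[k] > c(left, right)))
      peaks <- c(peaks, fractions[s])
  }
  peaks
}

#' Molecular weight at a fraction via log-linear calibration
#'
#' Interpolates log10(MW) linearly against fraction index through marker
#' points.  Later-eluting fractions must have strictly smaller MW (larger
#' species elute first); queries outside the marker range are refused
#' (no extrapolation).
#'
#' @param calibration data.frame with columns \code{fraction} and
#'   \code{kDa}.
#' @param fraction fraction index (vectorized).
#' @return molecular weight(s) in kDa.
#' @export
mwAtFraction <- function(calibration, fraction) {
  cal <- calibration[order(calibration$fraction), , drop = FALSE]
  if (any(diff(cal$kDa) >= 0))
    stop("calibration must be strictly decreasing in MW with fraction")
  if (any(fraction < min(cal$fraction) | fraction > max(cal$fraction)))
    stop("fraction outside the calibrated marker range (no extrapolation)")
  10^approx(cal$fraction, log10(cal$kDa), xout = fraction)$y
}

#' Per-fraction comparison of SEC profiles between groups
#'
#' Each replicate profile is first converted to percent-of-total (profiles
#' are always compared on the percent scale, never as raw amounts); each
#' fraction is then tested across groups with the small-sample dispatcher
#' of [groupCompare()], and p-values corrected across fractions (Sidak by
#' default, matching the multiple-comparison style of the elution-profile
#' figures).  With a single replicate per group only descriptive means are
#' returned.
#'
#' @param profiles long data.frame: columns \code{group},
#'   \code{replicate}, \code{fraction}, \code{amount}.
#' @param correction \code{"sidak"}, \code{"bonferroni"} or \code{"none"}.
#' @param alpha significance level after correction.
#' @return data.frame per fraction: group means (percent), \code{p},
#'   \code{p_adjusted}, \code{significant} (NA when untestable).
#' @export
compareProfiles <- function(profiles, correction = c("sidak", "bonferroni",
                                                     "none"), alpha = 0.05) {
  correction <- match.arg(correction)
  need <- c("group", "replicate", "fraction", "amount")
  stopifnot(all(need %in% colnames(profiles)))
  byRep <- split(profiles, interaction(profiles$group, profiles$replicate,
                                       drop = TRUE))
  pct <- do.call(rbind, lapply(byRep, function(d) {
    d <- d[order(d$fraction), , drop = FALSE]
    d$percent <- percentOfTotal(d$amount)
    d
  }))
  nRep <- tapply(pct$replicate, pct$group, function(x) length(unique(x)))
  testable <- all(nRep >= 2)
  frs <- sort(unique(pct$fraction))
  rows <- lapply(frs, function(fr) {
    d <- pct[pct$fraction == fr, , drop = FALSE]
    means <- tapply(d$percent, d$group, mean)
    row <- data.frame(fraction = fr, t(as.matrix(means)))
    colnames(row)[-1] <- paste0("mean_", names(means))
    row$p <- if (testable && var(d$percent) > 0)
      groupCompare(d$percent, d$group)$p else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p))
  out$p_adjusted <- switch(correction,
                           none = out$p,
                           bonferroni = pmin(1, out$p * m),
                           sidak = 1 - (1 - out$p)^m)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}
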