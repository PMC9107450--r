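#' PlateRun: an RT-QuIC plate of ThT kinetic curves
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding one
#' fluorescence assay (rows = wells, columns = reading cycles), the shared
#' time grid in hours as \code{colData(x)$time}, and the well layout
#' (\code{sample_id}, \code{group}, \code{replicate}, \code{batch}) as
#' \code{rowData}.  Generator-side per-well truth, when present, lives in
#' \code{metadata(x)$truth}.
#'
#' @slot .  inherits all slots from SummarizedExperiment
#' @seealso [PlateRun()], [readPlateRun()], [simulatePlate()], [scorePlate()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass PlateRun
setClass("PlateRun", contains = "SummarizedExperiment")

setValidity("PlateRun", function(object) {
  msg <- character()
  if (!"fluorescence" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fluorescence' is required")
  tm <- SummarizedExperiment::colData(object)$time
  if (is.null(tm)) {
    msg <- c(msg, "colData must carry a numeric 'time' column (hours)")
  } else {
    if (length(tm) < 20L)
      msg <- c(msg, "a plate needs at least 20 reading cycles")
    if (any(!is.finite(tm)) || any(diff(tm) <= 0))
      msg <- c(msg, "time grid must be finite and strictly increasing")
  }
  lay <- SummarizedExperiment::rowData(object)
  need <- c("sample_id", "group", "replicate")
  if (!all(need %in% colnames(lay)))
    msg <- c(msg, paste0("rowData must carry layout columns: ",
                         paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PlateRun
#'
#' @param fluorescence numeric matrix, wells in rows (rownames = well ids),
#'   reading cycles in columns, arbitrary fluorescence units (AU).
#' @param time numeric vector of cycle times in hours, strictly increasing,
#'   one per column of \code{fluorescence}.
#' @param layout data.frame with one row per well: columns \code{well},
#'   \code{sample_id}, \code{group}, \code{replicate} and optionally
#'   \code{batch}.
#' @param truth optional data.frame of generator ground truth, stored in
#'   \code{metadata()}.
#' @return a [PlateRun-class] object.
#' @export
PlateRun <- function(fluorescence, time, layout, truth = NULL) {
  fluorescence <- as.matrix(fluorescence)
  if (ncol(fluorescence) != length(time))
    stop("length(time) must equal the number of fluorescence columns")
  layout <- as.data.frame(layout)
  if (!"well" %in% colnames(layout)) stop("layout needs a 'well' column")
  if (is.null(rownames(fluorescence)))
    stop("fluorescence matrix must have well ids as rownames")
  missing <- setdiff(rownames(fluorescence), layout$well)
  if (length(missing))
    stop("layout is missing well(s): ", paste(missing, collapse = ", "))
  layout <- layout[match(rownames(fluorescence), layout$well), , drop = FALSE]
  if (!"batch" %in% colnames(layout)) layout$batch <- 1L
  rd <- S4Vectors::DataFrame(layout[setdiff(colnames(layout), "well")],
                             row.names = layout$well)
  md <- if (is.null(truth)) list() else list(truth = truth)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluorescence = fluorescence),
    rowData = rd,
    colData = S4Vectors::DataFrame(time = as.numeric(time)),
    metadata = md)
  new("PlateRun", se)
}

#' @describeIn PlateRun fluorescence matrix (wells x cycles, AU)
#' @param x a PlateRun
#' @export
wellFluorescence <- function(x) {
  stopifnot(is(x, "PlateRun"))
  SummarizedExperiment::assay(x, "fluorescence")
}

#' @describeIn PlateRun shared time grid in hours
#' @export
plateTimes <- function(x) {
  stopifnot(is(x, "PlateRun"))
  SummarizedExperiment::colData(x)$time
}

#' @describeIn PlateRun layout as a data.frame (well, sample_id, group,
#'   replicate, batch)
#' @export
plateLayout <- function(x) {
  stopifnot(is(x, "PlateRun"))
  lay <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(well = rownames(lay), lay, row.names = NULL,
             stringsAsFactors = FALSE)
}

setMethod("show", "PlateRun", function(object) {
  cat("PlateRun:", nrow(object), "wells x", ncol(object), "cycles,",
      sprintf("%.1f-%.1f h\n", min(plateTimes(object)), max(plateTimes(object))))
  g <- table(SummarizedExperiment::rowData(object)$group)
  cat("  groups:", paste(names(g), g, sep = "=", collapse = ", "), "\n")
})

#' PlateKinetics: scored RT-QuIC results for one or more plates
#'
#' Produced by [scorePlate()].  Holds the per-plate fluorescence threshold,
#' a per-well kinetics table (crossing time, PAR, MaxFL, positivity) and the
#' replicate-aggregated per-sample table.
#'
#' @slot threshold named numeric, one threshold (AU) per batch.
#' @slot wells DataFrame of per-well kinetics.
#' @slot samples DataFrame of per-sample aggregates.
#' @slot params list of scoring parameters used.
#' @exportClass PlateKinetics
setClass("PlateKinetics",
         representation(threshold = "numeric",
                        wells = "DataFrame",
                        samples = "DataFrame",
                        params = "list"))

#' @describeIn PlateKinetics per-plate threshold(s), AU
#' @param x a PlateKinetics
#' @export
plateThreshold <- function(x) {
  stopifnot(is(x, "PlateKinetics"))
  x@threshold
}

#' @describeIn PlateKinetics per-well kinetics as a data.frame
#' @export
wellKinetics <- function(x) {
  stopifnot(is(x, "PlateKinetics"))
  as.data.frame(x@wells)
}

#' @describeIn PlateKinetics per-sample aggregated results as a data.frame
#' @export
sampleResults <- function(x) {
  stopifnot(is(x, "PlateKinetics"))
  as.data.frame(x@samples)
}

setMethod("show", "PlateKinetics", function(object) {
  w <- wellKinetics(object); s <- sampleResults(object)
  cat("PlateKinetics:", nrow(w), "wells,", nrow(s), "samples\n")
  cat(sprintf("  threshold (AU): %s\n",
              paste(sprintf("%.1f", object@threshold), collapse = ", ")))
  cat(sprintf("  positive samples: %d / %d\n",
              sum(s$positive, na.rm = TRUE), nrow(s)))
})
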