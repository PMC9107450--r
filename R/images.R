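## Microscopy quantification: tanh contrast filter, FRET inclusion
## detection (binarize -> 10 px square closing -> 8-connected labelling ->
## eccentricity/area filter -> raw-intensity sums) and neurite length per
## nucleus (erode/threshold nuclei, dilate-subtract, skeletonize).

asPlane <- function(img) {
  m <- if (is(img, "Image")) t(EBImage::imageData(img)) else as.matrix(img)
  if (!all(is.finite(m))) stop("image contains non-finite values")
  m
}

#' Nonlinear tanh contrast filter
#'
#' Pre-processing used before nuclei/neurite detection: min-max rescale the
#' image onto [0,1], apply the linear map \eqn{y = m(x - b) + 0.5}, pass
#' through \eqn{\tanh}, and min-max renormalize onto [0,255].  Strictly
#' monotone before the final renormalization, so pixel ordering is
#' preserved.  A constant image has a degenerate min-max rescale and maps
#' to all zeros with a warning.
#'
#' @param img numeric matrix (0-255 scale) or EBImage Image.
#' @param m slope of the linear map (default 2, as used for the red/TUJ1
#'   channel).
#' @param b offset of the linear map (default 0.4).
#' @return numeric matrix on [0,255].
#' @export
tanhContrast <- function(img, m = 2, b = 0.4) {
  stopifnot(m > 0, b >= 0, b <= 1)
  x <- asPlane(img)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant image: min-max rescale degenerate, returning zeros")
    return(array(0, dim(x)))
  }
  x1 <- (x - rng[1]) / (rng[2] - rng[1])
  z <- tanh(m * (x1 - b) + 0.5)
  zr <- range(z)
  (z - zr[1]) / (zr[2] - zr[1]) * 255
}

#' Binarize an image plane
#'
#' Otsu's method by default (the thresholding step is otherwise
#' unspecified in this pipeline's provenance); a fixed level can be given
#' instead for full reproducibility.
#'
#' @param img numeric matrix, 0-255 scale.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param level threshold level for \code{method = "fixed"}; pixels
#'   strictly above it are foreground.
#' @return logical matrix.
#' @export
binarizeImage <- function(img, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  x <- asPlane(img)
  if (method == "fixed") {
    if (is.null(level)) stop("fixed binarization needs a 'level'")
  } else {
    level <- EBImage::otsu(EBImage::Image(x), range = c(0, 255), levels = 256)
  }
  x > level
}

## Binary morphology with a w x w square structuring element.  The mask is
## padded with background before the operation so that pixels beyond the
## canvas are treated as background (EBImage's native border handling
## would otherwise smear objects along the image edge).
morphSquare <- function(mask, width, op = c("close", "erode", "dilate")) {
  op <- match.arg(op)
  kern <- matrix(1L, width, width)
  p <- width + 1L
  padded <- matrix(0, nrow(mask) + 2L * p, ncol(mask) + 2L * p)
  padded[p + seq_len(nrow(mask)), p + seq_len(ncol(mask))] <- mask * 1
  img <- EBImage::Image(padded)
  out <- switch(op,
                close = EBImage::closing(img, kern),
                erode = EBImage::erode(img, kern),
                dilate = EBImage::dilate(img, kern))
  EBImage::imageData(out)[p + seq_len(nrow(mask)),
                          p + seq_len(ncol(mask))] > 0.5
}

#' Label 8-connected foreground regions
#'
#' Connected-component labelling under 8-connectivity (diagonal neighbors
#' join), the convention of the region-property analysis this package
#' reproduces.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background, regions numbered from
#'   1 in first-pixel order).
#' @export
labelRegions <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (!length(fg)) return(labels)
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    ok <- r + s[1] >= 1L & r + s[1] <= nr & c + s[2] >= 1L & c + s[2] <= nc
    p <- fg[ok]
    q <- p + s[1] + s[2] * nr
    keep <- mask[q]
    edges[[k]] <- cbind(match(p[keep], fg), match(q[keep], fg))
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  labels[fg] <- match(memb, unique(memb))  # renumber in first-pixel order
  labels
}

#' Region metrics: area, centroid, eccentricity, summed raw intensity
#'
#' Eccentricity comes from the ellipse with the same normalized second
#' central moments as the region (with the 1/12 unit-pixel variance
#' correction, the regionprops convention): 0 = circle, near 1 = line.
#' Summed intensity is always taken over the \emph{raw} pre-threshold
#' image.
#'
#' @param labels integer label matrix from [labelRegions()].
#' @param raw raw intensity matrix of the same size.
#' @return data.frame with one row per region: \code{label, area,
#'   centroid_row, centroid_col, eccentricity, summed_intensity}.
#' @export
regionMetrics <- function(labels, raw) {
  raw <- asPlane(raw)
  stopifnot(all(dim(labels) == dim(raw)))
  fg <- which(labels > 0)
  if (!length(fg))
    return(data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      eccentricity = numeric(), summed_intensity = numeric()))
  nr <- nrow(labels)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  lab <- labels[fg]
  out <- lapply(split(seq_along(fg), lab), function(i) {
    r <- rr[i]; c <- cc[i]
    rb <- mean(r); cb <- mean(c)
    u20 <- mean((r - rb)^2) + 1/12
    u02 <- mean((c - cb)^2) + 1/12
    u11 <- mean((r - rb) * (c - cb))
    common <- sqrt((u20 - u02)^2 + 4 * u11^2)
    lmax <- (u20 + u02 + common) / 2
    lmin <- (u20 + u02 - common) / 2
    data.frame(label = lab[i][1], area = length(i),
               centroid_row = rb, centroid_col = cb,
               eccentricity = sqrt(max(0, 1 - lmin / lmax)),
               summed_intensity = sum(raw[cbind(r, c)]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$label), , drop = FALSE]
}

#' Detect FRET-positive inclusions
#'
#' The inclusion-calling pipeline: binarize the FRET channel, close
#' morphologically with a square structuring element (default width 10
#' px), label 8-connected regions, and keep regions that are compact
#' (eccentricity < \code{eccMax}, default 0.8) and of plausible size
#' (area in [\code{areaMin}, \code{areaMax}] px, default [4, 1000],
#' bounds inclusive).  Intensities are summed over the raw image.
#'
#' @param raw FRET-channel matrix, 0-255 scale.
#' @param closeWidth closing structuring-element width, px.
#' @param eccMax eccentricity cutoff (exclusive).
#' @param areaMin,areaMax inclusive area bounds, px.
#' @param method,level binarization, see [binarizeImage()].
#' @return data.frame of kept regions (as [regionMetrics()]); the
#'   unfiltered table is attached as \code{attr(, "allRegions")}.
#' @export
detectInclusions <- function(raw, closeWidth = 10L, eccMax = 0.8,
                             areaMin = 4L, areaMax = 1000L,
                             method = c("otsu", "fixed"), level = NULL) {
  stopifnot(areaMin > 0, areaMin <= areaMax, eccMax > 0, eccMax <= 1)
  raw <- asPlane(raw)
  mask <- binarizeImage(raw, method, level)
  if (any(mask)) mask <- morphSquare(mask, closeWidth, "close")
  mets <- regionMetrics(labelRegions(mask), raw)
  keep <- mets[mets$eccentricity < eccMax &
                 mets$area >= areaMin & mets$area <= areaMax, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "allRegions") <- mets
  keep
}

#' Detect nuclei in the blue (DAPI) channel
#'
#' Erodes with a square structuring element, thresholds, and counts
#' 8-connected regions of sufficient area.  (Erosion is applied to the
#' binarized image; with a flat square element this is exactly equivalent
#' to grayscale erosion followed by thresholding.)  Touching nuclei merge
#' into one region - no watershed splitting is attempted.
#'
#' @param blue blue-channel matrix, 0-255 scale (typically after
#'   [tanhContrast()]).
#' @param erodeWidth erosion structuring-element width, px.
#' @param minArea minimum region area after erosion, px.
#' @param method,level binarization, see [binarizeImage()].
#' @return list: \code{mask} (logical matrix of kept nuclei), \code{count},
#'   \code{centroids} (matrix of (row, col)).
#' @export
detectNuclei <- function(blue, erodeWidth = 3L, minArea = 50L,
                         method = c("otsu", "fixed"), level = NULL) {
  blue <- asPlane(blue)
  mask <- binarizeImage(blue, method, level)
  if (any(mask)) mask <- morphSquare(mask, erodeWidth, "erode")
  labels <- labelRegions(mask)
  mets <- regionMetrics(labels, blue)
  kept <- mets[mets$area >= minArea, , drop = FALSE]
  out <- matrix(FALSE, nrow(blue), ncol(blue))
  if (nrow(kept)) out[labels %in% kept$label] <- TRUE
  list(mask = out, count = nrow(kept),
       centroids = as.matrix(kept[c("centroid_row", "centroid_col")]))
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning to a one-pixel-wide, 8-connected
#' medial curve.  One-pixel-wide input curves are fixed points.
#'
#' @param mask logical matrix.
#' @return logical matrix of the skeleton.
#' @export
skeletonize <- function(mask) {
  img <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask > 0
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors clockwise from north: P2..P9
      P <- list(shift(img, -1, 0), shift(img, -1, 1), shift(img, 0, 1),
                shift(img, 1, 1), shift(img, 1, 0), shift(img, 1, -1),
                shift(img, 0, -1), shift(img, -1, -1))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nr, nc)
      for (k in 1:8) {
        nxt <- P[[k %% 8 + 1]]
        A <- A + (!P[[k]] & nxt)
      }
      cond <- img & B >= 2 & B <= 6 & A == 1
      if (step == 1)
        cond <- cond & !(P[[1]] & P[[3]] & P[[5]]) & !(P[[3]] & P[[5]] & P[[7]])
      else
        cond <- cond & !(P[[1]] & P[[3]] & P[[7]]) & !(P[[1]] & P[[5]] & P[[7]])
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

#' Length of a skeleton
#'
#' \code{"geodesic"} (default) sums adjacency steps along the skeleton:
#' orthogonal neighbor pairs count 1, diagonal pairs \eqn{\sqrt 2}, and a
#' diagonal pair that merely shortcuts two orthogonal steps (shares an
#' on-skeleton 4-neighbor) is not double-counted.  This tracks Euclidean
#' length for axis-aligned and 45-degree curves alike.  \code{"pixel"}
#' counts skeleton pixels (one unit each), which undercounts diagonal
#' runs by a factor \eqn{\sqrt 2}.
#'
#' @param skel logical skeleton matrix.
#' @param mode \code{"geodesic"} or \code{"pixel"}.
#' @return length in px.
#' @export
skeletonLength <- function(skel, mode = c("geodesic", "pixel")) {
  mode <- match.arg(mode)
  skel <- skel > 0
  if (mode == "pixel") return(sum(skel))
  nr <- nrow(skel); nc <- ncol(skel)
  at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc &
    skel[cbind(pmax(pmin(r, nr), 1), pmax(pmin(c, nc), 1))]
  fg <- which(skel)
  if (!length(fg)) return(0)
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  len <- 0
  # orthogonal: east and south
  len <- len + sum(at(r, c + 1L)) + sum(at(r + 1L, c))
  # diagonal: south-east and north-east, skipping orthogonal shortcuts
  se <- at(r + 1L, c + 1L) & !at(r + 1L, c) & !at(r, c + 1L)
  ne <- at(r - 1L, c + 1L) & !at(r - 1L, c) & !at(r, c + 1L)
  len + sqrt(2) * (sum(se) + sum(ne))
}

#' Neurite length per nucleus
#'
#' Dilates the nuclei mask with a square structuring element, subtracts it
#' from the binarized neurite (red/TUJ1) channel, skeletonizes what
#' remains, and reports total skeleton length divided by the nucleus
#' count.
#'
#' @param red red-channel matrix, 0-255 scale (typically after
#'   [tanhContrast()]).
#' @param nuclei a [detectNuclei()] result, or a list with elements
#'   \code{mask} and \code{count}.
#' @param dilateWidth nuclei dilation width, px.
#' @param method,level binarization of the red channel, see
#'   [binarizeImage()].
#' @param lengthMode see [skeletonLength()].
#' @return list: \code{total_length} (px), \code{nuclei_count},
#'   \code{length_per_nucleus} (px; NA with a warning when there are no
#'   nuclei).
#' @export
measureNeurites <- function(red, nuclei, dilateWidth = 5L,
                            method = c("otsu", "fixed"), level = NULL,
                            lengthMode = c("geodesic", "pixel")) {
  red <- asPlane(red)
  lengthMode <- match.arg(lengthMode)
  mask <- binarizeImage(red, method, level)
  if (any(nuclei$mask))
    mask <- mask & !morphSquare(nuclei$mask, dilateWidth, "dilate")
  skel <- skeletonize(mask)
  total <- skeletonLength(skel, lengthMode)
  if (nuclei$count < 1L) {
    warning("no nuclei detected: length per nucleus undefined")
    ratio <- NA_real_
  } else ratio <- total / nuclei$count
  list(total_length = total, nuclei_count = nuclei$count,
       length_per_nucleus = ratio)
}

#' Percent of inclusion-positive cells
#'
#' A cell (nucleus) is called inclusion-positive when at least one kept
#' inclusion centroid lies within \code{radius} px of its nucleus
#' centroid - a proximity stand-in for the unavailable cell delineation.
#'
#' @param inclusions kept-region data.frame from [detectInclusions()].
#' @param nuclei a [detectNuclei()] result (needs \code{centroids} and
#'   \code{count}).
#' @param radius assignment radius, px.
#' @return percentage in [0, 100].
#' @export
percentInclusionPositiveCells <- function(inclusions, nuclei, radius = 15) {
  if (nuclei$count < 1L) stop("no nuclei: percentage undefined")
  if (nrow(inclusions) == 0L) return(0)
  ctr <- nuclei$centroids
  pos <- vapply(seq_len(nrow(ctr)), function(i) {
    d <- sqrt((inclusions$centroid_row - ctr[i, 1])^2 +
                (inclusions$centroid_col - ctr[i, 2])^2)
    any(d <= radius)
  }, logical(1))
  100 * sum(pos) / nuclei$count
}
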