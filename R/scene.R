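## Synthetic two-channel microscopy scenes with exact ground truth:
## disk nuclei (blue), 1-px polyline neurites and disk inclusions (red).

## Pixels whose centers lie within `radius` of (row, col); 1-based indices.
rasterizeDisk <- function(nrow, ncol, center, radius) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(nrow, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(ncol, ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  idx <- which(d2 <= radius^2, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

## Bresenham 8-connected line between integer endpoints, inclusive.
rasterizeSegment <- function(p0, p1) {
  x0 <- round(p0[1]); y0 <- round(p0[2])
  x1 <- round(p1[1]); y1 <- round(p1[2])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  n <- max(dx, dy) + 1L
  pts <- matrix(NA_integer_, n, 2L)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    pts[i, ] <- c(x, y)
    if (x == x1 && y == y1) { pts <- pts[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 <  dx) { err <- err + dx; y <- y + sy }
  }
  colnames(pts) <- c("row", "col")
  pts
}

rasterizePolyline <- function(vertices) {
  segs <- lapply(seq_len(nrow(vertices) - 1L), function(i)
    rasterizeSegment(vertices[i, ], vertices[i + 1L, ]))
  unique(do.call(rbind, segs))
}

polylineLength <- function(vertices) {
  d <- diff(vertices)
  sum(sqrt(rowSums(d^2)))
}

#' Render a synthetic two-channel fluorescence scene
#'
#' Draws disk nuclei into the blue (DAPI-like) channel and 1-px-wide
#' neurite polylines plus disk inclusions into the red channel on an 8-bit
#' canvas, adds Gaussian noise, and clips to 0-255 (clipping after noise,
#' as 8-bit acquisition would).  Polylines are hard-rasterized
#' (Bresenham, no anti-aliasing) so skeleton-based length measurements are
#' comparable to the recorded truth.  The returned truth records exact
#' pre-noise counts and the Euclidean polyline lengths.
#'
#' @param height,width canvas size in px.
#' @param nuclei list of \code{list(center = c(row, col), radius)}.
#' @param neurites list of polylines, each an n x 2 matrix of (row, col)
#'   vertices.
#' @param inclusions list of \code{list(center = c(row, col), radius,
#'   intensity)}.
#' @param nucleusIntensity,neuriteIntensity intensities (AU, 0-255 scale).
#' @param background background level, AU.
#' @param noiseSd Gaussian noise SD, AU.
#' @param seed RNG seed.
#' @return list with 8-bit matrices \code{red} and \code{blue} and a
#'   \code{truth} list (\code{n_nuclei, n_inclusions, neurite_length_px,
#'   nuclei, inclusions, neurite_pixels}).
#' @export
renderScene <- function(height, width, nuclei = list(), neurites = list(),
                        inclusions = list(), nucleusIntensity = 200,
                        neuriteIntensity = 200, background = 10,
                        noiseSd = 0, seed = NULL) {
  checkInside <- function(pts, what) {
    if (any(pts[, 1] < 1 | pts[, 1] > height | pts[, 2] < 1 | pts[, 2] > width))
      stop(what, " extends outside the canvas")
    pts
  }
  red <- matrix(background, height, width)
  blue <- matrix(background, height, width)
  for (nu in nuclei) {
    if (nu$center[1] - nu$radius < 1 || nu$center[1] + nu$radius > height ||
        nu$center[2] - nu$radius < 1 || nu$center[2] + nu$radius > width)
      stop("nucleus extends outside the canvas")
    px <- rasterizeDisk(height, width, nu$center, nu$radius)
    blue[px] <- nucleusIntensity
  }
  neuritePx <- vector("list", length(neurites))
  for (i in seq_along(neurites)) {
    px <- checkInside(rasterizePolyline(neurites[[i]]), "neurite")
    red[px] <- neuriteIntensity
    neuritePx[[i]] <- px
  }
  for (inc in inclusions) {
    if (inc$center[1] - inc$radius < 1 || inc$center[1] + inc$radius > height ||
        inc$center[2] - inc$radius < 1 || inc$center[2] + inc$radius > width)
      stop("inclusion extends outside the canvas")
    px <- rasterizeDisk(height, width, inc$center, inc$radius)
    red[px] <- inc$intensity
  }
  truth <- list(
    n_nuclei = length(nuclei),
    n_inclusions = length(inclusions),
    neurite_length_px = if (length(neurites))
      sum(vapply(neurites, polylineLength, numeric(1))) else 0,
    nuclei = nuclei, inclusions = inclusions,
    neurite_pixels = neuritePx)
  withSeed(seed, {
    if (noiseSd > 0) {
      red <- red + rnorm(length(red), 0, noiseSd)
      blue <- blue + rnorm(length(blue), 0, noiseSd)
    }
    list(red = pmin(pmax(red, 0), 255),
         blue = pmin(pmax(blue, 0), 255),
         truth = truth)
  })
}

#' Random scene with well-separated shapes
#'
#' Convenience generator for benchmark scenes: places disk nuclei, disk
#' inclusions and straight neurite segments (axis-aligned or 45 degrees)
#' at random, enforcing a minimum separation so that morphological closing
#' (10 px) cannot merge distinct objects - clean ground truth for detector
#' benchmarking, deliberately simpler than crowded real fields.
#'
#' @param height,width canvas size, px.
#' @param nNuclei,nInclusions,nNeurites object counts.
#' @param nucleusRadius,inclusionRadius radius ranges \code{c(min, max)}.
#' @param neuriteLength neurite segment length range, px.
#' @param minSep minimum center-to-center clearance beyond touching, px.
#' @param noiseSd Gaussian noise SD, AU.
#' @param seed RNG seed.
#' @return as [renderScene()].
#' @export
randomScene <- function(height = 192, width = 192, nNuclei = 3,
                        nInclusions = 3, nNeurites = 2,
                        nucleusRadius = c(6, 9), inclusionRadius = c(3, 8),
                        neuriteLength = c(40, 80), minSep = 14,
                        noiseSd = 2, seed = NULL) {
  withSeed(seed, {
    disks <- matrix(numeric(0), 0, 3)   # row, col, radius
    segs <- list()                      # 2 x 2 vertex matrices
    segPts <- function(v) cbind(seq(v[1, 1], v[2, 1], length.out = 25),
                                seq(v[1, 2], v[2, 2], length.out = 25))
    clear <- function(pts, rad) {
      for (i in seq_len(nrow(disks))) {
        d2 <- (pts[, 1] - disks[i, 1])^2 + (pts[, 2] - disks[i, 2])^2
        if (min(d2) <= (disks[i, 3] + rad + minSep)^2) return(FALSE)
      }
      for (s in segs) {
        sp <- segPts(s)
        d2 <- outer(pts[, 1], sp[, 1], "-")^2 +
          outer(pts[, 2], sp[, 2], "-")^2
        if (min(d2) <= (rad + minSep)^2) return(FALSE)
      }
      TRUE
    }
    # neurites first: long objects are the hardest to fit
    neurites <- lapply(seq_len(nNeurites), function(i) {
      len <- runif(1, neuriteLength[1], neuriteLength[2])
      dir <- sample(list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)), 1)[[1]]
      step <- dir / sqrt(sum(dir^2))
      for (try in 1:2000) {
        p0 <- c(runif(1, 2, height - 1), runif(1, 2, width - 1))
        p1 <- p0 + step * len
        if (all(p1 >= 2 & p1 <= c(height, width) - 1)) {
          v <- rbind(round(p0), round(p1))
          if (clear(segPts(v), 0)) {
            segs[[length(segs) + 1L]] <<- v
            return(v)
          }
        }
      }
      stop("could not place all neurites; reduce counts or lengths")
    })
    placeDisk <- function(radius) {
      margin <- radius + 2
      for (try in 1:2000) {
        p <- c(runif(1, margin + 1, height - margin),
               runif(1, margin + 1, width - margin))
        if (clear(matrix(p, 1), radius)) {
          disks <<- rbind(disks, c(p, radius))
          return(round(p))
        }
      }
      stop("could not place all objects; reduce counts or sizes")
    }
    nuclei <- lapply(seq_len(nNuclei), function(i) {
      r <- runif(1, nucleusRadius[1], nucleusRadius[2])
      list(center = placeDisk(r), radius = r)
    })
    inclusions <- lapply(seq_len(nInclusions), function(i) {
      r <- runif(1, inclusionRadius[1], inclusionRadius[2])
      list(center = placeDisk(r), radius = r,
           intensity = runif(1, 150, 250))
    })
    renderScene(height, width, nuclei, neurites, inclusions,
                noiseSd = noiseSd)
  })
}

#' Write a rendered scene to paired PNGs plus a JSON truth file
#'
#' @param scene a [renderScene()] result.
#' @param prefix output path prefix; writes \code{<prefix>_red.png},
#'   \code{<prefix>_blue.png} and \code{<prefix>_truth.json}.
#' @return invisibly, the three paths.
#' @export
writeScene <- function(scene, prefix) {
  paths <- paste0(prefix, c("_red.png", "_blue.png", "_truth.json"))
  EBImage::writeImage(EBImage::Image(t(scene$red) / 255), paths[1])
  EBImage::writeImage(EBImage::Image(t(scene$blue) / 255), paths[2])
  tr <- scene$truth
  tr$neurite_pixels <- NULL
  jsonlite::write_json(tr, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read one image channel into an 8-bit matrix
#'
#' @param path PNG/TIFF path (single channel or first channel taken).
#' @return numeric matrix on the 0-255 scale, rows = image rows.
#' @export
readImageChannel <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3L) img <- img[, , 1L]
  t(EBImage::imageData(img)) * 255
}
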