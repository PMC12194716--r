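#' @include AllClasses.R utils.R raster-io.R homogeneity.R
NULL

# Vectorized point-in-convex-polygon test (vertices in consistent winding
# order); pixel centers at integer (x = col, y = row).
pointsInPoly <- function(px, py, poly) {
  nv <- rrow <- nrow(poly)
  nxt <- c(seq_len(nv)[-1L], 1L)
  # polygon winding via the shoelace sum
  sgn <- sign(sum(poly[, 1L] * poly[nxt, 2L] - poly[nxt, 1L] * poly[, 2L]))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(nv)) {
    j <- nxt[i]
    cr <- (poly[j, 1L] - poly[i, 1L]) * (py - poly[i, 2L]) -
          (poly[j, 2L] - poly[i, 2L]) * (px - poly[i, 1L])
    inside <- inside & (cr * sgn >= 0)
  }
  inside
}

# Paint an image from a label matrix and a CIELab palette, optionally with
# per-channel Gaussian noise and Gaussian-blurred (soft) region transitions.
# Blurring is applied to the per-region indicator weights, not the labels,
# so tones blend gradually at boundaries; clipped to nominal Lab ranges.
paintRegions <- function(labels, palette, noise = 0, softness = 0) {
  M <- nrow(labels); N <- ncol(labels)
  ids <- sort(unique(as.vector(labels)))
  arr <- array(0, c(M, N, 3L))
  if (softness > 0) {
    wsum <- matrix(0, M, N)
    wlist <- lapply(ids, function(g) gaussBlur((labels == g) * 1, softness))
    wsum <- Reduce(`+`, wlist)
    for (i in seq_along(ids))
      for (ch in 1:3)
        arr[, , ch] <- arr[, , ch] + wlist[[i]] / wsum * palette[i, ch]
  } else {
    for (i in seq_along(ids))
      for (ch in 1:3)
        arr[, , ch] <- arr[, , ch] + (labels == ids[i]) * palette[i, ch]
  }
  if (noise > 0)
    arr <- arr + array(stats::rnorm(length(arr), sd = noise), dim(arr))
  RasterImage(clipLab(arr), "cielab")
}

.CUBE_PALETTE <- matrix(c(
   80,  15,  55,    # top face: light orange
   60,  30,  60,    # right face: mid orange
   40,  25,  45,    # left face: dark orange-brown
   75,  -5, -25,    # upper background: light blue
   55,  -2, -35),   # lower background: darker blue
  ncol = 3L, byrow = TRUE,
  dimnames = list(c("top", "right", "left", "bg_upper", "bg_lower"),
                  c("L", "a", "b")))

#' Five-region cube fixture
#'
#' An isometric cube (three visible faces in an orange palette family) on a
#' background split into two blueish areas: five ground-truth regions whose
#' CIELab tones are pairwise more than 20 units apart, used to study how
#' the cluster count r drives the smoothing. Depending on the reading it
#' contains two (cube/background), four, or five distinct regions.
#'
#' @param size image side in pixels (square, >= 8).
#' @param palette 5 x 3 CIELab tone matrix, rows = top/right/left face,
#'   upper/lower background.
#' @param noise per-channel Gaussian noise sd in CIELab units; the default
#'   0 gives the clean piecewise-constant rendering of a synthetic test
#'   figure (each region internally a single tone).
#' @param seed RNG seed (noise only; the geometry is deterministic).
#' @return list with elements \code{image} (CIELab [RasterImage-class]),
#'   \code{labels} ([RegionPartition-class], 1 = top face, 2 = right,
#'   3 = left, 4 = upper background, 5 = lower background) and
#'   \code{palette}.
#' @examples
#' fx <- cubeFixture(size = 32, noise = 0)
#' table(values(fx$labels))
#' @export
cubeFixture <- function(size = 128L, palette = .CUBE_PALETTE, noise = 0,
                        seed = 1L) {
  stopifnot(size >= 8L)
  if (is.null(dim(palette)) || nrow(palette) < 5L)
    stop("cube palette needs 5 tones (3 faces + 2 background areas)")
  cx <- (size + 1) / 2; cy <- (size + 1) / 2
  s <- 0.31 * size
  u <- c(sqrt(3) / 2, -0.5) * s     # screen x right-up
  v <- c(-sqrt(3) / 2, -0.5) * s    # screen x left-up
  w <- c(0, 1) * s                  # down
  C0 <- c(cx, cy)
  quad <- function(p, q) rbind(C0, C0 + p, C0 + p + q, C0 + q)
  px <- rep(seq_len(size), each = size)   # x = col
  py <- rep(seq_len(size), times = size)  # y = row
  lab <- matrix(0L, size, size)
  lab[pointsInPoly(px, py, quad(u, v))] <- 1L   # top
  lab[pointsInPoly(px, py, quad(u, w))] <- 2L   # right
  lab[pointsInPoly(px, py, quad(v, w))] <- 3L   # left
  bg <- lab == 0L
  lab[bg & row(lab) <= cy] <- 4L
  lab[bg & row(lab) > cy] <- 5L
  img <- withSeed(seed, paintRegions(lab, palette[1:5, , drop = FALSE],
                                     noise = noise))
  list(image = img, labels = regionPartition(lab),
       palette = palette[1:5, , drop = FALSE])
}

.PINK  <- c(L = 70, a = 45, b = -5)
.GREEN <- c(L = 65, a = -40, b = 30)
.GREEN2 <- c(L = 78, a = -30, b = 42)   # lighter green for speckle

#' Two-region spatial-coherence fixtures
#'
#' Three pink/green test images with identical tonal content but different
#' spatial structure, used to study the spatio-tonal weight alpha:
#' \describe{
#'   \item{A}{spatially coherent: a compact pink disc whose rim blends
#'     gradually into the green background (Gaussian-blurred transition).}
#'   \item{B}{partially coherent: the same compact pink disc, but the
#'     green background is an incoherent speckle of two green tones.}
#'   \item{C}{spatially incoherent: the pink pixels are scattered uniformly
#'     over the grid (exactly \code{round(pinkFraction * size^2)} of them),
#'     with no spatial structure at all.}
#' }
#'
#' @param kind \code{"A"}, \code{"B"} or \code{"C"}.
#' @param size image side in pixels.
#' @param pinkFraction target fraction of pink pixels for kind C.
#' @param softness Gaussian blur sd (pixels) of the rim transition (kind A).
#' @param seed RNG seed.
#' @return list with \code{image}, \code{labels} (1 = pink region,
#'   2 = green region) and \code{palette}.
#' @export
coherenceFixture <- function(kind = c("A", "B", "C"), size = 128L,
                             pinkFraction = 0.3, softness = 2, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(size >= 8L)
  palette <- rbind(pink = .PINK, green = .GREEN)
  radius <- 0.32 * size
  cx <- (size + 1) / 2
  dist2 <- (row(matrix(0, size, size)) - cx)^2 +
           (col(matrix(0, size, size)) - cx)^2
  withSeed(seed, {
    if (kind == "A") {
      lab <- matrix(2L, size, size)
      lab[dist2 <= radius^2] <- 1L
      img <- paintRegions(lab, palette, softness = softness)
    } else if (kind == "B") {
      lab <- matrix(2L, size, size)
      lab[dist2 <= radius^2] <- 1L
      arr <- values(paintRegions(lab, palette))
      speckle <- matrix(stats::runif(size * size) < 0.5, size, size) &
        lab == 2L
      for (ch in 1:3) {
        p <- arr[, , ch]
        p[speckle] <- .GREEN2[ch]
        arr[, , ch] <- p
      }
      img <- RasterImage(clipLab(arr), "cielab")
    } else {
      nPink <- round(pinkFraction * size * size)
      lab <- matrix(2L, size, size)
      lab[sample.int(size * size, nPink)] <- 1L
      img <- paintRegions(lab, palette)
    }
    list(image = img, labels = regionPartition(lab), palette = palette)
  })
}

#' Blob-deposit fixture
#'
#' Emulates immunohistochemistry patches: a light-bluish textured
#' background carrying 1-3 darker brownish blobs ("deposits") whose
#' boundaries are Gaussian-blurred into gradual transitions and whose
#' interiors share the background's unstructured speckle texture. The
#' returned labels are the crisp pre-blur geometry (1 = background,
#' 2 = deposit).
#'
#' @param size image side in pixels.
#' @param nBlobs number of blobs (1-3).
#' @param contrast CIELab distance between background and deposit tones.
#' @param radiusRange blob radius range as fractions of \code{size}.
#' @param blurRadius Gaussian blur sd (pixels) applied to the blob mask.
#' @param textureSd per-channel speckle noise sd in CIELab units.
#' @param seed RNG seed.
#' @return list with \code{image}, \code{labels} and \code{palette} (rows
#'   \code{background}, \code{deposit}).
#' @export
blobFixture <- function(size = 128L, nBlobs = 2L, contrast = 30,
                        radiusRange = c(0.10, 0.18), blurRadius = 1.5,
                        textureSd = 2.5, seed = 1L) {
  stopifnot(size >= 8L, nBlobs >= 1L, nBlobs <= 3L, contrast >= 0)
  bg <- c(L = 78, a = -2, b = -12)
  dirn <- c(-0.85, 0.40, 0.35)
  dirn <- dirn / sqrt(sum(dirn^2))
  deposit <- bg + contrast * dirn     # darker, brownish
  maxR <- max(radiusRange) * size
  if (maxR + 2 > size - maxR - 1) stop("blob area exceeds the image")
  withSeed(seed, {
    lab <- matrix(1L, size, size)
    rows <- row(lab); cols <- col(lab)
    for (b in seq_len(nBlobs)) {
      r <- stats::runif(1, radiusRange[1L], radiusRange[2L]) * size
      ccx <- stats::runif(1, r + 2, size - r - 1)
      ccy <- stats::runif(1, r + 2, size - r - 1)
      ecc <- stats::runif(1, 0.75, 1)     # mild ellipticity
      lab[((rows - ccy)^2) / ecc + ((cols - ccx)^2) * ecc <= r^2] <- 2L
    }
    soft <- gaussBlur((lab == 2L) * 1, blurRadius)
    arr <- array(0, c(size, size, 3L))
    for (ch in 1:3)
      arr[, , ch] <- (1 - soft) * bg[ch] + soft * deposit[ch]
    if (textureSd > 0)
      arr <- arr + array(stats::rnorm(length(arr), sd = textureSd),
                         dim(arr))
    list(image = RasterImage(clipLab(arr), "cielab"),
         labels = regionPartition(lab),
         palette = rbind(background = bg, deposit = deposit))
  })
}

#' Generate a fixture by name
#'
#' Dispatcher used by the command-line interface: \code{"cube"},
#' \code{"coherence-A"}, \code{"coherence-B"}, \code{"coherence-C"} or
#' \code{"blob-deposit"}.
#'
#' @param kind fixture kind.
#' @param size image side in pixels.
#' @param noise noise level (cube: tone noise sd; blob: texture sd;
#'   ignored by the coherence fixtures); NULL uses each generator's
#'   default.
#' @param seed RNG seed.
#' @param ... passed on to the specific generator.
#' @return list with \code{image} and \code{labels}.
#' @export
makeFixture <- function(kind, size = 128L, noise = NULL, seed = 1L, ...) {
  switch(kind,
    "cube" = if (is.null(noise))
        cubeFixture(size = size, seed = seed, ...)
      else cubeFixture(size = size, noise = noise, seed = seed, ...),
    "coherence-A" = coherenceFixture("A", size = size, seed = seed, ...),
    "coherence-B" = coherenceFixture("B", size = size, seed = seed, ...),
    "coherence-C" = coherenceFixture("C", size = size, seed = seed, ...),
    "blob-deposit" = if (is.null(noise))
        blobFixture(size = size, seed = seed, ...)
      else blobFixture(size = size, textureSd = noise, seed = seed, ...),
    stop("unknown fixture kind '", kind, "'"))
}
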