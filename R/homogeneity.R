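#' @include AllClasses.R AllGenerics.R utils.R raster-io.R
NULL

#' @describeIn localHomogeneity the homogeneity matrix.
#' @export
setMethod("values", "HomogeneityMap", function(x) x@values)

setMethod("show", "HomogeneityMap", function(object) {
  cat(sprintf(
    "HomogeneityMap: %d x %d, window radius n = %d (%s), mean H = %.4f\n",
    nrow(object@values), ncol(object@values), object@n, object@mode,
    mean(object@values)))
})

#' Construct a RegionPartition
#'
#' @param labels integer matrix of per-pixel region labels.
#' @return a [RegionPartition-class].
#' @export
regionPartition <- function(labels) {
  storage.mode(labels) <- "integer"
  new("RegionPartition", labels = labels)
}

#' @describeIn regionPartition the label matrix.
#' @param x a RegionPartition.
#' @export
setMethod("values", "RegionPartition", function(x) x@labels)

setMethod("show", "RegionPartition", function(object) {
  tb <- table(object@labels)
  cat(sprintf("RegionPartition: %d x %d, %d region(s): %s\n",
              nrow(object@labels), ncol(object@labels), length(tb),
              paste(sprintf("%s (%d px)", names(tb), tb), collapse = ", ")))
})

.homogeneityChannel <- function(mat, n) {
  1 - windowExtrema(mat, n, "max") + windowExtrema(mat, n, "min")
}

#' Local homogeneity map of a unit-normalized channel
#'
#' \eqn{H_I(x,y) = 1 - \bigvee I(x+i,y+j) + \bigwedge I(x+i,y+j)} over the
#' \code{(2n+1) x (2n+1)} window; positions outside the grid are excluded
#' from both extrema (no padding). H is 1 on flat patches and 0 across a
#' full-contrast edge. Input channels must already lie in [0,1] — pass the
#' image through [normalizeUnit()] first, which uses fixed nominal channel
#' ranges so maps from different iterations stay comparable. This is a
#' descriptive statistic of the smoothing process, not a standalone quality
#' metric.
#'
#' @param img a \code{unit}-tagged single-channel [RasterImage-class], or a
#'   numeric matrix with values in [0,1].
#' @param n window radius in pixels (default 2, a 5x5 window).
#' @return a [HomogeneityMap-class].
#' @examples
#' flat <- RasterImage(matrix(0.4, 8, 8), "unit")
#' all(values(localHomogeneity(flat, 1)) == 1)
#' @export
localHomogeneity <- function(img, n = 2L) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  if (is(img, "RasterImage")) {
    if (colorSpace(img) != "unit")
      stop("localHomogeneity needs unit-normalized input; ",
           "call normalizeUnit() first")
    if (nChannels(img) != 1L)
      stop("localHomogeneity is single-channel; ",
           "use multichannelHomogeneity()")
    mat <- values(img)[, , 1L]
  } else {
    mat <- as.matrix(img)
    if (min(mat) < 0 || max(mat) > 1)
      stop("localHomogeneity needs values in [0,1]")
  }
  new("HomogeneityMap", values = .homogeneityChannel(mat, n), n = n,
      mode = "single")
}

#' Multichannel local homogeneity
#'
#' The arithmetic mean of the per-channel homogeneity maps,
#' \eqn{H^*_I = k^{-1} \sum_i H_{I_i}}. For k = 1 it coincides with
#' [localHomogeneity()].
#'
#' @inheritParams localHomogeneity
#' @param img a \code{unit}-tagged [RasterImage-class] (any k).
#' @return a [HomogeneityMap-class].
#' @export
multichannelHomogeneity <- function(img, n = 2L) {
  n <- as.integer(n)
  stopifnot(is(img, "RasterImage"), n >= 0L)
  if (colorSpace(img) != "unit")
    stop("multichannelHomogeneity needs unit-normalized input; ",
         "call normalizeUnit() first")
  a <- values(img); k <- dim(a)[3L]
  H <- matrix(0, dim(a)[1L], dim(a)[2L])
  for (ch in seq_len(k)) H <- H + .homogeneityChannel(a[, , ch], n)
  new("HomogeneityMap", values = H / k, n = n,
      mode = if (k == 1L) "single" else "multichannel-average")
}

#' Boundary band of a region partition
#'
#' The set of pixels within distance \code{floor(w/2)} (Chebyshev by
#' default) of an inter-region label change, giving a band of width w
#' centered on the boundary; w = 7 reproduces a seven-pixel-wide boundary
#' band. A label change is marked on the first pixel of each differing
#' 4-adjacent pair (in scan order), so a straight boundary between two
#' half-planes yields exactly w full pixel rows/columns.
#'
#' @param partition a [RegionPartition-class].
#' @param w band width in pixels (w = 0 or a uniform partition give an
#'   empty band).
#' @param geometry \code{"chebyshev"} (square neighborhoods, matching the
#'   windowed homogeneity operator) or \code{"euclidean"}.
#' @return logical matrix mask (TRUE inside the band).
#' @export
edgeBand <- function(partition, w = 7L, geometry = c("chebyshev",
                                                     "euclidean")) {
  stopifnot(is(partition, "RegionPartition"), w >= 0L)
  geometry <- match.arg(geometry)
  lab <- partition@labels
  M <- nrow(lab); N <- ncol(lab)
  if (w == 0L) return(matrix(FALSE, M, N))
  boundary <- matrix(FALSE, M, N)
  if (M > 1L)
    boundary[-M, ] <- boundary[-M, ] | (lab[-M, ] != lab[-1L, ])
  if (N > 1L)
    boundary[, -N] <- boundary[, -N] | (lab[, -N] != lab[, -1L])
  dil <- if (geometry == "chebyshev") chebyshevDilate else euclideanDilate
  dil(boundary, as.integer(floor(w / 2)))
}

#' Mean homogeneity per region and in the boundary band
#'
#' Summarises a homogeneity map over (a) each labelled region excluding the
#' boundary band and (b) the band itself — the quantities used to check
#' that smoothing regularises region interiors while preserving (not
#' homogenising) the boundaries.
#'
#' @param H a [HomogeneityMap-class].
#' @param partition a [RegionPartition-class] of the same grid.
#' @param band logical band mask, typically from [edgeBand()]; NULL for no
#'   band (regions summarised whole).
#' @return a data.frame with columns \code{region} (label, or
#'   \code{"band"}), \code{mean_homogeneity} (NA for a region emptied by
#'   the band) and \code{n_pixels}.
#' @export
regionMeanHomogeneity <- function(H, partition, band = NULL) {
  stopifnot(is(H, "HomogeneityMap"), is(partition, "RegionPartition"))
  h <- values(H); lab <- values(partition)
  if (!identical(dim(h), dim(lab)))
    stop("homogeneity map and partition shapes differ")
  if (is.null(band)) band <- matrix(FALSE, nrow(h), ncol(h))
  if (!identical(dim(band), dim(h))) stop("band mask shape differs")
  out <- lapply(sort(unique(as.vector(lab))), function(g) {
    sel <- lab == g & !band
    if (!any(sel)) {
      message("region ", g, " is empty after band exclusion")
      return(data.frame(region = as.character(g), mean_homogeneity = NA_real_,
                        n_pixels = 0L))
    }
    data.frame(region = as.character(g), mean_homogeneity = mean(h[sel]),
               n_pixels = sum(sel))
  })
  out <- do.call(rbind, out)
  rbind(out, data.frame(
    region = "band",
    mean_homogeneity = if (any(band)) mean(h[band]) else NA_real_,
    n_pixels = sum(band)))
}

#' Homogeneity report over a smoothing trace
#'
#' Computes the multichannel homogeneity map of selected iterations of a
#' trace and summarises it per region and boundary band; the tabular
#' counterpart of inspecting the homogeneity maps visually.
#'
#' @param trace a [SmoothingTrace-class].
#' @param partition ground-truth [RegionPartition-class].
#' @param iterations iterations to evaluate (default: 0 and the final one).
#' @param n homogeneity window radius.
#' @param bandWidth boundary band width in pixels.
#' @return a data.frame with columns \code{iteration}, \code{region},
#'   \code{mean_homogeneity}, \code{n_pixels}.
#' @export
homogeneityReport <- function(trace, partition, iterations = NULL,
                              n = 2L, bandWidth = 7L) {
  stopifnot(is(trace, "SmoothingTrace"))
  Tmax <- length(trace@images) - 1L
  if (is.null(iterations)) iterations <- unique(c(0L, Tmax))
  band <- edgeBand(partition, bandWidth)
  do.call(rbind, lapply(iterations, function(t) {
    H <- multichannelHomogeneity(
      normalizeUnit(iterationImage(trace, t)), n)
    cbind(iteration = t, regionMeanHomogeneity(H, partition, band))
  }))
}
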