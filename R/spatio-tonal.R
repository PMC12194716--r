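#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Registered component metrics. Each entry is a function (A, B) -> numeric
# taking two conformable matrices (rows = points) and returning rowwise
# distances. "euclidean" is the recommended choice for both the spatial and
# the tonal component; the registry is the hook for alternatives.
.metricRegistry <- new.env(parent = emptyenv())
assign("euclidean",
       function(A, B) sqrt(rowSums((A - B)^2)),
       envir = .metricRegistry)

#' Register a component metric
#'
#' Adds a named rowwise metric usable as the spatial or tonal component of
#' the spatio-tonal distance. The function must accept two numeric matrices
#' with identical dimensions (one point per row) and return the vector of
#' rowwise distances.
#'
#' @param id identifier to register under.
#' @param fn the metric function.
#' @return \code{id}, invisibly.
#' @export
registerMetric <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  assign(id, fn, envir = .metricRegistry)
  invisible(id)
}

resolveMetric <- function(id) get(id, envir = .metricRegistry)

#' Construct a MetricSpec
#'
#' @param alpha spatio-tonal weight in [0,1]; 1 = tonal only, 0 = spatial
#'   only (content-unaware).
#' @param spatial,tonal identifiers of registered component metrics.
#' @return a [MetricSpec-class].
#' @examples
#' metricSpec(alpha = 0.5)
#' @export
metricSpec <- function(alpha = 1, spatial = "euclidean",
                       tonal = "euclidean") {
  new("MetricSpec", spatial = spatial, tonal = tonal, alpha = alpha)
}

setMethod("show", "MetricSpec", function(object) {
  cat(sprintf("MetricSpec: alpha = %g (tonal '%s', spatial '%s')\n",
              object@alpha, object@tonal, object@spatial))
})

#' Map a CIELab image into the spatio-tonal dataset
#'
#' Every pixel becomes an instance (x, y, t1, ..., tk): spatial coordinates
#' are 0-based pixel positions divided by a common divisor so they land in
#' [0,1] with the aspect ratio preserved; tonal values are copied unchanged
#' in CIELab units. Spatial and tonal information come in very different
#' scales, so the divisor convention is explicit and overridable.
#'
#' @param img a CIELab-tagged [RasterImage-class].
#' @param divisor \code{"max-dim"} (default: divide both axes by
#'   \code{max(M,N)}), \code{"per-axis"} (divide x by N, y by M), or
#'   \code{"none"} (raw 0-based pixel indices — spatial coordinates then
#'   exceed [0,1] and are stored unscaled).
#' @return a [SpatioTonalDataset-class].
#' @examples
#' img <- RasterImage(array(50, c(2, 3, 3)), "cielab")
#' ds <- imageToDataset(img)
#' head(values(ds))
#' @export
imageToDataset <- function(img, divisor = c("max-dim", "per-axis", "none")) {
  stopifnot(is(img, "RasterImage"))
  if (colorSpace(img) != "cielab")
    stop("imageToDataset expects a CIELab image; call toCielab() first")
  divisor <- match.arg(divisor)
  d <- dim(img); M <- d[1L]; N <- d[2L]; k <- d[3L]
  if (M * N == 0L) stop("empty image")
  row <- rep(seq_len(M) - 1L, times = N)   # y, 0-based
  col <- rep(seq_len(N) - 1L, each = M)    # x, 0-based
  div <- switch(divisor,
    "max-dim"  = c(max(M, N), max(M, N)),
    "per-axis" = c(max(N - 1L, 1L), max(M - 1L, 1L)),
    "none"     = c(1L, 1L))
  xy <- cbind(x = col / div[1L], y = row / div[2L])
  tones <- matrix(values(img), nrow = M * N, ncol = k)
  colnames(tones) <- if (k == 3L) c("L", "a", "b") else "L"
  new("SpatioTonalDataset", data = cbind(xy, tones),
      gridDim = c(M, N), divisor = as.numeric(div))
}

#' @describeIn imageToDataset rebuild the image from the tonal columns —
#'   exact inverse of the mapping (spatial scaling does not touch tones).
#' @param ds a [SpatioTonalDataset-class].
#' @export
datasetToImage <- function(ds) {
  stopifnot(is(ds, "SpatioTonalDataset"))
  M <- ds@gridDim[1L]; N <- ds@gridDim[2L]
  k <- ncol(ds@data) - 2L
  RasterImage(array(ds@data[, -(1:2)], c(M, N, k)), "cielab")
}

#' @describeIn imageToDataset instance matrix (one row per pixel).
#' @param x a SpatioTonalDataset.
#' @export
setMethod("values", "SpatioTonalDataset", function(x) x@data)

#' @describeIn imageToDataset number of instances and columns.
#' @export
setMethod("dim", "SpatioTonalDataset", function(x) dim(x@data))

setMethod("show", "SpatioTonalDataset", function(object) {
  cat(sprintf(
    "SpatioTonalDataset: %d instances (%d x %d grid), %d tonal channel(s)\n",
    nrow(object@data), object@gridDim[1L], object@gridDim[2L],
    ncol(object@data) - 2L))
})

#' Export a spatio-tonal dataset as a delimited text table
#'
#' @param ds a [SpatioTonalDataset-class].
#' @param path output path (tab-separated, with header).
#' @return \code{path}, invisibly.
#' @export
exportDataset <- function(ds, path) {
  utils::write.table(values(ds), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Component and combined spatio-tonal distances
#'
#' \code{spatialDistance} and \code{tonalDistance} are the Euclidean
#' component metrics on normalized positions and CIELab tones;
#' \code{spatioTonalDistance} fuses them as the convex combination
#' \code{alpha * tonal + (1 - alpha) * spatial}, which is itself a metric
#' for every alpha in [0,1]. All three are vectorized over rows.
#'
#' @param a,b numeric vectors (one point) or matrices (one point per row):
#'   spatial parts for \code{spatialDistance}, tonal parts for
#'   \code{tonalDistance}, full (2+k)-column instances for
#'   \code{spatioTonalDistance}.
#' @param spec a [MetricSpec-class].
#' @param k number of tonal columns in the instances (default: all but the
#'   first two).
#' @return numeric vector of distances.
#' @examples
#' spatialDistance(c(0, 0), c(0.6, 0.8))        # 1
#' tonalDistance(c(0, 0, 0), c(3, 4, 0))        # 5
#' spatioTonalDistance(c(0, 0, 0, 0, 0), c(0.6, 0.8, 3, 4, 0),
#'                     metricSpec(alpha = 0.5)) # 3
#' @export
spatialDistance <- function(a, b, spec = metricSpec()) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1L)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1L)
  stopifnot(ncol(a) == 2L, ncol(b) == 2L)
  resolveMetric(spec@spatial)(a, b)
}

#' @rdname spatialDistance
#' @export
tonalDistance <- function(a, b, spec = metricSpec()) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1L)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1L)
  if (ncol(a) != ncol(b))
    stop("tonal vectors must have the same dimension")
  resolveMetric(spec@tonal)(a, b)
}

#' @rdname spatialDistance
#' @export
spatioTonalDistance <- function(a, b, spec = metricSpec(), k = NULL) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1L)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1L)
  if (is.null(k)) k <- ncol(a) - 2L
  stopifnot(k >= 1L, ncol(a) == 2L + k, ncol(b) == 2L + k)
  al <- spec@alpha
  dtau   <- resolveMetric(spec@tonal)(a[, -(1:2), drop = FALSE],
                                      b[, -(1:2), drop = FALSE])
  domega <- resolveMetric(spec@spatial)(a[, 1:2, drop = FALSE],
                                        b[, 1:2, drop = FALSE])
  al * dtau + (1 - al) * domega
}
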