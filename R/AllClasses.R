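#' @import methods
NULL

.COLORSPACES <- c("srgb", "cielab", "unit")

#' RasterImage: a pixel grid with a colorspace tag
#'
#' Container for the images being smoothed. Pixel values are stored as an
#' \code{M x N x k} numeric array (rows = y, columns = x, k = 1 or 3
#' channels) together with a colorspace tag that the pipeline uses to keep
#' conversions explicit: \code{"srgb"} (values in [0,1]), \code{"cielab"}
#' (L in [0,100], a and b in [-128,127]) or \code{"unit"} (every channel
#' affinely mapped into [0,1], the form the homogeneity operator requires).
#'
#' @slot data numeric array of dimension \code{c(M, N, k)}.
#' @slot colorspace one of \code{"srgb"}, \code{"cielab"}, \code{"unit"}.
#'
#' @seealso [rasterImage()], [toCielab()], [normalizeUnit()], [readRaster()]
#' @export
setClass("RasterImage",
  representation(data = "array", colorspace = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
      return("data must be an M x N x k array")
    k <- dim(d)[3L]
    if (!k %in% c(1L, 3L))
      return("channel count k must be 1 or 3")
    if (!all(is.finite(d)))
      return("all pixel values must be finite")
    cs <- object@colorspace
    if (length(cs) != 1L || !cs %in% .COLORSPACES)
      return(sprintf("colorspace must be one of: %s",
                     paste(.COLORSPACES, collapse = ", ")))
    if (cs %in% c("unit", "srgb") && (min(d) < 0 || max(d) > 1))
      return(sprintf("%s values must lie in [0,1]", cs))
    if (cs == "cielab") {
      if (min(d[, , 1L]) < 0 || max(d[, , 1L]) > 100)
        return("CIELab L channel must lie in [0,100]")
      if (k == 3L && (min(d[, , 2:3]) < -128 || max(d[, , 2:3]) > 127))
        return("CIELab a,b channels must lie in [-128,127]")
    }
    TRUE
  })

#' SpatioTonalDataset: an image viewed as a clustering dataset
#'
#' One row per pixel: columns 1-2 hold the normalized spatial coordinates
#' (x, y), scaled by a common divisor (by default \code{1/max(M,N)} so the
#' aspect ratio is preserved and coordinates lie in [0,1]); the remaining k
#' columns hold the tonal values in native CIELab units. Rows are ordered
#' column-major (R's native order), so row \code{(col-1)*M + row} is pixel
#' \code{(row, col)} — a bijection onto the pixel grid.
#'
#' @slot data numeric matrix, \code{M*N} rows, \code{2+k} columns.
#' @slot gridDim integer vector \code{c(M, N)}.
#' @slot divisor the spatial scaling divisor actually used.
#'
#' @seealso [imageToDataset()], [datasetToImage()]
#' @export
setClass("SpatioTonalDataset",
  representation(data = "matrix", gridDim = "integer", divisor = "numeric"),
  validity = function(object) {
    M <- object@gridDim[1L]; N <- object@gridDim[2L]
    if (nrow(object@data) != M * N)
      return("row count must equal M*N")
    if (ncol(object@data) < 3L)
      return("dataset needs 2 spatial + at least 1 tonal column")
    sp <- object@data[, 1:2, drop = FALSE]
    if (!all(is.finite(object@data)) || min(sp) < 0)
      return("spatial coordinates must be finite and non-negative")
    # [0,1] holds under the scaled divisor conventions; divisor "none"
    # deliberately keeps raw pixel indices
    if (all(object@divisor > 1) && max(sp) > 1)
      return("scaled spatial coordinates must lie in [0,1]")
    TRUE
  })

#' MetricSpec: the spatio-tonal metric
#'
#' The distance used throughout the clustering is the convex combination
#' \eqn{d_\psi(a,b) = \alpha\, d_\tau(\hat a,\hat b) +
#' (1-\alpha)\, d_\omega(\tilde a,\tilde b)} of a tonal metric on the CIELab
#' components and a spatial metric on the normalized positions. \code{alpha}
#' in [0,1] sets the relative weight: 1 clusters by color alone, 0 ignores
#' color entirely (content-unaware). Both component metrics default to
#' Euclidean; other metrics can be registered with [registerMetric()].
#'
#' @slot spatial identifier of the spatial metric.
#' @slot tonal identifier of the tonal metric.
#' @slot alpha spatio-tonal weight in [0,1].
#'
#' @seealso [metricSpec()], [spatioTonalDistance()]
#' @export
setClass("MetricSpec",
  representation(spatial = "character", tonal = "character",
                 alpha = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
        object@alpha < 0 || object@alpha > 1)
      return("alpha must be a single value in [0,1]")
    for (id in c(object@spatial, object@tonal))
      if (!id %in% names(.metricRegistry))
        return(sprintf("unknown metric identifier '%s'", id))
    TRUE
  })

#' CentroidSet: cluster centroids in the spatio-tonal universe
#'
#' r centroids, each a point with 2 spatial + k tonal components, tracked
#' across iterations. The tonal part (columns 3..2+k) is what paints the
#' reconstructed images.
#'
#' @slot points numeric matrix, r rows, 2+k columns (same layout as the
#'   dataset).
#' @slot iter iteration index the set belongs to (0 = initialization).
#'
#' @seealso [forgyInit()], [updateCentroids()], [tonalPart()]
#' @export
setClass("CentroidSet",
  representation(points = "matrix", iter = "integer"),
  validity = function(object) {
    if (nrow(object@points) < 1L) return("need r >= 1 centroids")
    if (!all(is.finite(object@points)))
      return("all centroid components must be finite")
    TRUE
  })

#' MembershipField: per-pixel fuzzy memberships
#'
#' r membership maps over the pixel grid forming a Ruspini partition: every
#' value lies in [0,1] and per-pixel memberships sum to 1 (within 1e-9).
#' Stored as an \code{M*N x r} matrix in the same row order as the dataset.
#'
#' @slot values numeric matrix, \code{M*N} rows, r columns.
#' @slot gridDim integer vector \code{c(M, N)}.
#' @slot iter iteration index.
#'
#' @seealso [updateMemberships()], [reconstructImage()]
#' @export
setClass("MembershipField",
  representation(values = "matrix", gridDim = "integer", iter = "integer"),
  validity = function(object) {
    U <- object@values
    if (nrow(U) != prod(object@gridDim))
      return("membership rows must equal M*N")
    if (min(U) < -1e-12 || max(U) > 1 + 1e-12)
      return("memberships must lie in [0,1]")
    if (max(abs(rowSums(U) - 1)) > 1e-9)
      return("memberships must sum to 1 per pixel (Ruspini partition)")
    TRUE
  })

#' SmoothingConfig: parameters of a smoothing run
#'
#' @slot r number of clusters = number of distinct regions the user sees in
#'   the image.
#' @slot metric a [MetricSpec-class].
#' @slot delta convergence tolerance on the mean inter-iteration tonal
#'   difference, in CIELab units; \code{delta = 0} disables the convergence
#'   test so the run goes to the iteration cap (used by the experiment
#'   drivers that need an exact number of iterations).
#' @slot m fuzzifier exponent (> 1) of the fuzzy c-means updates.
#' @slot maxIter iteration cap.
#' @slot seed integer seed for the run's random generator (Forgy draw and
#'   any empty-cluster re-seeding).
#' @slot initCentroids optional explicit initial centroid matrix (r rows,
#'   2+k columns); when non-empty it replaces the Forgy draw.
#'
#' @seealso [smoothingConfig()], [runSfcm()]
#' @export
setClass("SmoothingConfig",
  representation(r = "integer", metric = "MetricSpec", delta = "numeric",
                 m = "numeric", maxIter = "integer", seed = "integer",
                 initCentroids = "matrix"),
  validity = function(object) {
    if (object@r < 1L) return("r must be >= 1")
    if (object@delta < 0) return("delta must be >= 0")
    if (object@m <= 1) return("fuzzifier m must be > 1")
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    TRUE
  })

#' SmoothingTrace: the full record of a smoothing run
#'
#' Holds the sequence of reconstructed images I0..IT, the per-iteration
#' difference values v_t = Phi(I_t, I_{t-1}), per-iteration centroid
#' snapshots, and why the run stopped.
#'
#' @slot images list of \code{M x N x k} CIELab arrays, I0 first.
#' @slot diffs numeric vector of v values (length T).
#' @slot centroids list of centroid matrices (C0 first).
#' @slot memberships list of membership matrices, possibly empty (kept only
#'   when requested — they are the largest part of a trace).
#' @slot termination \code{"converged"} or \code{"cap-reached"}.
#' @slot config the [SmoothingConfig-class] that produced the trace.
#' @slot gridDim integer vector \code{c(M, N)}.
#'
#' @seealso [runSfcm()], [finalImage()], [iterationImage()]
#' @export
setClass("SmoothingTrace",
  representation(images = "list", diffs = "numeric", centroids = "list",
                 memberships = "list", termination = "character",
                 config = "SmoothingConfig", gridDim = "integer"),
  validity = function(object) {
    if (!object@termination %in% c("converged", "cap-reached"))
      return("termination must be 'converged' or 'cap-reached'")
    if (length(object@images) != length(object@diffs) + 1L)
      return("images must be one longer than diffs (I0 has no diff)")
    TRUE
  })

#' HomogeneityMap: per-pixel local homogeneity
#'
#' Values in [0,1]: 1 on flat patches, 0 across full-contrast edges within
#' the \code{(2n+1) x (2n+1)} window.
#'
#' @slot values numeric matrix (same grid as the source image).
#' @slot n window radius in pixels.
#' @slot mode \code{"single"} or \code{"multichannel-average"}.
#'
#' @seealso [localHomogeneity()], [multichannelHomogeneity()]
#' @export
setClass("HomogeneityMap",
  representation(values = "matrix", n = "integer", mode = "character"),
  validity = function(object) {
    if (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-12)
      return("homogeneity values must lie in [0,1]")
    if (object@n < 0L) return("window radius n must be >= 0")
    TRUE
  })

#' RegionPartition: ground-truth or hardened region labels
#'
#' Integer label per pixel; labels cover the whole grid. Used both as
#' fixture ground truth and as the hardened (max-membership) output of a
#' smoothing run.
#'
#' @slot labels integer matrix, M x N.
#'
#' @seealso [edgeBand()], [regionMeanHomogeneity()], [hardenPartition()]
#' @export
setClass("RegionPartition",
  representation(labels = "matrix"),
  validity = function(object) {
    if (!is.numeric(object@labels))
      return("labels must be an integer matrix")
    if (any(!is.finite(object@labels)))
      return("labels must be finite")
    TRUE
  })
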