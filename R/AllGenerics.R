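#' @include AllClasses.R
NULL

#' Convert an image to CIELab
#'
#' @param img a [RasterImage-class].
#' @return a CIELab-tagged [RasterImage-class] (k = 3).
#' @export
setGeneric("toCielab", function(img) standardGeneric("toCielab"))

#' Map every channel affinely into [0,1]
#'
#' Uses the FIXED nominal channel ranges (CIELab: L/100, (a+128)/255,
#' (b+128)/255; sRGB is already [0,1]) rather than per-image extrema, so
#' homogeneity values stay comparable across the iteration sequence.
#'
#' @param img a [RasterImage-class] tagged \code{srgb} or \code{cielab}.
#' @return a \code{unit}-tagged [RasterImage-class].
#' @export
setGeneric("normalizeUnit", function(img) standardGeneric("normalizeUnit"))

#' Tonal part of a centroid set
#'
#' @param x a [CentroidSet-class].
#' @return matrix of the tonal columns (r x k).
#' @export
setGeneric("tonalPart", function(x) standardGeneric("tonalPart"))

#' Number of channels of an image
#' @param x a [RasterImage-class].
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Colorspace tag of an image
#' @param x a [RasterImage-class].
#' @export
setGeneric("colorSpace", function(x) standardGeneric("colorSpace"))

#' Extract the raw numeric values of an object
#' @param x a package object holding pixel-grid values.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Final (most-smoothed) image of a trace
#' @param x a [SmoothingTrace-class].
#' @export
setGeneric("finalImage", function(x) standardGeneric("finalImage"))

#' Image at a given iteration of a trace
#' @param x a [SmoothingTrace-class].
#' @param t iteration index (0 = initial reconstruction).
#' @export
setGeneric("iterationImage", function(x, t) standardGeneric("iterationImage"))

#' Per-iteration convergence statistic v_t = Phi(I_t, I_{t-1})
#' @param x a [SmoothingTrace-class].
#' @export
setGeneric("convergenceDiffs", function(x) standardGeneric("convergenceDiffs"))

#' Why a smoothing run stopped
#' @param x a [SmoothingTrace-class].
#' @return \code{"converged"} or \code{"cap-reached"}.
#' @export
setGeneric("terminationReason",
           function(x) standardGeneric("terminationReason"))

#' Harden a fuzzy result into a crisp region partition
#'
#' Assigns each pixel to its maximum-membership cluster. This is
#' segmentation, not smoothing — provided for evaluating how well the
#' clusters track ground-truth regions, not as part of the smoothing
#' pipeline.
#'
#' @param x a [MembershipField-class] or [SmoothingTrace-class].
#' @param ... unused.
#' @return a [RegionPartition-class].
#' @export
setGeneric("hardenPartition", function(x, ...) standardGeneric("hardenPartition"))
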