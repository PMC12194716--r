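#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a RasterImage
#'
#' @param data numeric array \code{M x N x k} (a plain matrix is treated as
#'   a single-channel image).
#' @param colorspace \code{"srgb"}, \code{"cielab"} or \code{"unit"}.
#' @return a [RasterImage-class].
#' @examples
#' img <- RasterImage(array(0.5, c(4, 4, 3)), "srgb")
#' dim(img)
#' @export
RasterImage <- function(data, colorspace = "srgb") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("RasterImage", data = data, colorspace = colorspace)
}

#' @describeIn RasterImage dimensions \code{c(M, N, k)}.
#' @param x a RasterImage.
#' @export
setMethod("dim", "RasterImage", function(x) dim(x@data))

#' @describeIn RasterImage raw pixel array.
#' @export
setMethod("values", "RasterImage", function(x) x@data)

#' @describeIn RasterImage number of channels.
#' @export
setMethod("nChannels", "RasterImage", function(x) dim(x@data)[3L])

#' @describeIn RasterImage colorspace tag.
#' @export
setMethod("colorSpace", "RasterImage", function(x) x@colorspace)

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("RasterImage: %d x %d pixels, %d channel(s), colorspace '%s'\n",
              d[1L], d[2L], d[3L], object@colorspace))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

.readers <- list(
  png  = function(p) png::readPNG(p),
  tif  = function(p) tiff::readTIFF(p),
  tiff = function(p) tiff::readTIFF(p),
  jpg  = function(p) jpeg::readJPEG(p),
  jpeg = function(p) jpeg::readJPEG(p)
)

#' Read a raster image from a PNG, TIFF or JPEG file
#'
#' Integer samples are rescaled to real values in [0,1] by the underlying
#' reader. An alpha channel, if present, is dropped. Grayscale files yield
#' k = 1; RGB files k = 3, tagged \code{srgb}.
#'
#' @param path file path; format chosen by extension.
#' @return a [RasterImage-class] tagged \code{srgb}.
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  reader <- .readers[[ext]]
  if (is.null(reader))
    stop("unsupported image format '.", ext, "' (PNG, TIFF, JPEG supported)")
  arr <- reader(path)
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  k <- dim(arr)[3L]
  if (k == 2L) arr <- arr[, , 1L, drop = FALSE]          # gray + alpha
  else if (k == 4L) arr <- arr[, , 1:3, drop = FALSE]    # RGBA
  else if (!k %in% c(1L, 3L))
    stop("unsupported channel count (", k, "); only grayscale and RGB")
  RasterImage(clip(arr, 0, 1), "srgb")
}

#' Write a raster image to PNG, TIFF or JPEG
#'
#' CIELab images are converted back to sRGB at write time (out-of-gamut
#' values are clipped to [0,1]); \code{unit} and \code{srgb} images are
#' written as-is.
#'
#' @param img a [RasterImage-class].
#' @param path output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
writeRaster <- function(img, path) {
  stopifnot(is(img, "RasterImage"))
  arr <- if (colorSpace(img) == "cielab") values(labToSrgb(img)) else
    values(img)
  if (dim(arr)[3L] == 1L) arr <- arr[, , 1L]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(arr, path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(arr, path, quality = 0.98),
    stop("unsupported output format '.", ext, "'"))
  invisible(path)
}

#' Write the image sequence of a smoothing trace
#'
#' Writes \code{iter_0000.png, iter_0001.png, ...} (I0 first).
#'
#' @param trace a [SmoothingTrace-class].
#' @param dir output directory (created if missing).
#' @param every keep every \code{every}-th iteration (I0 and the final
#'   image are always written).
#' @param prefix filename prefix.
#' @return character vector of paths written, invisibly.
#' @export
writeTraceImages <- function(trace, dir, every = 1L, prefix = "iter_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- seq_along(trace@images) - 1L
  keep <- idx %% every == 0L | idx == max(idx)
  paths <- character(0)
  for (t in idx[keep]) {
    p <- file.path(dir, sprintf("%s%04d.png", prefix, t))
    writeRaster(iterationImage(trace, t), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname toCielab
#' @details Grayscale images are lifted to luminance-only CIELab as
#'   \code{(100 * gray, 0, 0)}, so one metric and reconstruction path serves
#'   both k = 1 and k = 3. sRGB is converted under the D65/2-degree standard
#'   observer.
setMethod("toCielab", "RasterImage", function(img) {
  cs <- colorSpace(img)
  if (cs == "cielab") {
    warning("image is already in CIELab; returning unchanged")
    return(img)
  }
  if (cs == "unit")
    stop("cannot convert a unit-normalized image to CIELab; ",
         "keep the srgb/cielab original")
  d <- dim(img)
  if (d[3L] == 1L) {
    lab <- array(0, c(d[1L], d[2L], 3L))
    lab[, , 1L] <- 100 * values(img)[, , 1L]
  } else {
    a <- values(img)
    px <- cbind(as.vector(a[, , 1L]), as.vector(a[, , 2L]),
                as.vector(a[, , 3L]))
    labpx <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
    lab <- array(0, c(d[1L], d[2L], 3L))
    for (ch in 1:3) lab[, , ch] <- matrix(labpx[, ch], d[1L], d[2L])
  }
  out <- clipLab(lab)
  if (max(abs(out - lab)) > 1e-8)
    message("toCielab: out-of-range values clipped to nominal CIELab ranges")
  RasterImage(out, "cielab")
})

#' Convert a CIELab image back to sRGB
#'
#' Inverse of [toCielab()] for in-gamut colors (D65/2-degree observer);
#' out-of-gamut results are clipped to [0,1].
#'
#' @param img a CIELab-tagged [RasterImage-class].
#' @return an sRGB-tagged [RasterImage-class].
#' @export
labToSrgb <- function(img) {
  stopifnot(is(img, "RasterImage"), colorSpace(img) == "cielab")
  d <- dim(img)
  if (d[3L] == 1L)    # luminance-only Lab: invert the grayscale lift
    return(RasterImage(values(img) / 100, "srgb"))
  a <- values(img)
  px <- cbind(as.vector(a[, , 1L]), as.vector(a[, , 2L]),
              as.vector(a[, , 3L]))
  rgbpx <- grDevices::convertColor(px, from = "Lab", to = "sRGB")
  rgbpx <- clip(rgbpx, 0, 1)
  arr <- array(0, c(d[1L], d[2L], 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(rgbpx[, ch], d[1L], d[2L])
  RasterImage(arr, "srgb")
}

.LAB_OFFSET <- c(0, 128, 128)
.LAB_SCALE  <- c(100, 255, 255)

#' @rdname normalizeUnit
setMethod("normalizeUnit", "RasterImage", function(img) {
  cs <- colorSpace(img)
  if (cs == "unit") return(img)          # idempotent
  arr <- values(img)
  if (cs == "cielab") {
    for (ch in seq_len(dim(arr)[3L]))
      arr[, , ch] <- (arr[, , ch] + .LAB_OFFSET[ch]) / .LAB_SCALE[ch]
  }
  cl <- clip(arr, 0, 1)
  if (max(abs(cl - arr)) > 1e-12)
    message("normalizeUnit: values outside the nominal range were clipped")
  RasterImage(cl, "unit")
})
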