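#' @include AllClasses.R AllGenerics.R spatio-tonal.R reconstruction.R
NULL

#' Construct a SmoothingConfig
#'
#' @param r number of clusters; set it to the number of distinct regions
#'   you see in the image.
#' @param alpha spatio-tonal weight in [0,1] (1 = tonal only).
#' @param delta convergence tolerance on the mean inter-iteration tonal
#'   difference, in CIELab units; 0 runs to the iteration cap.
#' @param m fuzzifier (> 1); 2 is the customary fuzzy c-means default.
#' @param maxIter iteration cap.
#' @param seed seed of the run's random generator.
#' @param spatial,tonal component metric identifiers (see
#'   [registerMetric()]).
#' @param initCentroids optional explicit initial centroid matrix (r rows,
#'   2+k columns) replacing the Forgy draw.
#' @return a [SmoothingConfig-class].
#' @examples
#' smoothingConfig(r = 2, alpha = 0.5)
#' @export
smoothingConfig <- function(r, alpha = 1, delta = 0.05, m = 2,
                            maxIter = 200L, seed = 1L,
                            spatial = "euclidean", tonal = "euclidean",
                            initCentroids = NULL) {
  if (is.null(initCentroids)) initCentroids <- matrix(numeric(0), 0L, 0L)
  new("SmoothingConfig", r = as.integer(r),
      metric = metricSpec(alpha = alpha, spatial = spatial, tonal = tonal),
      delta = as.numeric(delta), m = as.numeric(m),
      maxIter = as.integer(maxIter), seed = as.integer(seed),
      initCentroids = initCentroids)
}

setMethod("show", "SmoothingConfig", function(object) {
  cat(sprintf(
    "SmoothingConfig: r = %d, alpha = %g, delta = %g, m = %g, maxIter = %d, seed = %d\n",
    object@r, object@metric@alpha, object@delta, object@m, object@maxIter,
    object@seed))
})

#' Forgy initialization of the centroid set
#'
#' Draws r distinct instances of the dataset uniformly without replacement
#' and uses them as the initial centroids. The draw uses the current RNG
#' stream when \code{seed = NULL} (as inside [runSfcm()], which owns one
#' seeded stream per run); passing a seed makes the call self-contained and
#' reproducible.
#'
#' @param data a [SpatioTonalDataset-class].
#' @param r number of centroids, \code{1 <= r <=} number of instances.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return a [CentroidSet-class] at iteration 0.
#' @export
forgyInit <- function(data, r, seed = NULL) {
  stopifnot(is(data, "SpatioTonalDataset"))
  n <- nrow(values(data))
  if (r < 1L) stop("r must be >= 1")
  if (r > n) stop("r (", r, ") cannot exceed the number of pixels (", n, ")")
  draw <- function() sort(sample.int(n, r))
  idx <- if (is.null(seed)) draw() else withSeed(seed, draw())
  new("CentroidSet", points = values(data)[idx, , drop = FALSE], iter = 0L)
}

# Distance of every instance to every centroid under the spatio-tonal
# metric: |Omega| x r matrix.
centroidDistances <- function(X, Cpts, spec) {
  n <- nrow(X); r <- nrow(Cpts)
  sp <- resolveMetric(spec@spatial); to <- resolveMetric(spec@tonal)
  al <- spec@alpha
  D <- matrix(0, n, r)
  Xsp <- X[, 1:2, drop = FALSE]; Xto <- X[, -(1:2), drop = FALSE]
  for (i in seq_len(r)) {
    Csp <- matrix(Cpts[i, 1:2], n, 2L, byrow = TRUE)
    Cto <- matrix(Cpts[i, -(1:2)], n, ncol(Xto), byrow = TRUE)
    D[, i] <- al * to(Xto, Cto) + (1 - al) * sp(Xsp, Csp)
  }
  D
}

#' Fuzzy membership update
#'
#' Standard fuzzy c-means membership formula under the spatio-tonal metric:
#' \eqn{\mu_i(p) = [\sum_j (d_\psi(p,C_i)/d_\psi(p,C_j))^{2/(m-1)}]^{-1}}.
#' When a pixel is at distance exactly 0 from one or more centroids, its
#' membership is split equally over the zero-distance centroids and is 0
#' elsewhere, which preserves the Ruspini partition symmetrically.
#'
#' @param data a [SpatioTonalDataset-class].
#' @param C a [CentroidSet-class].
#' @param spec a [MetricSpec-class].
#' @param m fuzzifier (> 1).
#' @return a [MembershipField-class] (Ruspini: per-pixel sums are 1).
#' @export
updateMemberships <- function(data, C, spec = metricSpec(), m = 2) {
  stopifnot(is(data, "SpatioTonalDataset"), is(C, "CentroidSet"), m > 1)
  if (!all(is.finite(C@points))) stop("non-finite centroid")
  D <- centroidDistances(values(data), C@points, spec)
  E <- D^(-2 / (m - 1))
  U <- E / rowSums(E)
  bad <- which(!is.finite(rowSums(U)))   # rows hit by a zero distance
  if (length(bad)) {
    Z <- D[bad, , drop = FALSE] == 0
    U[bad, ] <- Z / rowSums(Z)
  }
  new("MembershipField", values = U, gridDim = data@gridDim,
      iter = C@iter)
}

#' Fuzzy centroid update
#'
#' Standard fuzzy c-means centroid step over the full spatio-tonal
#' coordinates: \eqn{C_i = \sum_p \mu_i(p)^m p / \sum_p \mu_i(p)^m}. Every
#' updated centroid lies in the componentwise convex hull of the dataset.
#' A cluster whose total membership mass underflows is re-seeded from a
#' uniformly random instance (drawn from the current RNG stream), keeping r
#' fixed at the user's declared region count.
#'
#' @param data a [SpatioTonalDataset-class].
#' @param U a [MembershipField-class].
#' @param m fuzzifier (> 1).
#' @return a [CentroidSet-class] at iteration \code{U@iter + 1}.
#' @export
updateCentroids <- function(data, U, m = 2) {
  stopifnot(is(data, "SpatioTonalDataset"), is(U, "MembershipField"))
  X <- values(data)
  W <- values(U)^m
  mass <- colSums(W)
  empty <- which(mass < 1e-12)
  Cpts <- crossprod(W, X) / mass          # r x (2+k)
  if (length(empty)) {
    message("re-seeding ", length(empty), " empty cluster(s)")
    idx <- sample.int(nrow(X), length(empty))
    Cpts[empty, ] <- X[idx, , drop = FALSE]
  }
  new("CentroidSet", points = Cpts, iter = U@iter + 1L)
}

#' Mean pixel-to-pixel tonal difference between two images
#'
#' \eqn{\Phi(A,B) = |\Omega|^{-1} \sum_{(x,y)} d_\tau(A(x,y), B(x,y))}: the
#' average per-pixel tonal distance, used both as the convergence statistic
#' of the smoothing loop and to compare runs started from different
#' initializations. Symmetric, and 0 iff the images are tonally identical.
#'
#' @param A,B [RasterImage-class] objects with identical dimensions and
#'   colorspace.
#' @param spec a [MetricSpec-class] supplying the tonal metric.
#' @return a single non-negative number (CIELab units for CIELab images).
#' @export
imageDifference <- function(A, B, spec = metricSpec()) {
  stopifnot(is(A, "RasterImage"), is(B, "RasterImage"))
  if (!identical(dim(A), dim(B)))
    stop("images must have identical dimensions")
  if (colorSpace(A) != colorSpace(B))
    stop("images must share a colorspace")
  k <- dim(A)[3L]
  a <- matrix(values(A), ncol = k); b <- matrix(values(B), ncol = k)
  mean(resolveMetric(spec@tonal)(a, b))
}

# Phi on raw arrays (internal fast path of the smoothing loop).
arrayDifference <- function(a, b, k) {
  mean(sqrt(rowSums((matrix(a, ncol = k) - matrix(b, ncol = k))^2)))
}

#' Run the content-aware smoothing loop
#'
#' The full pipeline: the image is converted to CIELab and mapped into the
#' spatio-tonal dataset; r initial centroids are drawn by Forgy
#' initialization; initial memberships and the reconstruction I0 are
#' computed; then each iteration updates the centroids, updates the
#' memberships, reconstructs I_t, and evaluates
#' v = Phi(I_t, I_{t-1}). The loop stops when v <= delta (a non-trivial
#' converged state: the image settles on r region tones instead of flat
#' gray) or when the iteration cap is reached.
#'
#' The centroid update precedes the membership update within an iteration,
#' and the initial memberships are computed from the Forgy centroids before
#' the loop. All randomness (Forgy draw, empty-cluster re-seeding) comes
#' from one generator seeded with \code{config@seed}, so the same
#' configuration reproduces the trace bit-identically.
#'
#' @param img a [RasterImage-class] (sRGB, grayscale or CIELab).
#' @param config a [SmoothingConfig-class].
#' @param keepMemberships keep per-iteration membership snapshots in the
#'   trace (memory-heavy; off by default).
#' @param divisor spatial scaling convention, see [imageToDataset()].
#' @param verbose print one line per iteration (t, v, centroid tones).
#' @return a [SmoothingTrace-class].
#' @examples
#' img <- RasterImage(array(c(rep(20, 128), rep(80, 128)), c(16, 16, 1)),
#'                    "cielab")
#' tr <- runSfcm(img, smoothingConfig(r = 2, alpha = 1, seed = 1))
#' terminationReason(tr)
#' @export
runSfcm <- function(img, config, keepMemberships = FALSE,
                    divisor = "max-dim", verbose = FALSE) {
  stopifnot(is(img, "RasterImage"), is(config, "SmoothingConfig"))
  if (colorSpace(img) != "cielab")
    img <- suppressWarnings(toCielab(img))
  data <- imageToDataset(img, divisor = divisor)
  k <- ncol(values(data)) - 2L
  spec <- config@metric
  m <- config@m

  withSeed(config@seed, {
    C <- if (nrow(config@initCentroids)) {
      stopifnot(ncol(config@initCentroids) == 2L + k,
                nrow(config@initCentroids) == config@r)
      new("CentroidSet", points = config@initCentroids, iter = 0L)
    } else forgyInit(data, config@r)
    U <- updateMemberships(data, C, spec, m)
    I0 <- values(reconstructImage(U, C))

    images <- list(I0)
    diffs <- numeric(0)
    centroids <- list(C@points)
    # always retain at least the final memberships (needed to harden the
    # result); with keepMemberships every iteration is kept
    memberships <- list(values(U))

    v <- Inf; t <- 0L
    while (v > config@delta && t < config@maxIter) {
      t <- t + 1L
      C <- updateCentroids(data, U, m)
      U <- updateMemberships(data, C, spec, m)
      It <- values(reconstructImage(U, C))
      v <- arrayDifference(It, images[[t]], k)
      images[[t + 1L]] <- It
      diffs[t] <- v
      centroids[[t + 1L]] <- C@points
      if (keepMemberships) memberships[[t + 1L]] <- values(U)
      else memberships[[1L]] <- values(U)
      if (verbose)
        cat(sprintf("iter %4d  v = %.6f  tones: %s\n", t, v,
                    paste(apply(round(tonalPart(C), 2), 1L,
                                paste, collapse = ","),
                          collapse = " | ")))
    }
    term <- if (v <= config@delta) "converged" else "cap-reached"
    if (term == "cap-reached")
      message("iteration cap reached before v <= delta (v = ",
              format(v), ")")
    new("SmoothingTrace", images = images, diffs = diffs,
        centroids = centroids, memberships = memberships,
        termination = term, config = config, gridDim = data@gridDim)
  })
}

#' @rdname finalImage
setMethod("finalImage", "SmoothingTrace", function(x)
  iterationImage(x, length(x@images) - 1L))

#' @rdname iterationImage
setMethod("iterationImage", "SmoothingTrace", function(x, t) {
  stopifnot(t >= 0L, t <= length(x@images) - 1L)
  RasterImage(x@images[[t + 1L]], "cielab")
})

#' @rdname convergenceDiffs
setMethod("convergenceDiffs", "SmoothingTrace", function(x) x@diffs)

#' @rdname terminationReason
setMethod("terminationReason", "SmoothingTrace", function(x) x@termination)

setMethod("show", "SmoothingTrace", function(object) {
  cat(sprintf(
    "SmoothingTrace: %d iterations (%s), %d x %d grid, r = %d, alpha = %g\n",
    length(object@images) - 1L, object@termination, object@gridDim[1L],
    object@gridDim[2L], object@config@r, object@config@metric@alpha))
  if (length(object@diffs))
    cat(sprintf("  final v = %.6g (delta = %g)\n",
                utils::tail(object@diffs, 1L), object@config@delta))
})

#' @rdname hardenPartition
setMethod("hardenPartition", "MembershipField", function(x, ...) {
  lab <- max.col(x@values, ties.method = "first")
  new("RegionPartition",
      labels = matrix(as.integer(lab), x@gridDim[1L], x@gridDim[2L]))
})

#' @rdname hardenPartition
#' @details For a \code{SmoothingTrace} the final iteration's memberships
#'   are used (a trace always retains at least those).
setMethod("hardenPartition", "SmoothingTrace", function(x, ...) {
  U <- new("MembershipField",
           values = x@memberships[[length(x@memberships)]],
           gridDim = x@gridDim, iter = length(x@images) - 1L)
  hardenPartition(U)
})
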