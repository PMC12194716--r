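#' @include AllClasses.R AllGenerics.R spatio-tonal.R
NULL

#' @rdname tonalPart
setMethod("tonalPart", "CentroidSet",
          function(x) x@points[, -(1:2), drop = FALSE])

setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: r = %d centroids at iteration %d\n",
              nrow(object@points), object@iter))
  print(round(object@points, 3))
})

#' @describeIn updateMemberships membership matrix (pixels x clusters).
#' @export
setMethod("values", "MembershipField", function(x) x@values)

setMethod("show", "MembershipField", function(object) {
  cat(sprintf(
    "MembershipField: %d x %d grid, r = %d clusters, iteration %d\n",
    object@gridDim[1L], object@gridDim[2L], ncol(object@values),
    object@iter))
})

#' Reconstruct the iteration image from memberships and centroid tones
#'
#' Each pixel is painted with the membership-weighted convex combination of
#' the centroid tonal parts: \eqn{I_t(x,y) = \sum_i \mu_{t,i}(q)\,
#' \hat C_{t,i}}. Only the tonal components of the centroids are used, and
#' because memberships form a Ruspini partition every output tone lies in
#' the convex hull of the centroid tones. A pixel fully owned by one
#' cluster takes that centroid's color exactly.
#'
#' @param U a [MembershipField-class].
#' @param C a [CentroidSet-class] with matching r.
#' @return a CIELab-tagged [RasterImage-class].
#' @export
reconstructImage <- function(U, C) {
  stopifnot(is(U, "MembershipField"), is(C, "CentroidSet"))
  if (ncol(U@values) != nrow(C@points))
    stop("membership field and centroid set disagree on r")
  tones <- U@values %*% tonalPart(C)            # (MN x r) (r x k)
  M <- U@gridDim[1L]; N <- U@gridDim[2L]
  RasterImage(clipLab(array(tones, c(M, N, ncol(tones)))), "cielab")
}
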