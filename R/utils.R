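#' @include AllClasses.R
NULL

# Evaluate expr under a temporary, seeded RNG stream; the caller's RNG
# state is untouched. One such stream serves a whole smoothing run.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Clip a CIELab array into the nominal channel ranges.
clipLab <- function(arr) {
  arr[, , 1L] <- clip(arr[, , 1L], 0, 100)
  if (dim(arr)[3L] == 3L)
    arr[, , 2:3] <- clip(arr[, , 2:3], -128, 127)
  arr
}

# Windowed extrema over the (2n+1)^2 neighborhood with out-of-grid
# positions excluded (no padding): shift-and-compare over in-grid overlaps.
windowExtrema <- function(mat, n, op = c("max", "min")) {
  op <- match.arg(op)
  M <- nrow(mat); N <- ncol(mat)
  acc <- matrix(if (op == "max") -Inf else Inf, M, N)
  f <- if (op == "max") pmax else pmin
  for (di in -n:n) {
    r1 <- max(1L, 1L + di); r2 <- min(M, M + di)   # destination rows
    if (r1 > r2) next
    for (dj in -n:n) {
      c1 <- max(1L, 1L + dj); c2 <- min(N, N + dj)
      if (c1 > c2) next
      acc[r1:r2, c1:c2] <-
        f(acc[r1:r2, c1:c2], mat[(r1:r2) - di, (c1:c2) - dj])
    }
  }
  acc
}

# Separable Gaussian blur with border renormalization (kernel mass falling
# outside the grid is dropped and the remainder rescaled, so flat inputs
# stay flat up to the border). Used only by the fixture generators.
gaussBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  blur1d <- function(m) {       # along rows (dimension 1)
    M <- nrow(m); N <- ncol(m)
    num <- matrix(0, M, N); den <- matrix(0, M, N)
    for (i in seq_along(k)) {
      d <- i - h - 1L
      r1 <- max(1L, 1L + d); r2 <- min(M, M + d)
      if (r1 > r2) next
      num[r1:r2, ] <- num[r1:r2, ] + k[i] * m[(r1:r2) - d, , drop = FALSE]
      den[r1:r2, ] <- den[r1:r2, ] + k[i]
    }
    num / den
  }
  t(blur1d(t(blur1d(mat))))
}

# Chebyshev dilation of a logical mask by integer radius.
chebyshevDilate <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  M <- nrow(mask); N <- ncol(mask)
  out <- matrix(FALSE, M, N)
  for (di in -radius:radius) {
    r1 <- max(1L, 1L + di); r2 <- min(M, M + di)
    if (r1 > r2) next
    for (dj in -radius:radius) {
      c1 <- max(1L, 1L + dj); c2 <- min(N, N + dj)
      if (c1 > c2) next
      out[r1:r2, c1:c2] <-
        out[r1:r2, c1:c2] | mask[(r1:r2) - di, (c1:c2) - dj]
    }
  }
  out
}

# Euclidean dilation (disc structuring element) — alternative band geometry.
euclideanDilate <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  M <- nrow(mask); N <- ncol(mask)
  out <- matrix(FALSE, M, N)
  for (di in -radius:radius) {
    r1 <- max(1L, 1L + di); r2 <- min(M, M + di)
    if (r1 > r2) next
    for (dj in -radius:radius) {
      if (di * di + dj * dj > radius * radius) next
      c1 <- max(1L, 1L + dj); c2 <- min(N, N + dj)
      if (c1 > c2) next
      out[r1:r2, c1:c2] <-
        out[r1:r2, c1:c2] | mask[(r1:r2) - di, (c1:c2) - dj]
    }
  }
  out
}
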