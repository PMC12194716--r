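# Independent oracles, coded with explicit loops and textbook formulas so
# they share no code path with the package implementation.

# Reference sRGB (D65, 2 degree observer) -> CIELab conversion, scalar math.
refSrgbToLab <- function(rgb) {
  lin <- vapply(rgb, function(c)
    if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4, 0)
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  wn <- c(0.95047, 1, 1.08883)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / wn[1]); fy <- f(Y / wn[2]); fz <- f(Z / wn[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Brute-force spatio-tonal distance of one instance to one centroid.
oracleDist <- function(p, cen, alpha) {
  dsp <- sqrt(sum((p[1:2] - cen[1:2])^2))
  dto <- sqrt(sum((p[-(1:2)] - cen[-(1:2)])^2))
  alpha * dto + (1 - alpha) * dsp
}

# Double-loop fuzzy c-means membership update.
oracleMemberships <- function(X, C, alpha, m) {
  n <- nrow(X); r <- nrow(C)
  U <- matrix(0, n, r)
  for (p in seq_len(n)) {
    d <- vapply(seq_len(r), function(i) oracleDist(X[p, ], C[i, ], alpha), 0)
    if (any(d == 0)) {
      U[p, d == 0] <- 1 / sum(d == 0)
    } else {
      for (i in seq_len(r))
        U[p, i] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
    }
  }
  U
}

# Double-loop centroid update over the full spatio-tonal coordinates.
oracleCentroids <- function(X, U, m) {
  r <- ncol(U)
  C <- matrix(0, r, ncol(X))
  for (i in seq_len(r)) {
    num <- rep(0, ncol(X)); den <- 0
    for (p in seq_len(nrow(X))) {
      w <- U[p, i]^m
      num <- num + w * X[p, ]
      den <- den + w
    }
    C[i, ] <- num / den
  }
  C
}

# Per-pixel reconstruction from centroid tonal parts.
oracleReconstruct <- function(U, C, gridDim, k) {
  tones <- matrix(0, nrow(U), k)
  for (p in seq_len(nrow(U)))
    for (i in seq_len(ncol(U)))
      tones[p, ] <- tones[p, ] + U[p, i] * C[i, -(1:2)]
  array(tones, c(gridDim, k))
}

# Brute-force local homogeneity (explicit window scan, grid-clipped).
oracleHomogeneity <- function(mat, n) {
  M <- nrow(mat); N <- ncol(mat)
  H <- matrix(0, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    win <- mat[max(1, i - n):min(M, i + n), max(1, j - n):min(N, j + n)]
    H[i, j] <- 1 - max(win) + min(win)
  }
  H
}

# Random in-range CIELab test image.
randomLabImage <- function(M, N, seed) {
  withr::with_seed(seed, {
    arr <- array(0, c(M, N, 3))
    arr[, , 1] <- runif(M * N, 5, 95)
    arr[, , 2] <- runif(M * N, -60, 60)
    arr[, , 3] <- runif(M * N, -60, 60)
    RasterImage(arr, "cielab")
  })
}
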