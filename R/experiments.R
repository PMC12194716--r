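#' @include AllClasses.R sfcm.R fixtures.R
NULL

#' Count distinct tones of an image after rounding
#'
#' Rounds every channel to the nearest multiple of \code{rounding} (0.5
#' CIELab units by default) and counts unique pixel tones — the measure
#' used to check that a converged run paints at most r distinct region
#' tones.
#'
#' @param img a [RasterImage-class].
#' @param rounding rounding quantum per channel.
#' @return integer count of distinct rounded tones.
#' @export
distinctToneCount <- function(img, rounding = 0.5) {
  stopifnot(is(img, "RasterImage"))
  k <- dim(img)[3L]
  tones <- round(matrix(values(img), ncol = k) / rounding) * rounding
  nrow(unique(tones))
}

# All injective assignments of pred labels onto truth labels (truth side
# may be larger); returns best-matching agreement fraction.
.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

#' Best-matching agreement between two region partitions
#'
#' Fraction of pixels on which the two label maps agree under the best
#' one-to-one relabelling (brute force over label permutations; intended
#' for small label counts, r <= 7). Used to compare a hardened clustering
#' output with fixture ground truth.
#'
#' @param pred,truth [RegionPartition-class] objects on the same grid.
#' @return agreement fraction in [0,1].
#' @export
partitionAgreement <- function(pred, truth) {
  p <- as.vector(values(pred)); g <- as.vector(values(truth))
  stopifnot(length(p) == length(g))
  pl <- sort(unique(p)); gl <- sort(unique(g))
  if (length(pl) > 8L || length(gl) > 8L)
    stop("brute-force matching supports at most 8 labels")
  tab <- table(factor(g, gl), factor(p, pl))
  if (length(pl) <= length(gl)) {
    best <- 0
    for (perm in .permutations(seq_along(gl))) {
      sel <- perm[seq_along(pl)]
      best <- max(best, sum(tab[cbind(sel, seq_along(pl))]))
    }
  } else {
    best <- 0
    for (perm in .permutations(seq_along(pl))) {
      sel <- perm[seq_along(gl)]
      best <- max(best, sum(tab[cbind(seq_along(gl), sel)]))
    }
  }
  best / length(p)
}

# Run to exactly nIters iterations (delta = 0); if the image sequence
# stops changing (v hits exact 0) the last image is repeated so every
# iteration index is populated.
.runExact <- function(img, config, nIters, seed, divisor = "max-dim") {
  cfg <- config
  cfg@delta <- 0
  cfg@maxIter <- as.integer(nIters)
  cfg@seed <- as.integer(seed)
  tr <- runSfcm(img, cfg, divisor = divisor)
  imgs <- tr@images
  while (length(imgs) < nIters + 1L)
    imgs[[length(imgs) + 1L]] <- imgs[[length(imgs)]]
  list(trace = tr, images = imgs)
}

#' Initialization-sensitivity experiment
#'
#' Runs the smoother \code{nSeeds} times with distinct Forgy
#' initializations (seeds \code{config@seed + 0 ... + nSeeds - 1}) for
#' exactly \code{nIters} iterations, and at every iteration computes the
#' mean tonal image difference for all \code{nSeeds (nSeeds-1) / 2}
#' unordered pairs of runs. A robust smoother shows large pairwise
#' differences in the first iterations (the random draw matters early) that
#' collapse to near zero as the centroids settle.
#'
#' @param img a [RasterImage-class].
#' @param config a [SmoothingConfig-class] (its delta/maxIter are
#'   overridden to run exactly \code{nIters} iterations).
#' @param nSeeds number of runs (>= 2).
#' @param nIters iterations per run.
#' @param seeds optional explicit seed vector (length \code{nSeeds});
#'   default \code{config@seed + 0:(nSeeds-1)}.
#' @return a data.frame with columns \code{iteration} (0..nIters),
#'   \code{max_diff}, \code{mean_diff} (CIELab units).
#' @export
initSensitivityExperiment <- function(img, config, nSeeds = 10L,
                                      nIters = 50L, seeds = NULL) {
  stopifnot(nSeeds >= 2L, nIters >= 1L)
  if (is.null(seeds)) seeds <- config@seed + seq_len(nSeeds) - 1L
  stopifnot(length(seeds) == nSeeds)
  if (colorSpace(img) != "cielab") img <- suppressWarnings(toCielab(img))
  k <- dim(img)[3L]
  runs <- lapply(seeds, function(s)
    .runExact(img, config, nIters, s)$images)
  pairs <- utils::combn(nSeeds, 2L)
  do.call(rbind, lapply(0:nIters, function(t) {
    d <- apply(pairs, 2L, function(pr)
      arrayDifference(runs[[pr[1L]]][[t + 1L]],
                      runs[[pr[2L]]][[t + 1L]], k))
    data.frame(iteration = t, max_diff = max(d), mean_diff = mean(d))
  }))
}

#' Cluster-count sweep
#'
#' Runs one smoothing trace per value of r for exactly \code{max(iters)}
#' iterations and snapshots the listed iterations, counting the distinct
#' output tones of every snapshot: the grid that shows under- and
#' over-segmentation as r moves away from the true region count.
#'
#' @param img a [RasterImage-class].
#' @param rList integer vector of cluster counts.
#' @param iters iterations to snapshot.
#' @param config template [SmoothingConfig-class] (r, delta, maxIter are
#'   overridden per run).
#' @param outDir optional directory; when given, every snapshot is written
#'   as \code{r<k>_iter<t>.png}.
#' @return list with \code{summary} (data.frame: r, iteration, n_tones)
#'   and \code{images} (nested list, \code{images[[as.character(r)]][[as.character(t)]]}).
#' @export
sweepClusters <- function(img, rList, iters = c(1L, 10L, 50L, 100L),
                          config = smoothingConfig(r = 2L),
                          outDir = NULL) {
  stopifnot(all(rList >= 1L), all(iters >= 0L))
  if (colorSpace(img) != "cielab") img <- suppressWarnings(toCielab(img))
  nIters <- max(iters)
  images <- list(); rows <- list()
  for (r in rList) {
    cfg <- config; cfg@r <- as.integer(r)
    imgs <- .runExact(img, cfg, nIters, cfg@seed)$images
    snap <- list()
    for (t in iters) {
      im <- RasterImage(imgs[[t + 1L]], "cielab")
      snap[[as.character(t)]] <- im
      rows[[length(rows) + 1L]] <-
        data.frame(r = r, iteration = t, n_tones = distinctToneCount(im))
      if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeRaster(im, file.path(outDir, sprintf("r%d_iter%03d.png", r, t)))
      }
    }
    images[[as.character(r)]] <- snap
  }
  list(summary = do.call(rbind, rows), images = images)
}

#' Spatio-tonal weight sweep
#'
#' One converged-or-capped run per value of alpha, all from the same seed,
#' returning the final images: shows how the weight shifts the clustering
#' from purely spatial (alpha = 0, content-unaware) to purely tonal
#' (alpha = 1).
#'
#' @param img a [RasterImage-class].
#' @param alphaList numeric vector of weights, each in [0,1].
#' @param config template [SmoothingConfig-class].
#' @param outDir optional directory for \code{alpha<value>.png} snapshots.
#' @return list with \code{summary} (data.frame: alpha, iterations,
#'   termination, n_tones), \code{images} (final images, one per alpha) and
#'   \code{traces}.
#' @export
sweepAlpha <- function(img, alphaList, config = smoothingConfig(r = 2L),
                       outDir = NULL) {
  if (any(alphaList < 0 | alphaList > 1))
    stop("every alpha must lie in [0,1]")
  if (colorSpace(img) != "cielab") img <- suppressWarnings(toCielab(img))
  images <- list(); traces <- list(); rows <- list()
  for (al in alphaList) {
    cfg <- config; cfg@metric@alpha <- al
    tr <- runSfcm(img, cfg)
    fin <- finalImage(tr)
    key <- format(al)
    images[[key]] <- fin; traces[[key]] <- tr
    rows[[length(rows) + 1L]] <- data.frame(
      alpha = al, iterations = length(tr@images) - 1L,
      termination = terminationReason(tr), n_tones = distinctToneCount(fin))
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeRaster(fin, file.path(outDir, sprintf("alpha%s.png", key)))
    }
  }
  list(summary = do.call(rbind, rows), images = images, traces = traces)
}
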