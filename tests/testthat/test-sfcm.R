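makeDataset <- function(M, N, seed = 1) {
  imageToDataset(randomLabImage(M, N, seed))
}

test_that("Forgy initialization draws distinct dataset rows, seeded", {
  ds <- makeDataset(5, 2, seed = 31)
  c1 <- forgyInit(ds, 3, seed = 7)
  c2 <- forgyInit(ds, 3, seed = 7)
  expect_identical(c1@points, c2@points)
  expect_identical(nrow(c1@points), 3L)
  # every centroid is a dataset row
  for (i in 1:3)
    expect_true(any(apply(values(ds), 1, function(row)
      all(row == c1@points[i, ]))))
  expect_false(identical(c1@points, forgyInit(ds, 3, seed = 8)@points))
})

test_that("Forgy with r = |Omega| exhausts the dataset; bad r errors", {
  ds <- makeDataset(2, 2, seed = 32)
  cs <- forgyInit(ds, 4, seed = 1)
  expect_identical(cs@points[order(cs@points[, 3]), ],
                   values(ds)[order(values(ds)[, 3]), ])
  expect_error(forgyInit(ds, 5, seed = 1), "cannot exceed")
  expect_error(forgyInit(ds, 0, seed = 1), ">= 1")
})

test_that("membership update matches hand-computed cases", {
  # one pixel at tonal distances (1, 2) from two centroids, m = 2
  img <- RasterImage(array(c(0, 0, 0), c(1, 1, 3)), "cielab")
  ds <- imageToDataset(img)
  C <- new("CentroidSet", points = rbind(c(0.5, 0.5, 1, 0, 0),
                                         c(0.5, 0.5, 2, 0, 0)), iter = 0L)
  U <- updateMemberships(ds, C, metricSpec(alpha = 1), m = 2)
  expect_equal(as.vector(values(U)), c(0.8, 0.2))
  # equidistant pixel splits 0.5 / 0.5
  C2 <- new("CentroidSet", points = rbind(c(0.5, 0.5, 3, 0, 0),
                                          c(0.5, 0.5, -3, 0, 0)),
            iter = 0L)
  U2 <- updateMemberships(ds, C2, metricSpec(alpha = 1), m = 2)
  expect_equal(as.vector(values(U2)), c(0.5, 0.5))
})

test_that("zero-distance pixels take crisp membership", {
  img <- RasterImage(array(c(10, 0, 0), c(1, 1, 3)), "cielab")
  ds <- imageToDataset(img)
  p <- values(ds)[1, ]
  C <- new("CentroidSet", points = rbind(p, p + c(0, 0, 5, 0, 0),
                                         p + c(0, 0, 9, 0, 0)), iter = 0L)
  U <- updateMemberships(ds, C, metricSpec(alpha = 0.5), m = 2)
  expect_equal(as.vector(values(U)), c(1, 0, 0))
})

test_that("membership rows always form a Ruspini partition", {
  ds <- makeDataset(6, 6, seed = 33)
  for (r in c(2, 4)) for (alpha in c(0, 0.5, 1)) {
    U <- updateMemberships(ds, forgyInit(ds, r, seed = r),
                           metricSpec(alpha = alpha), m = 2)
    expect_lt(max(abs(rowSums(values(U)) - 1)), 1e-9)
    expect_gte(min(values(U)), 0)
  }
})

test_that("centroid update reduces to the weighted mean and stays in hull", {
  ds <- makeDataset(4, 4, seed = 34)
  X <- values(ds)
  # single cluster with full membership -> componentwise mean
  U1 <- new("MembershipField", values = matrix(1, 16, 1),
            gridDim = c(4L, 4L), iter = 0L)
  C1 <- updateCentroids(ds, U1, m = 2)
  expect_equal(as.vector(C1@points), unname(colMeans(X)))
  # random memberships stay within the componentwise hull
  Uv <- withr::with_seed(5, matrix(runif(16 * 3), 16, 3))
  Uv <- Uv / rowSums(Uv)
  U2 <- new("MembershipField", values = Uv, gridDim = c(4L, 4L), iter = 0L)
  C2 <- updateCentroids(ds, U2, m = 2)
  for (j in seq_len(ncol(X))) {
    expect_gte(min(C2@points[, j]), min(X[, j]) - 1e-12)
    expect_lte(max(C2@points[, j]), max(X[, j]) + 1e-12)
  }
  expect_identical(C2@iter, 1L)
})

test_that("crisp memberships on two point masses recover those points", {
  arr <- array(0, c(2, 1, 3)); arr[1, 1, ] <- c(10, 5, 5)
  arr[2, 1, ] <- c(90, -5, -5)
  ds <- imageToDataset(RasterImage(arr, "cielab"))
  U <- new("MembershipField", values = rbind(c(1, 0), c(0, 1)),
           gridDim = c(2L, 1L), iter = 0L)
  C <- updateCentroids(ds, U, m = 2)
  expect_equal(C@points, values(ds), ignore_attr = TRUE)
})

test_that("centroid update matches a double-loop oracle", {
  ds <- makeDataset(8, 8, seed = 35)
  Uv <- withr::with_seed(6, matrix(runif(64 * 3), 64, 3))
  Uv <- Uv / rowSums(Uv)
  U <- new("MembershipField", values = Uv, gridDim = c(8L, 8L), iter = 0L)
  C <- updateCentroids(ds, U, m = 2)
  expect_equal(C@points, oracleCentroids(values(ds), Uv, 2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("empty clusters are re-seeded from the dataset", {
  ds <- makeDataset(3, 3, seed = 36)
  Uv <- cbind(rep(1, 9), rep(0, 9))   # cluster 2 has no mass
  U <- new("MembershipField", values = Uv, gridDim = c(3L, 3L), iter = 0L)
  expect_message(C <- withr::with_seed(1, updateCentroids(ds, U, m = 2)),
                 "re-seeding")
  expect_true(all(is.finite(C@points)))
  # the re-seeded centroid is an actual instance
  expect_true(any(apply(values(ds), 1, function(row)
    all(row == C@points[2, ]))))
})

test_that("image difference is the mean per-pixel tonal distance", {
  A <- randomLabImage(10, 10, seed = 41)
  expect_identical(imageDifference(A, A), 0)
  # one differing pixel with tonal distance 10 in a 10x10 image -> 0.1
  arrB <- values(A)
  arrB[3, 4, ] <- arrB[3, 4, ] + c(10, 0, 0) * sign(50 - arrB[3, 4, 1])
  B <- RasterImage(arrB, "cielab")
  expect_equal(imageDifference(A, B), 0.1)
  expect_equal(imageDifference(A, B), imageDifference(B, A))
  # random pair against explicit per-pixel summation
  Cc <- randomLabImage(10, 10, seed = 42)
  manual <- mean(sqrt(apply((values(A) - values(Cc))^2, c(1, 2), sum)))
  expect_equal(imageDifference(A, Cc), manual)
  expect_error(imageDifference(A, randomLabImage(5, 5, seed = 1)),
               "dimensions")
})

test_that("a constant image with one cluster is returned unchanged", {
  img <- RasterImage(array(rep(c(55, 10, -20), each = 36), c(6, 6, 3)),
                     "cielab")
  tr <- runSfcm(img, smoothingConfig(r = 1, alpha = 0.5, seed = 2))
  expect_identical(terminationReason(tr), "converged")
  expect_lt(max(abs(values(finalImage(tr)) - values(img))), 1e-6)
  expect_identical(length(convergenceDiffs(tr)), 1L)
})

test_that("half-and-half image with r=2 converges to the two region means", {
  arr <- array(0, c(16, 16, 1))
  arr[, 1:8, 1] <- 20; arr[, 9:16, 1] <- 80
  img <- RasterImage(arr, "cielab")
  ds <- imageToDataset(img)
  # deterministic init: one instance from each half
  init <- values(ds)[c(1, 256), , drop = FALSE]
  tr <- runSfcm(img, smoothingConfig(r = 2, alpha = 1, seed = 1,
                                     initCentroids = init))
  fin <- values(finalImage(tr))
  expect_identical(terminationReason(tr), "converged")
  expect_setequal(unique(as.vector(round(fin[, , 1], 6))), c(20, 80))
  expect_true(all(fin[, 1:8, 1] == fin[1, 1, 1]))
  expect_true(all(fin[, 9:16, 1] == fin[1, 16, 1]))
})

test_that("traces are bit-identical for identical configs and seeds", {
  img <- randomLabImage(10, 10, seed = 51)
  cfg <- smoothingConfig(r = 3, alpha = 0.8, delta = 0, maxIter = 15,
                         seed = 99)
  t1 <- runSfcm(img, cfg)
  t2 <- runSfcm(img, cfg)
  expect_identical(t1@images, t2@images)
  expect_identical(t1@diffs, t2@diffs)
  expect_identical(t1@centroids, t2@centroids)
})

test_that("the iteration cap is honored and reported", {
  img <- randomLabImage(8, 8, seed = 52)
  cfg <- smoothingConfig(r = 2, alpha = 1, delta = 1e-9, maxIter = 3,
                         seed = 1)
  expect_message(tr <- runSfcm(img, cfg), "cap")
  expect_identical(terminationReason(tr), "cap-reached")
  expect_identical(length(convergenceDiffs(tr)), 3L)
})

test_that("hardened partitions assign each pixel to its top cluster", {
  Uv <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.5, 0.5), c(0.1, 0.9))
  U <- new("MembershipField", values = Uv, gridDim = c(2L, 2L), iter = 0L)
  expect_identical(as.vector(values(hardenPartition(U))),
                   c(1L, 2L, 1L, 2L))
})
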