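test_that("constant images have homogeneity 1 everywhere", {
  H <- localHomogeneity(RasterImage(matrix(0.37, 9, 9), "unit"), n = 2)
  expect_true(all(values(H) == 1))
})

test_that("a binary step gives H = 0 exactly on window-straddling pixels", {
  mat <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  H <- values(localHomogeneity(RasterImage(mat, "unit"), n = 1))
  straddle <- col(mat) %in% c(4, 5)   # windows crossing the step
  expect_true(all(H[straddle] == 0))
  expect_true(all(H[!straddle] == 1))
})

test_that("a linear ramp has H = 1 - 2s at interior pixels (n = 1)", {
  s <- 0.01
  mat <- matrix(rep(seq(0, by = s, length.out = 30), each = 10), 10, 30)
  H <- values(localHomogeneity(RasterImage(mat, "unit"), n = 1))
  interior <- H[2:9, 2:29]
  expect_equal(as.vector(interior), rep(1 - 2 * s, length(interior)))
  # border columns see a truncated window: H = 1 - s there
  expect_equal(H[5, 1], 1 - s)
})

test_that("homogeneity matches the brute-force window scan", {
  mat <- withr::with_seed(61, matrix(runif(15 * 12), 15, 12))
  for (n in c(0, 1, 3))
    expect_equal(values(localHomogeneity(RasterImage(mat, "unit"), n)),
                 oracleHomogeneity(mat, n))
})

test_that("H never increases with the window radius and is in [0,1]", {
  mat <- withr::with_seed(62, matrix(runif(20 * 20), 20, 20))
  img <- RasterImage(mat, "unit")
  prev <- values(localHomogeneity(img, 0))
  for (n in 1:4) {
    cur <- values(localHomogeneity(img, n))
    expect_true(all(cur <= prev + 1e-15))
    expect_gte(min(cur), 0); expect_lte(max(cur), 1)
    prev <- cur
  }
})

test_that("H is invariant under tonal inversion I -> 1 - I", {
  mat <- withr::with_seed(63, matrix(runif(64), 8, 8))
  expect_equal(values(localHomogeneity(RasterImage(mat, "unit"), 2)),
               values(localHomogeneity(RasterImage(1 - mat, "unit"), 2)))
})

test_that("multichannel homogeneity averages the per-channel maps", {
  arr <- withr::with_seed(64, array(runif(10 * 10 * 3), c(10, 10, 3)))
  img <- RasterImage(arr, "unit")
  Hm <- values(multichannelHomogeneity(img, 1))
  ref <- (oracleHomogeneity(arr[, , 1], 1) + oracleHomogeneity(arr[, , 2], 1) +
          oracleHomogeneity(arr[, , 3], 1)) / 3
  expect_equal(Hm, ref)
  # constant + step channel -> 0.5 at straddling pixels
  arr2 <- array(0.5, c(6, 6, 3))
  arr2[, 4:6, 1] <- 1; arr2[, 1:3, 1] <- 0
  arr2[, , 2] <- 0.2; arr2[, , 3] <- 0.9
  H2 <- values(multichannelHomogeneity(RasterImage(arr2, "unit"), 1))
  expect_equal(H2[3, 3], (0 + 1 + 1) / 3)
})

test_that("non-normalized input is rejected", {
  lab <- RasterImage(array(50, c(4, 4, 3)), "cielab")
  expect_error(localHomogeneity(lab, 1), "unit-normalized")
  expect_error(multichannelHomogeneity(lab, 1), "unit-normalized")
})

test_that("edge bands have the stated geometry", {
  lab <- matrix(1L, 20, 20); lab[, 11:20] <- 2L
  part <- regionPartition(lab)
  expect_false(any(edgeBand(part, 0)))
  expect_false(any(edgeBand(regionPartition(matrix(1L, 5, 5)), 7)))
  band <- edgeBand(part, 7)
  expect_identical(sum(band), 140L)                 # 7 columns x 20 rows
  expect_true(all(which(colSums(band) > 0) %in% 7:13))
})

test_that("region means are computed over band-excluded masks", {
  h <- matrix(1, 10, 10)
  lab <- matrix(1L, 10, 10); lab[, 6:10] <- 2L
  part <- regionPartition(lab)
  band <- edgeBand(part, 3)
  h[band] <- 0.5
  H <- new("HomogeneityMap", values = h, n = 2L, mode = "single")
  tab <- regionMeanHomogeneity(H, part, band)
  expect_equal(tab$mean_homogeneity[tab$region == "1"], 1)
  expect_equal(tab$mean_homogeneity[tab$region == "2"], 1)
  expect_equal(tab$mean_homogeneity[tab$region == "band"], 0.5)
  expect_identical(tab$n_pixels[tab$region == "band"], sum(band))
  # random map against explicit masked summation
  hr <- withr::with_seed(65, matrix(runif(100), 10, 10))
  Hr <- new("HomogeneityMap", values = hr, n = 2L, mode = "single")
  tr <- regionMeanHomogeneity(Hr, part, band)
  expect_equal(tr$mean_homogeneity[tr$region == "1"],
               mean(hr[lab == 1 & !band]))
  # a region fully swallowed by the band reports NA
  small <- regionPartition(rbind(c(1L, 2L), c(1L, 2L)))
  bandAll <- matrix(TRUE, 2, 2)
  expect_message(tabNA <- regionMeanHomogeneity(
    new("HomogeneityMap", values = matrix(0.5, 2, 2), n = 1L,
        mode = "single"), small, bandAll), "empty")
  expect_true(all(is.na(tabNA$mean_homogeneity[tabNA$region %in%
                                                 c("1", "2")])))
})
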