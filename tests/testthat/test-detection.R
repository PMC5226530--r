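gauss2d <- function(nr, nc, cy, cx, amp, sigma) {
  outer(seq_len(nr), seq_len(nc), function(i, j)
    amp * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2)))
}

test_that("a uniform section has no maxima", {
  expect_equal(nrow(findMaxima2D(matrix(5, 20, 20), 3)), 0)
})

test_that("a single clear spot yields exactly one maximum at its peak", {
  img <- round(gauss2d(32, 32, 16, 20, 100, 3)) + 10
  mx <- findMaxima2D(img, 20)
  expect_equal(nrow(mx), 1)
  expect_equal(unname(mx[1, ]), c(16, 20))
})

test_that("two spots merge or split depending on prominence vs their "
          %+% "connecting ridge", {
  # twin ridge profile: peaks 100 at x = 10 and 22, saddle exactly 95
  prof <- pmax(100 - (5 / 6) * abs(1:32 - 10),
               100 - (5 / 6) * abs(1:32 - 22))
  img <- outer(1:32, 1:32, function(i, j) pmax(prof[j] - 10 * abs(i - 16),
                                               0))
  expect_equal(img[16, 16], 95)
  expect_equal(nrow(findMaxima2D(img, 20)), 1)
  expect_equal(nrow(findMaxima2D(img, 3)), 2)
  expect_identical(findMaxima2D(img, 20), oracleMaxima2D(img, 20))
  expect_identical(findMaxima2D(img, 3), oracleMaxima2D(img, 3))
})

test_that("2D maxima agree exactly with the brute-force flood oracle on "
          %+% "random arrays", {
  set.seed(42)
  for (i in 1:50) {
    img <- matrix(sample(0:40, 24 * 24, TRUE), 24, 24)
    if (i %% 3 == 0) img <- img + round(gauss2d(24, 24, sample(5:20, 1),
                                                sample(5:20, 1), 80, 3))
    prom <- sample(c(3, 8, 15), 1)
    got <- findMaxima2D(img, prom)
    want <- oracleMaxima2D(img, prom)
    expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                     want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("isolated noiseless 3D spots are each found once, within one "
          %+% "voxel", {
  geom <- NucleusGeometry(dim = c(40, 120, 120),
                          semiAxes = c(2.2, 3.2, 3.2))
  mask <- makeNuclearMask(geom)
  set.seed(31)
  # well-separated grid of 10 spots
  centers <- expand.grid(z = c(2, 3.4), y = c(2.2, 3.6, 5.0),
                         x = c(2.4, 3.8, 5.2))[1:10, ]
  foci <- data.frame(z = centers$z, y = centers$y, x = centers$x,
                     amplitude = 150, sigma_xy = 0.12, sigma_z = 0.22)
  g <- renderStack(mask, foci, noise = list(offset = 2, poissonScale = 0,
                                            gaussianSD = 0))
  pk <- findMaxima3D(g, mask, prominence = 20)
  expect_equal(nPeaks(pk), 10)
  d <- oracleNN(peakCenters(pk), as.matrix(foci[, c("z", "y", "x")]))
  expect_true(all(d <= sqrt(sum(voxelSize(mask)^2))))
})

test_that("an empty grid yields an empty PeakSet", {
  g <- array(0, c(8, 16, 16))
  pk <- findMaxima3D(g, prominence = 5, voxelSize = c(0.1, 0.1, 0.1))
  expect_equal(nPeaks(pk), 0)
})

test_that("single-family maxima are rejected by the conjunction and "
          %+% "extended structures do not produce peak strings", {
  # a flat plane: maximal along z (every xz section reports it) but flat
  # within every xy section, so the conjunction leaves nothing
  a <- array(0, c(12, 24, 24))
  a[6, , ] <- 100
  pk <- findMaxima3D(a, prominence = 10, voxelSize = c(0.1, 0.1, 0.1))
  expect_equal(nPeaks(pk), 0)
  # a column along z collapses to a single representative, not one peak
  # per slice
  b <- array(0, c(12, 24, 24))
  b[, 12, 12] <- 100
  pk2 <- findMaxima3D(b, prominence = 10, voxelSize = c(0.1, 0.1, 0.1))
  expect_lte(nPeaks(pk2), 1)
})

test_that("detection is invariant to a constant intensity offset", {
  geom <- smallGeometry()
  sim <- simulateNucleus(geom, smallConfig(), seed = 13)
  g <- sim$record@channels$gammaH2AX
  pk1 <- findMaxima3D(g, sim$record@mask, 10)
  shifted <- intensities(g) + 40
  pk2 <- findMaxima3D(shifted, maskArray(sim$record@mask), 10,
                      voxelSize = voxelSize(g))
  expect_identical(peakCoords(pk1), peakCoords(pk2))
})

test_that("raising prominence never increases the number of maxima", {
  set.seed(17)
  for (i in 1:50) {
    img <- matrix(sample(0:60, 32 * 32, TRUE), 32, 32)
    n1 <- nrow(findMaxima2D(img, 4))
    n2 <- nrow(findMaxima2D(img, 8))
    n3 <- nrow(findMaxima2D(img, 16))
    expect_true(n1 >= n2 && n2 >= n3)
  }
})

test_that("auto prominence recovers k sigma on Gaussian background", {
  geom <- smallGeometry()
  mask <- makeNuclearMask(geom)
  proms <- vapply(1:20, function(s) {
    set.seed(100 + s)
    arr <- array(round(rnorm(prod(dim(maskArray(mask))), 50, 3)),
                 dim(maskArray(mask)))
    autoProminence(arr, mask, k = 5)
  }, 0)
  expect_equal(mean(proms), 15, tolerance = 0.2)
})

test_that("constant background falls back to prominence one", {
  mask <- makeNuclearMask(smallGeometry())
  arr <- array(7, dim(maskArray(mask)))
  expect_warning(p <- autoProminence(arr, mask), "fall")
  expect_equal(p, 1)
})
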