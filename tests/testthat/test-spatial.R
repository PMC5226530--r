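maskS <- makeNuclearMask(smallGeometry())

test_that("nearest-neighbour distances: identity, hand case, errors", {
  a <- samplePositions(maskS, 30, "csr", seed = 1)
  expect_equal(nnDistances(a, a), rep(0, 30))
  src <- rbind(c(0, 0, 0))
  tgt <- rbind(c(0, 0, 1), c(0, 3, 0))
  expect_equal(nnDistances(src, tgt), 1)
  expect_error(nnDistances(src, src[0, , drop = FALSE]),
               "no target foci")
  expect_error(nnDistances(src, src, auto = TRUE), "no target foci")
})

test_that("nnDistances and ripleyK agree exactly with exhaustive "
          %+% "enumeration", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:200, 1); m <- sample(5:200, 1)
    a <- samplePositions(maskS, n, "csr")
    b <- samplePositions(maskS, m, "csr")
    r <- seq(0.1, 1.5, by = 0.2)
    expect_equal(nnDistances(a, b), oracleNN(a, b), tolerance = 1e-12)
    expect_equal(nnDistances(a, a, auto = TRUE),
                 oracleNN(a, a, auto = TRUE), tolerance = 1e-12)
    expect_identical(ripleyK(a, b, r), oraclePairCounts(a, b, r))
    expect_identical(ripleyK(a, rGrid = r),
                     oraclePairCounts(a, a, r, auto = TRUE))
  }
})

test_that("histograms bin right-open with an overflow bin and an unbinned "
          %+% "median", {
  h <- nnHistogram(c(0.1, 0.1, 0.5), binWidth = 0.2, rMax = 1)
  expect_equal(h$counts[1], 2)
  expect_equal(h$counts[3], 1)
  expect_equal(sum(h$counts), 3)
  expect_equal(h$median, 0.1)
  # boundary value 0.2 falls into the second (right-open) bin
  expect_equal(nnHistogram(0.2, 0.2, 1)$counts[2], 1)
  he <- nnHistogram(numeric(0))
  expect_true(all(he$counts == 0))
  expect_true(is.na(he$median))
  # distances beyond rMax land in the overflow bin
  ho <- nnHistogram(c(5, 7), binWidth = 0.2, rMax = 1)
  expect_equal(ho$counts[length(ho$counts)], 2)
})

test_that("pooled histograms equal the histogram of pooled distances", {
  set.seed(4)
  per <- lapply(1:20, function(i) runif(sample(3:30, 1), 0, 2.5))
  pooled <- nnHistogram(unlist(per), 0.1, 2)
  summed <- Reduce(`+`, lapply(per, function(d) nnHistogram(d, 0.1,
                                                            2)$counts))
  expect_equal(pooled$counts, summed)
})

test_that("ripleyK counts ordered pairs cumulatively", {
  two <- rbind(c(0, 0, 0), c(0, 0, 1))
  expect_equal(ripleyK(two, rGrid = c(0.5, 1.5)), c(0, 2))
  far <- rbind(c(5, 5, 5))
  expect_equal(ripleyK(two, far, rGrid = c(0.5, 1)), c(0, 0))
  expect_error(ripleyK(rbind(c(0, 0, 0)), rGrid = c(1)), ">= 2 points")
  expect_error(ripleyK(two, rGrid = c(1, 1)), "increasing")
})

test_that("the Monte-Carlo CSR reference approaches the closed-form "
          %+% "uniform limit in a sphere", {
  geom <- NucleusGeometry(dim = c(66, 66, 66),
                          voxelSize = c(0.1, 0.1, 0.1),
                          semiAxes = c(3, 3, 3))
  sphere <- makeNuclearMask(geom)
  r <- c(0.12)
  ref <- csrReference(sphere, 500, NULL, r, nSims = 300, seed = 9)
  closed <- 500 * 499 * (4 / 3 * pi * r^3) / maskVolume(sphere)
  expect_equal(ref$mean[1], closed, tolerance = 0.05)
  # single-point auto case: no pairs at any distance
  one <- csrReference(sphere, 2, NULL, c(0.001), nSims = 5, seed = 1)
  expect_equal(one$mean, 0)
  expect_error(csrReference(sphere, 0, NULL, r, 10), "positive")
})

test_that("the CSR reference is deterministic under a fixed seed", {
  r <- seq(0.1, 1, 0.1)
  a <- csrReference(maskS, 40, 30, r, nSims = 20, seed = 5)
  b <- csrReference(maskS, 40, 30, r, nSims = 20, seed = 5)
  expect_identical(a, b)
  c <- csrReference(maskS, 40, 30, r, nSims = 20, seed = 6)
  expect_false(identical(a$mean, c$mean))
})

test_that("L normalization: 0 at random, 1 at doubled counts, -1 at "
          %+% "zero observed, NA where undefined", {
  r <- seq(0.1, 0.5, 0.1)
  ref <- c(0, 2, 4, 8, 16)
  lc <- normalizeL(ref, ref, r)
  expect_equal(lValues(lc)[-1], rep(0, 4))
  expect_true(is.na(lValues(lc)[1]))
  expect_equal(lValues(normalizeL(2 * ref, ref, r))[-1], rep(1, 4))
  expect_equal(lValues(normalizeL(rep(0, 5), ref, r))[-1], rep(-1, 4))
})

test_that("the per-distance test flags CSR data at about the nominal "
          %+% "rate and handles degenerate variance", {
  set.seed(6)
  r <- seq(0.1, 1, 0.1)
  # L curves built from independent unit-mean pair-count noise
  flags <- replicate(60, {
    lcs <- lapply(1:10, function(i) {
      obs <- rpois(length(r), 40)
      normalizeL(obs, rep(40, length(r)), r, nucleus = as.character(i))
    })
    testLvsZero(lcs)$significant
  })
  rate <- mean(flags)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(flags)))
  # degenerate: identical L = 0.5 across nuclei
  lcs <- lapply(1:5, function(i) normalizeL(rep(6, 3), rep(4, 3),
                                            c(0.1, 0.2, 0.3)))
  tab <- testLvsZero(lcs)
  expect_true(all(tab$significant))
  expect_true(all(tab$p <= .Machine$double.xmin))
  # fewer than two contributing nuclei: undefined
  tab1 <- testLvsZero(lcs[1])
  expect_true(all(is.na(tab1$significant)))
})

test_that("two-sample count comparisons match the closed-form t-test", {
  same <- compareCounts(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0)
  expect_gt(same$p, 0.99)
  sep <- compareCounts(c(1, 2, 3), c(11, 12, 13))
  expect_lt(sep$p, 0.01)
  ref <- t.test(c(1, 2, 3), c(11, 12, 13))
  expect_equal(sep$t, unname(ref$statistic))
  expect_equal(sep$p, ref$p.value)
  degen <- compareCounts(c(5, 5), c(7, 7))
  expect_true(degen$significant)
})

test_that("L is invariant under a rigid motion applied to points and "
          %+% "mask alike", {
  # rotation by 90 degrees about z on an isotropic grid is an exact
  # relabeling of voxels, so observed counts and the CSR reference both
  # carry over
  geom <- NucleusGeometry(dim = c(40, 50, 50),
                          voxelSize = c(0.1, 0.1, 0.1),
                          semiAxes = c(1.6, 1.4, 2.0))
  m1 <- makeNuclearMask(geom)
  a1 <- samplePositions(m1, 60, "csr", seed = 2)
  r <- seq(0.2, 1, 0.2)
  obs1 <- ripleyK(a1, rGrid = r)
  # rotate: (z, y, x) -> (z, x, extent_y - y)
  ext <- dim(maskArray(m1)) * voxelSize(m1)
  rot <- maskArray(m1)
  rot <- aperm(rot, c(1, 3, 2))
  rot <- rot[, , dim(rot)[3]:1]
  m2 <- new("NuclearMask", mask = rot, voxelSize = voxelSize(m1))
  a2 <- cbind(z = a1[, "z"], y = a1[, "x"], x = ext[2] - a1[, "y"])
  obs2 <- ripleyK(a2, rGrid = r)
  expect_equal(obs1, obs2)
  ref1 <- csrReference(m1, 60, NULL, r, nSims = 400, seed = 3)
  ref2 <- csrReference(m2, 60, NULL, r, nSims = 400, seed = 4)
  L1 <- lValues(normalizeL(obs1, ref1$mean, r))
  L2 <- lValues(normalizeL(obs2, ref2$mean, r))
  expect_lt(max(abs(L1 - L2)), 0.15)
})
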