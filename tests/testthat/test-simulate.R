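mask32 <- makeNuclearMask(smallGeometry())

test_that("n = 0 yields an empty position set", {
  p <- samplePositions(mask32, 0)
  expect_equal(nrow(p), 0)
})

test_that("CSR positions are uniform: nearest-neighbour mean matches a "
          %+% "brute-force resampling oracle", {
  d <- samplePositions(mask32, 500, "csr", seed = 11)
  obs <- mean(oracleNN(d, d, auto = TRUE))
  ref <- replicate(100, {
    p <- samplePositions(mask32, 500, "csr")
    mean(oracleNN(p, p, auto = TRUE))
  })
  expect_lt(abs(obs - mean(ref)), 3 * sd(ref))
})

test_that("all sampled positions lie inside the mask, for every mode", {
  ref <- samplePositions(mask32, 50, "csr", seed = 1)
  for (p in list(ref,
                 samplePositions(mask32, 200, "clustered", seed = 2),
                 samplePositions(mask32, 200, "colocalized",
                                 reference = ref, fraction = 0.7,
                                 seed = 3))) {
    v <- foci3d:::.umToVoxel(p, voxelSize(mask32), dim(maskArray(mask32)))
    expect_true(all(maskArray(mask32)[v]))
  }
})

test_that("full colocalization with zero offset reproduces the reference", {
  ref <- samplePositions(mask32, 40, "csr", seed = 4)
  p <- samplePositions(mask32, 40, "colocalized", reference = ref,
                       fraction = 1, offsetSigma = 0, seed = 5)
  expect_equal(p[order(p[, 1], p[, 2]), ],
               ref[order(ref[, 1], ref[, 2]), ], ignore_attr = TRUE)
})

test_that("colocalized fraction outside [0,1] and empty masks error", {
  ref <- samplePositions(mask32, 5, "csr", seed = 1)
  expect_error(samplePositions(mask32, 10, "colocalized", reference = ref,
                               fraction = 1.2), "\\[0, 1\\]")
  empty <- new("NuclearMask", mask = array(FALSE, c(4, 4, 4)),
               voxelSize = c(0.1, 0.1, 0.1))
  expect_error(samplePositions(empty, 3), "empty")
})

test_that("raising the colocalization fraction raises the fraction of "
          %+% "sources with a near neighbour (monotone over f)", {
  nearFrac <- function(f, seed) {
    ref <- samplePositions(mask32, 200, "csr", seed = seed)
    p <- samplePositions(mask32, 200, "colocalized", reference = ref,
                         fraction = f, offsetSigma = 0.15,
                         seed = seed + 1000)
    mean(oracleNN(p, ref) <= 0.3)
  }
  fr <- vapply(c(0, 0.5, 1), function(f)
    mean(vapply(1:20, function(s) nearFrac(f, s), 0)), 0)
  expect_true(fr[1] < fr[2] && fr[2] < fr[3])
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulateNucleus(smallGeometry(), smallConfig(), seed = 7)
  b <- simulateNucleus(smallGeometry(), smallConfig(), seed = 7)
  expect_identical(lapply(a$record@channels, intensities),
                   lapply(b$record@channels, intensities))
  expect_identical(a$truth, b$truth)
  c <- simulateNucleus(smallGeometry(), smallConfig(), seed = 8)
  expect_false(identical(a$truth, c$truth))
})

test_that("rendering without foci or noise is a uniform offset stack", {
  g <- renderStack(mask32, data.frame(), channel = "EdU",
                   noise = list(offset = 7, poissonScale = 0,
                                gaussianSD = 0))
  expect_true(all(intensities(g) == 7))
})

test_that("a noiseless spot peaks at the voxel nearest its true centre "
          %+% "and integrates to its analytic Gaussian mass", {
  vs <- voxelSize(mask32)
  ctr <- dim(maskArray(mask32)) * vs / 2 + c(0.011, 0.013, 0.017)
  spot <- data.frame(z = ctr[1], y = ctr[2], x = ctr[3], amplitude = 200,
                     sigma_xy = 0.15, sigma_z = 0.25)
  g <- renderStack(mask32, spot, psfSigmaXY = 0.08, psfSigmaZ = 0.18,
                   noise = noNoise)
  pk <- arrayInd(which.max(intensities(g)), dim(intensities(g)))
  expect_equal(as.vector(pk),
               as.vector(foci3d:::.umToVoxel(ctr, vs,
                                             dim(maskArray(mask32)))))
  sz <- sqrt(0.25^2 + 0.18^2); sxy <- sqrt(0.15^2 + 0.08^2)
  analytic <- 200 * (2 * pi)^1.5 * sxy^2 * sz / prod(vs)
  expect_equal(sum(intensities(g)), analytic, tolerance = 0.05)
})

test_that("oversaturating amplitudes clip at exactly 255, at the voxels "
          %+% "the analytic rendering predicts", {
  vs <- voxelSize(mask32)
  ctr <- dim(maskArray(mask32)) * vs / 2
  spot <- data.frame(z = ctr[1], y = ctr[2], x = ctr[3], amplitude = 400,
                     sigma_xy = 0.15, sigma_z = 0.25)
  g <- renderStack(mask32, spot, psfSigmaXY = 0.08, psfSigmaZ = 0.18,
                   noise = list(offset = 10, poissonScale = 0,
                                gaussianSD = 0))
  expect_equal(max(intensities(g)), 255)
  # independent analytic prediction of the clipped voxel count
  d <- dim(maskArray(mask32))
  sz <- sqrt(0.25^2 + 0.18^2); sxy <- sqrt(0.15^2 + 0.08^2)
  zc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  xc <- (seq_len(d[3]) - 0.5) * vs[3]
  q <- outer(outer((zc - ctr[1])^2 / (2 * sz^2),
                   (yc - ctr[2])^2 / (2 * sxy^2), "+"),
             (xc - ctr[3])^2 / (2 * sxy^2), "+")
  predicted <- sum(400 * exp(-q) + 10 >= 254.5)
  expect_gt(predicted, 0)
  expect_equal(sum(intensities(g) == 255), predicted)
})

test_that("unsupported bit depths are rejected", {
  expect_error(renderStack(mask32, data.frame(), bitDepth = 12), "8 or 16")
})

test_that("foci outside the mask are rejected at render time", {
  spot <- data.frame(z = 0.05, y = 0.05, x = 0.05, amplitude = 10,
                     sigma_xy = 0.1, sigma_z = 0.2)
  expect_error(renderStack(mask32, spot), "inside the mask")
})

test_that("ground truth covers three channels with linked colocalization", {
  tr <- simulateGroundTruth(mask32, smallConfig(), seed = 3)
  expect_setequal(unique(tr$channel), c("53BP1", "gammaH2AX", "EdU"))
  expect_equal(sum(tr$population == "bright"), 8)
  expect_equal(sum(tr$population == "dim"), 12)
  # bright foci carry links into the EdU set at the configured fraction
  br <- tr[tr$population == "bright", ]
  expect_equal(sum(!is.na(br$link_id)), round(0.8 * nrow(br)))
  expect_true(all(tr$amplitude > 0 & tr$sigma_xy > 0 & tr$sigma_z > 0))
})
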