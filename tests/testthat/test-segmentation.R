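renderSpot <- function(dims, vs, center, amp, sxy, sz, offset = 0) {
  zc <- (seq_len(dims[1]) - 0.5) * vs[1]
  yc <- (seq_len(dims[2]) - 0.5) * vs[2]
  xc <- (seq_len(dims[3]) - 0.5) * vs[3]
  q <- outer(outer((zc - center[1])^2 / (2 * sz^2),
                   (yc - center[2])^2 / (2 * sxy^2), "+"),
             (xc - center[3])^2 / (2 * sxy^2), "+")
  round(amp * exp(-q)) + offset
}

peaksAt <- function(coords, arr, vs) {
  coords <- rbind(coords)
  new("PeakSet", coords = coords,
      centers = sweep(coords - 0.5, 2, vs, "*"),
      values = as.numeric(arr[coords]), prominence = 1,
      channel = "gammaH2AX")
}

test_that("an isolated spot floods to the analytic super-floor volume", {
  vs <- c(0.1, 0.1, 0.1)
  dims <- c(40, 40, 40)
  arr <- renderSpot(dims, vs, c(2, 2, 2), amp = 200, sxy = 0.3, sz = 0.3,
                    offset = 5)
  pk <- peaksAt(c(20, 20, 20), arr, vs)
  fl <- floodRegions(arr, pk, floorLevel = 6, step = 1)
  vol <- sum(fl$labels == 1) * prod(vs)
  # quantized spot voxels reach floor 6 (= offset + 1) where the
  # continuous spot is at least 0.5; that level set is a ball
  r2 <- 2 * 0.3^2 * log(200 / 0.5)
  analytic <- 4 / 3 * pi * r2^1.5
  expect_equal(vol, analytic, tolerance = 0.2)
})

test_that("two equal spots split along the equidistant plane and match "
          %+% "the synchronous flood oracle exactly", {
  vs <- c(0.1, 0.1, 0.1)
  dims <- c(20, 20, 30)
  arr <- renderSpot(dims, vs, c(1, 1, 1), 100, 0.25, 0.25) +
    renderSpot(dims, vs, c(1, 1, 2), 100, 0.25, 0.25) + 2
  pk <- peaksAt(rbind(c(10, 10, 10), c(10, 10, 20)), arr, vs)
  fl <- floodRegions(arr, pk, floorLevel = 4, step = 1)
  expect_setequal(unique(as.vector(fl$labels)), c(0L, 1L, 2L))
  # every claimed voxel is nearer its own peak, within one voxel slack
  for (k in 1:2) {
    idx <- arrayInd(which(fl$labels == k & !fl$frozen), dims)
    dOwn <- sqrt(colSums((t(idx) - c(10, 10, c(10, 20)[k]))^2))
    dOther <- sqrt(colSums((t(idx) - c(10, 10, c(20, 10)[k]))^2))
    expect_true(all(dOwn <= dOther + 1))
  }
  orc <- oracleFlood(arr, rbind(c(10, 10, 10), c(10, 10, 20)),
                     floorLevel = 4, step = 1, voxelSize = vs)
  expect_identical(fl$labels, orc$labels)
  expect_identical(fl$frozen, orc$frozen)
})

test_that("flooding matches the oracle on random multi-peak fields", {
  set.seed(77)
  vs <- c(0.13, 0.06, 0.06)
  dims <- c(14, 18, 18)
  for (i in 1:5) {
    arr <- array(sample(0:10, prod(dims), TRUE), dims)
    pkc <- cbind(sample(3:12, 3), sample(3:16, 3), sample(3:16, 3))
    pkc <- pkc[!duplicated(pkc), , drop = FALSE]
    arr[pkc] <- arr[pkc] + sample(30:60, nrow(pkc), TRUE)
    pk <- peaksAt(pkc, arr, vs)
    fl <- floodRegions(arr, pk, floorLevel = 8, step = 2)
    orc <- oracleFlood(arr, pkc, floorLevel = 8, step = 2, voxelSize = vs)
    expect_identical(fl$labels, orc$labels)
  }
})

test_that("an empty peak set floods to nothing", {
  arr <- array(5, c(6, 6, 6))
  pk <- new("PeakSet", coords = matrix(integer(), 0, 3),
            centers = matrix(numeric(), 0, 3), values = numeric(),
            prominence = 1, channel = "gammaH2AX")
  fl <- floodRegions(arr, pk, floorLevel = 1, step = 1)
  expect_true(all(fl$labels == 0L))
})

test_that("a peak below the floor keeps a single-voxel region", {
  arr <- array(2, c(8, 8, 8)); arr[4, 4, 4] <- 3
  pk <- peaksAt(c(4, 4, 4), arr, c(0.1, 0.1, 0.1))
  expect_warning(fl <- floodRegions(arr, pk, floorLevel = 10, step = 1),
                 "below the flooding floor")
  expect_equal(which(fl$labels == 1L), which(arr == 3))
})

test_that("regions partition claimed voxels and contain their seeds", {
  sim <- simulateNucleus(smallGeometry(), smallConfig(), seed = 19)
  g <- sim$record@channels$gammaH2AX
  mask <- sim$record@mask
  pk <- findMaxima3D(g, mask, autoProminence(g, mask))
  fl <- floodRegions(g, pk, mask = mask)
  lab <- fl$labels
  expect_true(all(lab[peakCoords(pk)] == seq_len(nPeaks(pk))))
  # region voxel count never exceeds the mask volume
  expect_lte(sum(lab > 0), sum(maskArray(mask)))
  # 26-connectivity of each region
  for (k in seq_len(nPeaks(pk))) {
    sub <- foci3d:::cpp_label3d(lab == k, dim(lab))
    expect_equal(max(sub), 1)
  }
})

test_that("estimated volume grows monotonically with true spot width", {
  vs <- c(0.1, 0.1, 0.1)
  dims <- c(40, 40, 40)
  vols <- vapply(c(0.1, 0.15, 0.2, 0.25), function(s) {
    arr <- renderSpot(dims, vs, c(2, 2, 2), 150, s, s, offset = 3)
    pk <- peaksAt(c(20, 20, 20), arr, vs)
    fl <- floodRegions(arr, pk, floorLevel = 5, step = 1)
    sum(fl$labels == 1) * prod(vs)
  }, 0)
  expect_true(all(diff(vols) > 0))
})

test_that("focus measurement computes exact volumes and saturation-aware "
          %+% "means", {
  vs <- c(0.13, 0.06, 0.06)
  # 534 voxels at the acquisition calibration: 0.2499 um^3
  arr <- array(0, c(10, 20, 20))
  idx <- arrayInd(seq_len(534), dim(arr))
  f <- measureFocus(idx, arr, voxelSize = vs)
  expect_equal(f$volume, 534 * 0.13 * 0.06 * 0.06, tolerance = 1e-12)
  expect_equal(round(f$volume, 4), 0.2499)
  # one-voxel region carries its raw value
  arr[2, 3, 4] <- 42
  expect_equal(measureFocus(cbind(2, 3, 4), arr,
                            voxelSize = vs)$meanIntensity, 42)
  # saturated voxels leave numerator and denominator
  arr[1, 1, 1] <- 10; arr[1, 1, 2] <- 20; arr[1, 1, 3] <- 255
  sat <- array(FALSE, dim(arr)); sat[1, 1, 3] <- TRUE
  f3 <- measureFocus(cbind(1, 1, 1:3), arr, saturationMask = sat,
                     voxelSize = vs)
  expect_equal(f3$meanIntensity, 15)
  # fully saturated region reports the top code with a flag
  f4 <- measureFocus(cbind(1, 1, 3), arr, saturationMask = sat,
                     voxelSize = vs)
  expect_equal(f4$meanIntensity, 255)
  expect_true(f4$allSaturated)
  expect_error(measureFocus(cbind(99, 1, 1), arr, voxelSize = vs),
               "bounds")
})
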