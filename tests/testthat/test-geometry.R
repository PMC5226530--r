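test_that("rasterized mask volume matches the analytic ellipsoid", {
  geom <- NucleusGeometry(dim = c(100, 300, 300),
                          voxelSize = c(0.13, 0.06, 0.06),
                          semiAxes = c(5, 8, 8))
  m <- makeNuclearMask(geom)
  expect_equal(maskVolume(m), ellipsoidVolume(geom),
               tolerance = 0.02)
  expect_equal(ellipsoidVolume(geom), 4 / 3 * pi * 5 * 8 * 8)
})

test_that("degenerate sub-voxel ellipsoid keeps the centre voxel", {
  geom <- NucleusGeometry(dim = c(15, 15, 15), voxelSize = c(0.2, 0.2, 0.2),
                          semiAxes = c(0.05, 0.05, 0.05))
  m <- makeNuclearMask(geom)
  expect_gte(sum(maskArray(m)), 1)
  expect_true(maskArray(m)[8, 8, 8])
})

test_that("mask is symmetric under reflection through the centre", {
  geom <- NucleusGeometry(dim = c(20, 40, 40), voxelSize = c(0.2, 0.1, 0.1),
                          semiAxes = c(1.5, 1.7, 1.3))
  a <- maskArray(makeNuclearMask(geom))
  expect_identical(a, a[dim(a)[1]:1, dim(a)[2]:1, dim(a)[3]:1])
})

test_that("invalid geometries are rejected", {
  expect_error(NucleusGeometry(dim = c(10, 10, 10),
                               voxelSize = c(0.1, 0.1, 0.1),
                               semiAxes = c(5, 1, 1)),
               "exceeds")
  expect_error(NucleusGeometry(semiAxes = c(-1, 2, 2)), "positive")
  expect_error(NucleusGeometry(voxelSize = c(0, 0.06, 0.06)), "positive")
})
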