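test_that("the bright/dim rule follows volume OR intensity, inclusively", {
  expect_equal(classifyFocus(0.30, 20), "bright")   # volume branch
  expect_equal(classifyFocus(0.10, 40), "bright")   # intensity branch
  expect_equal(classifyFocus(0.10, 20), "dim")      # neither
  expect_equal(classifyFocus(0.25, 35), "bright")   # inclusive boundary
  expect_equal(classifyFocus(0.25, 35, inclusive = FALSE), "dim")
  expect_error(classifyFocus(-0.1, 20), "non-negative")
  expect_error(classifyFocus(0.1, -2), "non-negative")
  expect_error(classThresholds(volume = 0), "positive")
})

test_that("bright + dim always equals the gamma-H2AX total", {
  set.seed(3)
  foci <- data.frame(
    channel = sample(c("gammaH2AX", "53BP1", "EdU"), 60, TRUE),
    volume = runif(60, 0, 0.6),
    meanIntensity = runif(60, 0, 60))
  cls <- classifyFoci(foci)
  counts <- countByClass(cls)
  ng <- sum(foci$channel == "gammaH2AX")
  expect_equal(sum(counts$count[counts$channel == "gammaH2AX"]), ng)
  expect_true(all(cls$class[cls$channel == "gammaH2AX"] %in%
                    c("bright", "dim")))
  expect_true(all(cls$class[cls$channel != "gammaH2AX"] ==
                    "unclassified"))
  empty <- countByClass(classifyFoci(foci[0, ]))
  expect_true(all(empty$count == 0))
})

test_that("lowering either threshold never decreases the bright count", {
  set.seed(8)
  for (i in 1:100) {
    foci <- data.frame(channel = "gammaH2AX",
                       volume = runif(30, 0, 0.6),
                       meanIntensity = runif(30, 0, 70))
    base <- sum(classifyFoci(foci)$class == "bright")
    lowerV <- sum(classifyFoci(foci, classThresholds(0.15, 35))$class ==
                    "bright")
    lowerI <- sum(classifyFoci(foci, classThresholds(0.25, 20))$class ==
                    "bright")
    expect_gte(lowerV, base)
    expect_gte(lowerI, base)
  }
})

test_that("classes recovered from rendered nuclei agree with the "
          %+% "generating populations", {
  sim <- simulateNucleus(smallGeometry(), smallConfig(), seed = 23)
  res <- suppressWarnings(runNucleus(sim$record,
                                     runConfig(nSims = 10, seed = 2)))
  g <- res$foci[res$foci$channel == "gammaH2AX", ]
  tru <- sim$truth[sim$truth$channel == "gammaH2AX", ]
  tp <- as.matrix(tru[, c("z", "y", "x")])
  agree <- 0L; tot <- 0L
  for (i in seq_len(nrow(g))) {
    d <- sqrt(colSums((t(tp) - c(g$z_um[i], g$y_um[i], g$x_um[i]))^2))
    j <- which.min(d)
    if (d[j] <= 0.3) {
      tot <- tot + 1L
      agree <- agree + (g$class[i] == tru$population[j])
    }
  }
  expect_gt(tot, 0.8 * nrow(tru))
  expect_gte(agree / tot, 0.9)
})
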