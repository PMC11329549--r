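# Partition arithmetic, calibration fitting and material decomposition.

miniVolume <- function(hu, timepoint, bin = "single") {
  d <- dim(hu)
  cart <- array(FALSE, d); cart[2:3, 2:3, ] <- TRUE
  bath <- array(FALSE, d); bath[1, , ] <- TRUE
  AttenuationVolume(hu, 40, timepoint, bin, cart, bath)
}

test_that("bulk partition follows the attenuation-difference formula", {
  d <- c(4, 4, 2)
  v0 <- miniVolume(array(200, d), "0h")
  v96a <- miniVolume(array(200, d), "96h")
  expect_equal(bulkPartition(v0, v96a, 3000), 0)

  v96b <- miniVolume(array(200 + 3000, d), "96h")
  expect_equal(bulkPartition(v0, v96b, 3000), 100)

  v96c <- miniVolume(array(1700, d), "96h")
  expect_equal(bulkPartition(v0, v96c, 3000), 50)

  ## invariant to a global additive HU offset applied to both timepoints
  off <- function(v, k) miniVolume(v@hu + k, v@timepoint)
  expect_equal(bulkPartition(off(v0, 137), off(v96c, 137), 3000), 50)

  expect_error(bulkPartition(v0, v96c, 0), "positive")
  expect_error(bulkPartition(v0, miniVolume(array(1, c(4, 4, 3)), "96h"), 1),
               "grids")
})

test_that("calibration fit recovers a known affine model exactly", {
  A <- rbind(low = c(Ta = 80, I = 45), total = c(Ta = 55, I = 28))
  b <- c(12, 7)
  mix <- generateCalibrationMixtures(
    coefficients = list(low_10_80keV = A["low", ],
                        total_10_120keV = A["total", ]),
    offsets = list(low_10_80keV = b[1], total_10_120keV = b[2]),
    noiseSD = 0)
  expect_equal(nrow(mix), 16)
  cal <- fitDecompositionCalibration(mix)
  expect_equal(unname(cal@A), unname(A), tolerance = 1e-10)
  expect_equal(cal@b, b, tolerance = 1e-9)
  expect_lt(cal@residualRMS, 1e-9)
  expect_true(is.finite(cal@conditionNumber))
})

test_that("degenerate mixture designs are rejected loudly", {
  pureWater <- data.frame(C_Ta = 0, C_I = 0,
                          HU_low = c(0, 0, 0), HU_total = c(0, 0, 0))
  expect_error(fitDecompositionCalibration(pureWater), "degenerate")
  prop <- data.frame(C_Ta = c(1, 2, 4), C_I = c(2, 4, 8),
                     HU_low = 1:3, HU_total = 1:3)
  expect_error(fitDecompositionCalibration(prop), "degenerate")
  expect_warning(generateCalibrationMixtures(
    grid = data.frame(C_Ta = c(1, 2, 4), C_I = c(2, 4, 8))), "collinear")
})

test_that("calibration residual RMS tracks the injected HU noise", {
  sigma <- 25
  mix <- generateCalibrationMixtures(
    grid = expand.grid(C_Ta = seq(0, 30, length.out = 10),
                       C_I = seq(0, 45, length.out = 10)),
    noiseSD = sigma, seed = 99)
  cal <- fitDecompositionCalibration(mix)
  expect_equal(cal@residualRMS, sigma, tolerance = 0.2)
})

test_that("voxelwise decomposition inverts the forward model", {
  A <- rbind(low = c(Ta = 80, I = 45), total = c(Ta = 55, I = 28))
  b <- c(12, 7)
  cal <- new("DecompositionCalibration", A = A, b = b,
             conditionNumber = kappa(A), residualRMS = 0)
  ## background maps to (0, 0)
  z <- decomposeVoxelwise(b[1], b[2], cal)
  expect_equal(z$C_Ta, 0, tolerance = 1e-12)
  expect_equal(z$C_I, 0, tolerance = 1e-12)
  ## forward-then-inverse round trip on random concentrations
  set.seed(3)
  cTa <- runif(50, 0, 30); cI <- runif(50, 0, 45)
  hu <- A %*% rbind(cTa, cI) + b
  out <- decomposeVoxelwise(hu[1, ], hu[2, ], cal)
  expect_equal(out$C_Ta, cTa, tolerance = 1e-12)
  expect_equal(out$C_I, cI, tolerance = 1e-12)
  ## linearity in the agent signal (affine offset handled)
  h2 <- A %*% rbind(2 * cTa, 2 * cI) + b
  out2 <- decomposeVoxelwise(h2[1, ], h2[2, ], cal)
  expect_equal(out2$C_Ta, 2 * out$C_Ta, tolerance = 1e-10)
  ## negative solutions are retained and counted, not clipped
  neg <- decomposeVoxelwise(b[1] - 100, b[2] - 100, cal)
  expect_true(neg$C_Ta < 0 || neg$C_I < 0)
  expect_gte(sum(attr(neg, "nNegative")), 1)
})

test_that("decomposition is mean-unbiased under HU noise", {
  A <- rbind(low = c(Ta = 80, I = 45), total = c(Ta = 55, I = 28))
  cal <- new("DecompositionCalibration", A = A, b = c(0, 0),
             conditionNumber = kappa(A), residualRMS = 0)
  set.seed(11)
  n <- 1e4
  truth <- c(Ta = 12, I = 25)
  hu <- A %*% truth
  out <- decomposeVoxelwise(hu[1] + rnorm(n, sd = 40),
                            hu[2] + rnorm(n, sd = 40), cal)
  expect_equal(mean(out$C_Ta), truth[["Ta"]], tolerance = 0.02)
  expect_equal(mean(out$C_I), truth[["I"]], tolerance = 0.02)
})

test_that("combined partition is the Ta/I ratio with its guard rails", {
  expect_equal(round(combinedPartition(177.9, 58.0), 1), 3.1)
  expect_equal(combinedPartition(60, 60), 1)
  expect_equal(combinedPartition(0, 58), 0)
  expect_error(combinedPartition(100, 0), "undefined")
  expect_error(combinedPartition(100, -5), "undefined")
})

test_that("end-to-end dual phantom returns the configured partitions", {
  sp <- phantomSpec(noiseSD = 0, partitions = c(Ta = 177.9, I = 58.0))
  ph <- generateDualEnergyPhantom(sp)
  cal <- fitDecompositionCalibration(generateCalibrationMixtures(noiseSD = 0))
  pr <- dualContrastPartitions(ph$volumes, cal, sp$bathConcentrations)
  expect_equal(partitionTa(pr), 177.9, tolerance = 1e-9)
  expect_equal(partitionI(pr), 58.0, tolerance = 1e-9)
  expect_equal(partitionCombined(pr), 177.9 / 58.0, tolerance = 1e-9)

  ## with default noise the partitions stay within 2 percentage points
  spN <- phantomSpec(noiseSD = 30, partitions = c(Ta = 177.9, I = 58.0),
                     seed = 5)
  phN <- generateDualEnergyPhantom(spN)
  prN <- dualContrastPartitions(phN$volumes, cal, spN$bathConcentrations)
  expect_lt(abs(partitionTa(prN) - 177.9), 2)
  expect_lt(abs(partitionI(prN) - 58.0), 2)
})

test_that("end-to-end single phantom returns the configured partition", {
  sp <- phantomSpec(noiseSD = 0, method = "single",
                    bathConcentrations = c(Ta = 30, I = 0),
                    partitions = c(Ta = 313.7, I = 0))
  ph <- generateDualEnergyPhantom(sp)
  expect_equal(bulkPartition(ph$volumes[["0h_single"]],
                             ph$volumes[["96h_single"]],
                             ph$groundTruth$bathHU[["single"]]),
               313.7, tolerance = 1e-9)
  ## the measured bath attenuation equals the nominal one here
  expect_equal(measuredBathHU(ph$volumes[["0h_single"]]),
               ph$groundTruth$bathHU[["single"]], tolerance = 1e-9)
  pr <- singleContrastPartition(ph$volumes[["0h_single"]],
                                ph$volumes[["96h_single"]])
  expect_equal(partitionTa(pr), 313.7, tolerance = 1e-9)
  expect_true(is.na(partitionI(pr)))
})
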