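# Generators: determinism, noise calibration, cohort structure.

test_that("force-curve generator is deterministic and noise-calibrated", {
  truth <- FRPEParameters(E_f0 = 0.3, E_feps = 8, E_nf = 0.2, k0 = 4e-15,
                          M = 15)
  geom <- coarseDemoGeometry()
  clean <- generateForceCurve(truth, geom, noise_cv = 0, meshNr = 8,
                              meshNz = 5, holdSteps = 25)
  clean2 <- generateForceCurve(truth, geom, noise_cv = 0, meshNr = 8,
                               meshNz = 5, holdSteps = 25)
  expect_identical(forces(clean), forces(clean2))
  expect_identical(clean@metadata$groundTruth$params,
                   as.vector(truth))

  n1 <- generateForceCurve(truth, geom, noise_cv = 0.01, seed = 5, meshNr = 8,
                           meshNz = 5, holdSteps = 25)
  n1b <- generateForceCurve(truth, geom, noise_cv = 0.01, seed = 5, meshNr = 8,
                            meshNz = 5, holdSteps = 25)
  expect_identical(forces(n1), forces(n1b))
  n2 <- generateForceCurve(truth, geom, noise_cv = 0.01, seed = 6, meshNr = 8,
                           meshNz = 5, holdSteps = 25)
  expect_false(identical(forces(n1), forces(n2)))

  ## pooled relative deviations across seeds estimate the configured cv
  devs <- unlist(lapply(1:25, function(s) {
    nz <- generateForceCurve(truth, geom, noise_cv = 0.01, seed = s,
                             meshNr = 8, meshNz = 5, holdSteps = 25)
    forces(nz) / forces(clean) - 1
  }))
  expect_gt(length(devs), 4000)
  expect_equal(sd(devs), 0.01, tolerance = 0.1)
})

test_that("cohort has the requested design and location effects", {
  spec <- cohortSpec(nPerLocation = 40, seed = 3)
  co <- generateCohort(spec)
  ## two locations x two imaging arms
  expect_equal(nrow(co), 4 * 40)
  expect_equal(as.integer(table(co$location)), c(80L, 80L))
  co2 <- generateCohort(spec)
  expect_identical(co, co2)  # pure function of (spec, seed)

  expect_gt(mean(co$E_nf[co$location == "medial_condyle"]),
            mean(co$E_nf[co$location == "distal_groove"]))
  expect_lt(mean(co$k0[co$location == "medial_condyle"]),
            mean(co$k0[co$location == "distal_groove"]))
  ## all parameters positive; partitions present per arm
  expect_true(all(co$E_nf > 0 & co$k0 > 0 & co$M > 0))
  expect_true(all(is.na(co$partition_I[co$method == "single"])))
  expect_true(all(is.finite(co$partition_I[co$method == "dual"])))
})

test_that("cohort couplings are sign-correct in the latent PG factor", {
  co <- generateCohort(cohortSpec(nPerLocation = 150, seed = 8))
  ## the latent links are defined within a location and imaging arm
  ## (between-location differences ride on the latent shift instead)
  for (arm in c("single", "dual")) {
    for (loc in unique(co$location)) {
      sub <- co[co$method == arm & co$location == loc, ]
      expect_gt(cor(sub$latent_g, sub$E_nf, method = "spearman"), 0.4)
      expect_gt(cor(sub$latent_g, sub$partition_Ta, method = "spearman"), 0.4)
      expect_lt(cor(sub$latent_g, sub$k0, method = "spearman"), -0.2)
    }
  }
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(nPerLocation = 2), "at least 3")
  expect_error(cohortSpec(loadings = list(Enf = c(g = NaN, q = 0, c = 0))),
               "invalid loadings")
  expect_error(cohortSpec(loadings = list(Enf = c(g = 1, q = 1, c = 0))),
               "invalid loadings")
})

test_that("phantom zero-noise bath equals the affine map of bath concentrations", {
  sp <- phantomSpec(noiseSD = 0)
  ph <- generateDualEnergyPhantom(sp)
  v <- ph$volumes[["0h_low_10_80keV"]]
  co <- sp$coefficients$low_10_80keV
  expect_equal(mean(v@hu[v@bathMask]),
               co[["Ta"]] * 20 + co[["I"]] * 40, tolerance = 1e-12)
  ## 0 h cartilage carries no agent, only the tissue offset
  expect_equal(mean(v@hu[v@cartilageMask]), sp$tissueOffsetHU,
               tolerance = 1e-12)
  ## voxelwise decomposition of the 96 h cartilage recovers the
  ## configured concentrations to machine precision
  cal <- fitDecompositionCalibration(generateCalibrationMixtures(noiseSD = 0))
  lo <- ph$volumes[["96h_low_10_80keV"]]
  to <- ph$volumes[["96h_total_10_120keV"]]
  dec <- decomposeVoxelwise(
    mean(lo@hu[lo@cartilageMask]) - sp$tissueOffsetHU,
    mean(to@hu[to@cartilageMask]) - sp$tissueOffsetHU, cal)
  expect_equal(dec$C_Ta, 177.9 / 100 * 20, tolerance = 1e-9)
  expect_equal(dec$C_I, 58 / 100 * 40, tolerance = 1e-9)
})

test_that("phantom validates geometry against the grid", {
  expect_error(phantomSpec(gridDim = c(16, 16, 16), voxelSize = 40,
                           cartilageRadius = 2e-3), "exceeds")
})

test_that("mixture tables are reproducible per seed", {
  a <- generateCalibrationMixtures(noiseSD = 10, seed = 4)
  b <- generateCalibrationMixtures(noiseSD = 10, seed = 4)
  expect_identical(a, b)
  c2 <- generateCalibrationMixtures(noiseSD = 10, seed = 5)
  expect_false(identical(a, c2))
})
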