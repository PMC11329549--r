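# The coupled displacement/pore-pressure solver, checked against
# closed-form and independently assembled oracles.

noFibrilParams <- function(E_nf = 0.5, k0 = 4.7e-15, M = 0)
  FRPEParameters(E_f0 = 0, E_feps = 0, E_nf = E_nf, k0 = k0, M = M)

test_that("zero prescribed displacement from equilibrium gives zero force", {
  m <- buildMesh(1e-3, 2e-3, 0.275e-3, n_r = 6, n_z = 4,
                 material = noFibrilParams())
  st <- solveTimeStep(m, dt = 1, indenterDisplacement = 0)
  expect_equal(st$reactionForce, 0, tolerance = 1e-10)
  expect_equal(max(abs(st$model@displacements)), 0, tolerance = 1e-15)
})

test_that("confined-compression pressure decay matches the consolidation series", {
  p <- noFibrilParams()
  E <- 0.5e6; nu <- 0.42
  K <- E / (3 * (1 - 2 * nu)); G <- E / (2 * (1 + nu))
  cv <- p@k0 * (K / 2 + 4 * G / 3)  # linearised confined modulus of the law
  H <- 1e-3
  Tvs <- c(0.05, 0.1, 0.2, 0.5, 1.0)
  cc <- simulateConfinedConsolidation(p, height = H, radius = 0.5e-3,
                                      n_z = 30, sigma0 = 100,
                                      times = Tvs * H^2 / cv, nSubsteps = 30)
  zeta <- 1 - cc$z / H
  for (j in seq_along(Tvs)) {
    expect_lt(max(abs(cc$pressure[, j] - 100 * terzaghiSeries(zeta, Tvs[j]))),
              2.0)  # 2% of the applied 100 Pa at this resolution
  }
  ## undrained start: pore pressure carries the full load initially
  early <- simulateConfinedConsolidation(p, height = H, radius = 0.5e-3,
                                         n_z = 30, sigma0 = 100,
                                         times = 1e-3 * H^2 / cv)
  expect_equal(early$pressure[1, 1], 100, tolerance = 1e-2)
})

test_that("drained equilibrium matches an independent linear-elastic solve", {
  p <- noFibrilParams(E_nf = 0.3)
  m <- buildMesh(1e-3, 2e-3, 0.275e-3, n_r = 10, n_z = 6, material = p)
  d <- 2e-7  # small displacement: geometric nonlinearity negligible
  fNonlinear <- staticIndentationForce(m, d)
  E <- 0.3e6; nu <- 0.42
  K <- E / (3 * (1 - 2 * nu)); G <- E / (2 * (1 + nu))
  fLinear <- linearElasticIndentationForce(m, d, K / 2, G)
  expect_equal(fNonlinear, fLinear, tolerance = 0.005)
})

test_that("pre-stress search reaches the 40 kPa target within 0.5%", {
  p <- FRPEParameters(E_f0 = 0.29, E_feps = 10.1, E_nf = 0.13,
                      k0 = 4.7e-15, M = 20.5)
  m <- buildMesh(1.2e-3, 2e-3, 0.275e-3, n_r = 8, n_z = 5, material = p)
  proto <- loadingProtocol()
  d <- findPrestressDisplacement(m, proto)
  target <- 40e3 * pi * (0.275e-3)^2  # ~9.50e-3 N over the indenter face
  expect_equal(target, 9.50e-3, tolerance = 1e-3)
  expect_equal(attr(d, "force") / target, 1, tolerance = 0.005)
  expect_gt(as.numeric(d), 0)
  ## zero target: zero displacement
  d0 <- findPrestressDisplacement(m, loadingProtocol(prestress = 0))
  expect_equal(as.numeric(d0), 0)
})

test_that("pre-stress displacement is near-linear in the target for a linear material", {
  p <- noFibrilParams(E_nf = 0.4)
  m <- buildMesh(1e-3, 2e-3, 0.275e-3, n_r = 8, n_z = 5, material = p)
  d1 <- as.numeric(findPrestressDisplacement(m, loadingProtocol(prestress = 5e3)))
  d2 <- as.numeric(findPrestressDisplacement(m, loadingProtocol(prestress = 10e3)))
  expect_equal(d2 / d1, 2, tolerance = 0.03)
})

test_that("stress relaxation: holds relax, pressures dissipate, runs are reproducible", {
  p <- FRPEParameters(E_f0 = 0.29, E_feps = 10.1, E_nf = 0.13,
                      k0 = 4.7e-15, M = 20.5)
  m <- buildMesh(1.2e-3, 2e-3, 0.275e-3, n_r = 8, n_z = 5, material = p)
  cur <- simulateStressRelaxation(m, loadingProtocol(), holdSteps = 30)
  f <- forces(cur); sb <- stepBounds(cur)
  expect_equal(nrow(sb), 4)
  for (s in 1:4) {
    seg <- f[sb[s, 1]:sb[s, 2]]
    expect_lt(f[sb[s, 2]], max(seg))              # hold ends below ramp peak
    hold <- seg[which.max(seg):length(seg)]
    expect_true(all(diff(hold) <= 1e-12))         # monotone relaxation
  }
  ## ramp amplitudes shrink with remaining thickness
  meta <- cur@metadata
  expect_true(is.finite(meta$prestress_force_N))
  ## determinism: bit-identical repeat
  cur2 <- simulateStressRelaxation(m, loadingProtocol(), holdSteps = 30)
  expect_identical(forces(cur2), f)
  expect_identical(times(cur2), times(cur))
})

test_that("drained limit: very high permeability removes the transient peak", {
  p <- noFibrilParams(E_nf = 0.3, k0 = 1e-10)
  m <- buildMesh(1e-3, 2e-3, 0.275e-3, n_r = 6, n_z = 4, material = p)
  proto <- loadingProtocol(relaxTime = 50)
  cur <- simulateStressRelaxation(m, proto, holdSteps = 20)
  f <- forces(cur); sb <- stepBounds(cur)
  for (s in 1:4) {
    seg <- f[sb[s, 1]:sb[s, 2]]
    expect_equal(max(seg) / f[sb[s, 2]], 1, tolerance = 0.02)
  }
  ## contrast: at physiological permeability the same protocol gives
  ## peak/equilibrium ratios far above 1
  pSlow <- noFibrilParams(E_nf = 0.3, k0 = 4.7e-15)
  mS <- buildMesh(1e-3, 2e-3, 0.275e-3, n_r = 6, n_z = 4, material = pSlow)
  curS <- simulateStressRelaxation(mS, proto, holdSteps = 20)
  fS <- forces(curS); sbS <- stepBounds(curS)
  expect_gt(max(fS[sbS[1, 1]:sbS[1, 2]]) / fS[sbS[1, 2]], 1.15)
})

test_that("fluid mass is conserved over a relaxation hold", {
  p <- noFibrilParams(E_nf = 0.5, M = 0)
  model <- buildMesh(1e-3, 2e-3, 0.275e-3, n_r = 8, n_z = 5, material = p)
  matv <- frpecect:::.matVec(p, 0.1)
  fib <- frpecect:::.fibMat(p)
  drained <- frpecect:::.dof(sort(unique(c(model@nodeSets$surfaceFree,
                                           model@nodeSets$lateral))), 3L)
  v0 <- meshVolumes(model)[["current"]]
  ## ramp to a fixed indentation, then hold; integrate the boundary-flux
  ## reactions at every drained pressure dof over the whole history
  dTarget <- 2e-5
  schedule <- rbind(cbind(dt = rep(0.02, 10), d = dTarget * (1:10) / 10),
                    cbind(dt = rep(2, 40), d = dTarget))
  efflux <- 0
  for (i in seq_len(nrow(schedule))) {
    Un <- frpecect:::.stateVector(model)
    st <- solveTimeStep(model, dt = schedule[i, "dt"],
                        indenterDisplacement = schedule[i, "d"])
    model <- st$model
    Rint <- frpecect:::cpp_frpe_residual(model@coords, model@elements,
                                         frpecect:::.stateVector(model), Un,
                                         schedule[i, "dt"], matv, fib)
    efflux <- efflux + sum(Rint[drained]) * schedule[i, "dt"]
  }
  v1 <- meshVolumes(model)[["current"]]
  ## volume lost by the tissue equals net fluid outflow through the
  ## drained faces (incompressible constituents)
  expect_gt(abs(v0 - v1), 1e-14)  # the balance is nontrivial
  ## the pressure-row reaction at a drained node is minus the outflux
  expect_equal(unname(-efflux / (v0 - v1)), 1, tolerance = 1e-3)
})

test_that("pressure dissipates to under 1% of its ramp peak over a full hold", {
  p <- FRPEParameters(E_f0 = 0.29, E_feps = 10.1, E_nf = 0.13,
                      k0 = 4.7e-15, M = 20.5)
  m <- buildMesh(1.2e-3, 2e-3, 0.275e-3, n_r = 6, n_z = 4, material = p)
  proto <- loadingProtocol(nSteps = 1)
  cur <- simulateStressRelaxation(m, proto, holdSteps = 40)
  U <- cur@metadata$final_state
  pEnd <- max(abs(U[seq(3, length(U), by = 3)]))
  ## ramp-peak pressure scale: the force jump over the contact area
  f <- forces(cur); sb <- stepBounds(cur)
  pPeak <- (max(f) - f[1]) / (pi * (0.275e-3)^2)
  expect_lt(pEnd / pPeak, 0.01)
})

test_that("equilibrium forces are mesh-converged near the production density", {
  p <- FRPEParameters(E_f0 = 0.29, E_feps = 10.1, E_nf = 0.13,
                      k0 = 4.7e-15, M = 20.5)
  m1 <- buildMesh(1.2e-3, 2e-3, 0.275e-3, n_r = 25, n_z = 14, material = p)
  m2 <- buildMesh(1.2e-3, 2e-3, 0.275e-3, n_r = 50, n_z = 28, material = p)
  d <- 0.06e-3
  f1 <- staticIndentationForce(m1, d)
  f2 <- staticIndentationForce(m2, d)
  expect_equal(f1 / f2, 1, tolerance = 0.02)
})

test_that("impossible protocols are rejected", {
  p <- noFibrilParams()
  m <- buildMesh(1e-3, 2e-3, 0.275e-3, n_r = 6, n_z = 4, material = p)
  expect_error(simulateStressRelaxation(
    m, loadingProtocol(nSteps = 4, stepFraction = 0.3)),
    "thickness")
  expect_error(loadingProtocol(stepFraction = 1.2))
  expect_error(loadingProtocol(relaxTime = -1))
})
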