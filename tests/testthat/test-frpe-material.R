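test_that("elastic moduli follow the bulk/shear conversion", {
  m <- elasticModuli(1.0, 0.0)
  expect_equal(m$K_nf, 1 / 3)
  expect_equal(m$G_nf, 1 / 2)

  m <- elasticModuli(0.42, 0.42)
  expect_equal(m$K_nf, 0.875, tolerance = 1e-12)
  expect_equal(m$G_nf, 0.42 / (2 * 1.42), tolerance = 1e-12)
  expect_equal(m$G_nf, 0.14789, tolerance = 1e-4)

  m <- elasticModuli(0, 0.42)
  expect_equal(m$K_nf, 0)
  expect_equal(m$G_nf, 0)

  expect_error(elasticModuli(1, 0.5), "incompressible")
  expect_error(elasticModuli(-1, 0.3), ">= 0")
})

test_that("non-fibrillar Neo-Hookean stress matches direct substitution", {
  m <- elasticModuli(1.0, 0.3)
  expect_equal(nonfibrillarStress(diag(3), m), matrix(0, 3, 3))

  F <- 1.01 * diag(3)
  J <- 1.01^3
  expected <- (0.5 * m$K_nf * (J - 1) / J +
                 m$G_nf / J * (1.01^2 - J^(2 / 3))) * diag(3)
  expect_equal(nonfibrillarStress(F, m), expected, tolerance = 1e-12)

  expect_error(nonfibrillarStress(-diag(3), m), "inverted")
})

test_that("non-fibrillar stress linearises to the isotropic law with (K/2, G)", {
  ## the volumetric term (1/2) K (J-1)/J linearises to half the bulk
  ## modulus; the linear-limit oracle uses (K/2, G)
  m <- elasticModuli(1.0, 0.3)
  eps <- 1e-4
  F <- diag(c(1 + eps, 1, 1))
  sig <- nonfibrillarStress(F, m)
  E <- matrix(0, 3, 3); E[1, 1] <- eps
  lin <- (m$K_nf / 2) * sum(diag(E)) * diag(3) +
    2 * m$G_nf * (E - sum(diag(E)) / 3 * diag(3))
  expect_equal(sig, lin, tolerance = 1e-3)

  ## shear path: pure deviatoric response is governed by G alone
  Fs <- diag(3); Fs[1, 2] <- eps
  sigS <- nonfibrillarStress(Fs, m)
  expect_equal(sigS[1, 2], m$G_nf * eps, tolerance = 1e-3)
})

test_that("fibril law is tension-only and quadratic in strain", {
  expect_equal(fibrilStress1d(0, 0.3, 10), 0)
  expect_equal(fibrilStress1d(-0.05, 0.3, 10), 0)
  expect_equal(fibrilStress1d(0.10, 0.3, 10), 0.08, tolerance = 1e-12)
  expect_equal(fibrilStress1d(c(-1, 0, 0.1), 0.3, 10), c(0, 0, 0.08))
})

test_that("fibril arrangement has 4 + 13 unit directions", {
  arr <- fibrilArrangement()
  expect_equal(nrow(arr$primary), 4)
  expect_equal(nrow(arr$secondary), 13)
  expect_equal(rowSums(arr$primary^2), rep(1, 4), tolerance = 1e-12)
  expect_equal(rowSums(arr$secondary^2), rep(1, 13), tolerance = 1e-12)
  ## primary fibrils lie parallel to the articulating surface
  expect_equal(arr$primary[, 3], rep(0, 4))
})

test_that("fibril network stress equals the explicit 17-term summation", {
  p <- FRPEParameters(E_f0 = 0.3, E_feps = 10, E_nf = 0.2)
  expect_equal(fibrilNetworkStress(diag(3), p), matrix(0, 3, 3))

  for (F in list(diag(c(1.05, 1, 1)), diag(c(0.98, 0.98, 1.06)),
                 diag(c(1.02, 1.03, 0.97)))) {
    expect_equal(fibrilNetworkStress(F, p),
                 bruteForceFibrilStress(F, 0.3, 10, p@C),
                 tolerance = 1e-12)
  }
})

test_that("doubling C doubles only the primary-fibril contribution", {
  F <- diag(c(1.04, 1.01, 0.97))
  p1 <- FRPEParameters(E_f0 = 0.3, E_feps = 10, C = 12.16)
  p2 <- FRPEParameters(E_f0 = 0.3, E_feps = 10, C = 2 * 12.16)
  arr <- fibrilArrangement()
  sec <- bruteForceFibrilStress(F, 0.3, 10, C = 0)  # secondary family only
  s1 <- fibrilNetworkStress(F, p1, arr)
  s2 <- fibrilNetworkStress(F, p2, arr)
  expect_equal(s2 - sec, 2 * (s1 - sec), tolerance = 1e-12)
})

test_that("fibril stress has zero projection along non-stretched directions", {
  p <- FRPEParameters(E_f0 = 0.5, E_feps = 20)
  ## axial compression with lateral bulging: every direction with a z
  ## component shortens; only surface-parallel fibrils load
  F <- diag(c(1.03, 1.03, 0.9))
  sig <- fibrilNetworkStress(F, p)
  expect_equal(sig[3, 3], 0)
  expect_gt(sig[1, 1], 0)
  ## all-compressive state: nothing carries load
  expect_equal(fibrilNetworkStress(0.95 * diag(3), p), matrix(0, 3, 3))
})

test_that("stresses are objective under rigid rotations", {
  set.seed(42)
  p <- FRPEParameters(E_f0 = 0.3, E_feps = 10, E_nf = 0.4)
  m <- elasticModuli(p@E_nf, p@nu_nf)
  for (i in 1:5) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.03), 3, 3)
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0),
                c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    R <- Rz %*% Rx
    expect_equal(nonfibrillarStress(R %*% F, m),
                 R %*% nonfibrillarStress(F, m) %*% t(R), tolerance = 1e-9)
    expect_equal(fibrilNetworkStress(R %*% F, p),
                 R %*% fibrilNetworkStress(F, p) %*% t(R), tolerance = 1e-9)
  }
})

test_that("permeability follows the void-ratio power law", {
  p <- FRPEParameters(k0 = 4.7e-15, M = 5)
  expect_equal(updatePermeability(3.5, p), 4.7e-15)
  p0 <- FRPEParameters(k0 = 4.7e-15, M = 0)
  expect_equal(updatePermeability(c(0.5, 2, 7), p0), rep(4.7e-15, 3))
  expect_equal(updatePermeability(3.0, p), 4.7e-15 * (4 / 4.5)^5,
               tolerance = 1e-12)
  expect_equal(updatePermeability(3.0, p), 2.608e-15, tolerance = 1e-3)
  ## nondecreasing in e for M >= 0
  e <- seq(0, 8, by = 0.25)
  expect_true(all(diff(updatePermeability(e, p)) >= 0))
})

test_that("total stress assembles sigma_nf + sigma_f - p I", {
  z <- matrix(0, 3, 3)
  expect_equal(totalStress(z, z, 1)$sigma_t, -diag(3))
  set.seed(7)
  for (i in 1:5) {
    a <- matrix(rnorm(9), 3, 3); a <- (a + t(a)) / 2
    b <- matrix(rnorm(9), 3, 3); b <- (b + t(b)) / 2
    pv <- rnorm(1)
    expect_equal(totalStress(a, b, pv)$sigma_t, a + b - pv * diag(3))
    expect_equal(totalStress(a, b, 0)$sigma_t, a + b)
  }
  asym <- matrix(1:9, 3, 3)
  expect_error(totalStress(asym, z, 0), "symmetric")
})

test_that("void ratio maps to fluid fraction", {
  expect_equal(round(100 * voidRatioToFluidFraction(3.5)), 78)
  expect_equal(voidRatioToFluidFraction(0), 0)
  expect_equal(voidRatioToFluidFraction(1), 0.5)
})

test_that("parameter container validates its invariants", {
  expect_error(FRPEParameters(k0 = 0), "k0")
  expect_error(FRPEParameters(nu_nf = 0.5), "nu_nf")
  expect_error(FRPEParameters(E_nf = -1), "moduli")
  expect_error(FRPEParameters(M = -2), "M must")
  p <- FRPEParameters(E_f0 = 0.29, E_feps = 10.1, E_nf = 0.13,
                      k0 = 4.7e-15, M = 20.5)
  v <- as.vector(p)
  expect_equal(unname(v[c("E_nf", "C", "e0")]), c(0.13, 12.16, 3.5))
})
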