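# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Closed-form consolidation series for a laterally confined column under a
# step axial traction: drained at zeta = 0 (top), impermeable at zeta = 1
# (base). Returns p / sigma0.
terzaghiSeries <- function(zeta, Tv, nterm = 500) {
  s <- 0
  for (m in 0:nterm) {
    lam <- (2 * m + 1) * pi / 2
    s <- s + 4 / ((2 * m + 1) * pi) * sin(lam * zeta) * exp(-lam^2 * Tv)
  }
  s
}

# Independent small-strain linear-elastic axisymmetric FE solve of the
# indentation problem: bilinear quads, dense assembly, B-matrix
# formulation. Returns the reaction force on the contact nodes for a
# prescribed indenter displacement d (m). K and G are the target moduli
# (Pa).
linearElasticIndentationForce <- function(model, d, K, G) {
  coords <- model@coords
  conn <- model@elements
  nn <- nrow(coords)
  lam <- K - 2 * G / 3
  D <- matrix(c(lam + 2 * G, lam, lam, 0,
                lam, lam + 2 * G, lam, 0,
                lam, lam, lam + 2 * G, 0,
                0, 0, 0, G), 4, 4, byrow = TRUE)
  gp <- 1 / sqrt(3)
  pts <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp))
  xiN <- c(-1, 1, 1, -1); etN <- c(-1, -1, 1, 1)
  Kg <- matrix(0, 2 * nn, 2 * nn)
  for (e in seq_len(nrow(conn))) {
    nd <- conn[e, ]
    xe <- coords[nd, 1]; ze <- coords[nd, 2]
    Ke <- matrix(0, 8, 8)
    for (g in 1:4) {
      xi <- pts[g, 1]; eta <- pts[g, 2]
      N <- 0.25 * (1 + xi * xiN) * (1 + eta * etN)
      dNxi <- 0.25 * xiN * (1 + eta * etN)
      dNet <- 0.25 * etN * (1 + xi * xiN)
      J <- rbind(c(sum(dNxi * xe), sum(dNxi * ze)),
                 c(sum(dNet * xe), sum(dNet * ze)))
      dJ <- det(J)
      dN <- solve(J, rbind(dNxi, dNet))
      r <- sum(N * xe)
      B <- matrix(0, 4, 8)
      for (a in 1:4) {
        B[1, 2 * a - 1] <- dN[1, a]          # e_rr
        B[2, 2 * a] <- dN[2, a]              # e_zz
        B[3, 2 * a - 1] <- N[a] / r          # e_theta
        B[4, 2 * a - 1] <- dN[2, a]          # gamma_rz
        B[4, 2 * a] <- dN[1, a]
      }
      Ke <- Ke + t(B) %*% D %*% B * 2 * pi * r * dJ
    }
    idx <- as.vector(rbind(2 * nd - 1, 2 * nd))
    Kg[idx, idx] <- Kg[idx, idx] + Ke
  }
  ns <- model@nodeSets
  fixed <- c(2 * ns$bottom - 1, 2 * ns$bottom, 2 * ns$axis - 1)
  presc <- 2 * ns$contact
  u <- numeric(2 * nn)
  u[presc] <- -d
  free <- setdiff(seq_len(2 * nn), c(fixed, presc))
  rhs <- -Kg[free, c(fixed, presc), drop = FALSE] %*% u[c(fixed, presc)]
  u[free] <- solve(Kg[free, free], rhs)
  f <- Kg %*% u
  -sum(f[presc])
}

# Brute-force fibril network stress: explicit 17-direction summation
# written independently of the package (Cartesian x, y, z with z axial).
bruteForceFibrilStress <- function(F, E_f0, E_feps, C, rho_z = 1) {
  s2 <- 1 / sqrt(2); s3 <- 1 / sqrt(3)
  prim <- list(c(1, 0, 0), c(0, 1, 0), c(s2, s2, 0), c(s2, -s2, 0))
  sec <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(s2, s2, 0), c(s2, -s2, 0), c(s2, 0, s2), c(s2, 0, -s2),
              c(0, s2, s2), c(0, s2, -s2),
              c(s3, s3, s3), c(s3, s3, -s3), c(s3, -s3, s3), c(s3, -s3, -s3))
  law <- function(eps) if (eps > 0) 0.5 * E_feps * eps^2 + E_f0 * eps else 0
  sig <- matrix(0, 3, 3)
  for (n0 in prim) {
    v <- as.numeric(F %*% n0); l <- sqrt(sum(v^2)); eps <- log(l)
    sig <- sig + (rho_z * C / 4) * law(eps) * (v %o% v) / l^2
  }
  for (n0 in sec) {
    v <- as.numeric(F %*% n0); l <- sqrt(sum(v^2)); eps <- log(l)
    sig <- sig + (rho_z / 13) * law(eps) * (v %o% v) / l^2
  }
  sig
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all group
# labelings (small n only).
bruteForceMannWhitneyP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  uStat <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- uStat(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, uStat)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Shared quick-test fixtures
coarseDemoGeometry <- function() list(thickness = 1.2e-3, sampleRadius = 2e-3,
                                      indenterRadius = 0.275e-3)

coarseFitConfig <- function(...) {
  args <- utils::modifyList(list(meshNr = 8L, meshNz = 5L, holdSteps = 30L,
                                 nStarts = 6L, nRefine = 2L, seed = 11L),
                            list(...))
  do.call(fitConfig, args)
}
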