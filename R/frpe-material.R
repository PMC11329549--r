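## Point-level FRPE constitutive model.
##
## Total stress decomposes as sigma_t = sigma_nf + sigma_f - p I: a
## Neo-Hookean non-fibrillar (proteoglycan) matrix, a tension-only collagen
## fibril network over 4 primary + 13 secondary directions, and pore fluid
## pressure. Permeability follows the void-ratio power law
## k = k0 ((1+e)/(1+e0))^M. These R functions are the reference
## implementation of the material; the finite-element solver evaluates the
## same laws in compiled code at Gauss points.

#' Bulk and shear moduli of the non-fibrillar matrix
#'
#' Converts the non-fibrillar elastic modulus and Poisson's ratio into the
#' bulk and shear moduli used by the Neo-Hookean law:
#' \eqn{K = E/(3(1-2\nu))}, \eqn{G = E/(2(1+\nu))}.
#'
#' @param E_nf non-fibrillar matrix modulus (any stress unit; output matches)
#' @param nu_nf Poisson's ratio, in [0, 0.5)
#' @return list with components \code{K_nf} and \code{G_nf}
#' @examples
#' elasticModuli(0.42, 0.42)
#' @export
elasticModuli <- function(E_nf, nu_nf) {
  if (!is.finite(E_nf) || E_nf < 0) stop("E_nf must be a finite number >= 0")
  if (!is.finite(nu_nf) || nu_nf < 0 || nu_nf >= 0.5)
    stop("nu_nf must lie in [0, 0.5); nu_nf = 0.5 is incompressible")
  list(K_nf = E_nf / (3 * (1 - 2 * nu_nf)),
       G_nf = E_nf / (2 * (1 + nu_nf)))
}

#' Neo-Hookean non-fibrillar matrix stress
#'
#' Cauchy stress of the non-fibrillar matrix,
#' \eqn{\sigma_{nf} = \tfrac12 K (J-1)/J \, I + (G/J)(F F^T - J^{2/3} I)}.
#'
#' @param F 3x3 deformation gradient
#' @param moduli list with \code{K_nf}, \code{G_nf} (see
#'   \code{\link{elasticModuli}})
#' @return symmetric 3x3 Cauchy stress in the units of the moduli
#' @examples
#' m <- elasticModuli(1, 0.42)
#' nonfibrillarStress(diag(3), m)          # zero at the undeformed state
#' @export
nonfibrillarStress <- function(F, moduli) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("inverted element: det(F) must be > 0")
  I3 <- diag(3)
  s <- 0.5 * moduli$K_nf * (J - 1) / J * I3 +
    moduli$G_nf / J * (F %*% t(F) - J^(2 / 3) * I3)
  (s + t(s)) / 2
}

#' Tension-only stress of a single collagen fibril
#'
#' \eqn{\sigma_f = \tfrac12 E_f^\epsilon \epsilon_f^2 + E_f^0 \epsilon_f}
#' for fibril strain \eqn{\epsilon_f > 0}; fibrils carry no load in
#' compression.
#'
#' @param eps_f fibril strain (logarithmic strain of the fibre stretch);
#'   vectorised
#' @param E_f0 initial fibril network modulus
#' @param E_feps strain-dependent fibril network modulus
#' @return fibril stress, same units as the moduli
#' @examples
#' fibrilStress1d(0.10, 0.3, 10)   # 0.08
#' fibrilStress1d(-0.05, 0.3, 10)  # 0: compression carries no fibril load
#' @export
fibrilStress1d <- function(eps_f, E_f0, E_feps) {
  stopifnot(all(is.finite(eps_f)), is.finite(E_f0), is.finite(E_feps))
  ifelse(eps_f > 0, 0.5 * E_feps * eps_f^2 + E_f0 * eps_f, 0)
}

#' Fibril direction arrangement
#'
#' The collagen network uses 4 organised primary fibrils forming a mesh-like
#' structure parallel to the articulating surface (the x-y plane here; z is
#' the depth/axial direction) and 13 secondary fibrils along the coordinate
#' axes and all 45-degree diagonals.
#'
#' @return list with \code{primary} (4 x 3) and \code{secondary} (13 x 3)
#'   matrices of unit direction vectors (rows)
#' @export
fibrilArrangement <- function() {
  s2 <- 1 / sqrt(2)
  s3 <- 1 / sqrt(3)
  primary <- rbind(c(1, 0, 0), c(0, 1, 0), c(s2, s2, 0), c(s2, -s2, 0))
  secondary <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(s2, s2, 0), c(s2, -s2, 0),
    c(s2, 0, s2), c(s2, 0, -s2),
    c(0, s2, s2), c(0, s2, -s2),
    c(s3, s3, s3), c(s3, s3, -s3), c(s3, -s3, s3), c(s3, -s3, -s3))
  list(primary = primary, secondary = secondary)
}

#' Fibril network Cauchy stress
#'
#' Convects every fibril direction by the deformation gradient, evaluates the
#' tension-only fibril law on the logarithmic fibre strain, scales primary
#' fibrils by \code{rho_z * C} and secondary fibrils by \code{rho_z}, and
#' assembles rank-one Cauchy contributions along the deformed directions.
#' Contributions are averaged within each family (weights 1/4 and 1/13).
#'
#' @param F 3x3 deformation gradient
#' @param params a \linkS4class{FRPEParameters} object (moduli in MPa)
#' @param arr fibril arrangement, see \code{\link{fibrilArrangement}}
#' @return symmetric 3x3 fibril network Cauchy stress (MPa)
#' @export
fibrilNetworkStress <- function(F, params, arr = fibrilArrangement()) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  if (det(F) <= 0) stop("inverted element: det(F) must be > 0")
  stopifnot(nrow(arr$primary) == 4, nrow(arr$secondary) == 13)
  sig <- matrix(0, 3, 3)
  addFamily <- function(dirs, familyScale, sig) {
    w <- 1 / nrow(dirs)
    for (i in seq_len(nrow(dirs))) {
      v <- as.numeric(F %*% dirs[i, ])
      lam <- sqrt(sum(v^2))
      eps <- log(lam)
      if (eps > 0) {
        s <- fibrilStress1d(eps, params@E_f0, params@E_feps)
        m <- v / lam
        sig <- sig + w * familyScale * s * tcrossprod(m)
      }
    }
    sig
  }
  sig <- addFamily(arr$primary, params@rho_z * params@C, sig)
  sig <- addFamily(arr$secondary, params@rho_z, sig)
  (sig + t(sig)) / 2
}

#' Strain-dependent permeability
#'
#' \eqn{k = k_0 ((1+e)/(1+e_0))^M}: compaction (lower void ratio) reduces
#' permeability for \code{M > 0}.
#'
#' @param e current void ratio (>= 0); vectorised
#' @param params a \linkS4class{FRPEParameters} object
#' @return permeability in the units of \code{k0}
#' @examples
#' p <- FRPEParameters(k0 = 4.7e-15, M = 5)
#' updatePermeability(3.5, p)  # reference state: k = k0
#' @export
updatePermeability <- function(e, params) {
  stopifnot(all(is.finite(e)), all(e >= 0))
  params@k0 * ((1 + e) / (1 + params@e0))^params@M
}

#' Total stress assembly
#'
#' \eqn{\sigma_t = \sigma_{nf} + \sigma_f - p I}.
#'
#' @param sigma_nf,sigma_f symmetric 3x3 stress tensors
#' @param p pore fluid pressure (same units)
#' @return list with \code{sigma_nf}, \code{sigma_f} and \code{sigma_t}
#' @export
totalStress <- function(sigma_nf, sigma_f, p) {
  checkSym <- function(s, nm) {
    stopifnot(is.matrix(s), all(dim(s) == c(3, 3)))
    if (max(abs(s - t(s))) > 1e-8 * max(abs(s), 1))
      stop(nm, " must be symmetric")
  }
  checkSym(sigma_nf, "sigma_nf")
  checkSym(sigma_f, "sigma_f")
  list(sigma_nf = sigma_nf, sigma_f = sigma_f,
       sigma_t = sigma_nf + sigma_f - p * diag(3))
}

#' Fluid volume fraction from void ratio
#'
#' The void ratio e (fluid volume over solid volume) corresponds to a fluid
#' volume fraction e/(1+e); the default initial void ratio 3.5 gives 78%
#' fluid to the nearest percent.
#'
#' @param e void ratio (>= 0); vectorised
#' @return fluid volume fraction in [0, 1)
#' @examples
#' voidRatioToFluidFraction(3.5)
#' @export
voidRatioToFluidFraction <- function(e) {
  stopifnot(all(is.finite(e)), all(e >= 0))
  e / (1 + e)
}
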