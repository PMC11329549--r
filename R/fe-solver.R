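## Driver layer over the compiled axisymmetric poroelastic solver:
## boundary conditions, time stepping with step halving, the indentation
## protocol, and verification geometries.

#' Solver control settings
#'
#' Newton and time-integration tolerances for the coupled
#' displacement/pore-pressure solver. The Newton iteration stops when the
#' residual norm falls below \code{tol_rel} times its initial value, or
#' below the absolute floors (\code{abs_u} in N for momentum, \code{abs_p}
#' in m^3/s for mass balance). \code{h_u}/\code{h_p} are the
#' central-difference steps used for the element tangents; \code{stab} is
#' the equal-order pressure-stabilisation coefficient (dimensionless).
#'
#' @param max_iter maximum Newton iterations per step
#' @param tol_rel relative residual tolerance
#' @param abs_u absolute momentum residual floor (N)
#' @param abs_p absolute mass residual floor (m^3/s)
#' @param h_u finite-difference step for displacement dofs (m)
#' @param h_p finite-difference step for pressure dofs (Pa)
#' @param stab pressure-projection stabilisation coefficient
#' @param max_halving maximum recursive step halvings on Newton failure
#' @return a named list of class \code{feControl}
#' @export
feControl <- function(max_iter = 30L, tol_rel = 1e-8, abs_u = 1e-12,
                      abs_p = 1e-20, h_u = 1e-10, h_p = 1e-2, stab = 0.1,
                      max_halving = 6L) {
  structure(list(max_iter = as.integer(max_iter), tol_rel = tol_rel,
                 abs_u = abs_u, abs_p = abs_p, h_u = h_u, h_p = h_p,
                 stab = stab, max_halving = as.integer(max_halving)),
            class = "feControl")
}

#' Stress-relaxation loading protocol
#'
#' The indentation protocol: an equilibrium pre-stress (default 40 kPa over
#' the indenter face), then \code{nSteps} compression ramps each of
#' \code{stepFraction} of the remaining cartilage thickness at a ramp rate
#' of \code{rampRate} thicknesses per second (1.0 = 100%/s), each followed
#' by \code{relaxTime} seconds of relaxation.
#'
#' @param prestress equilibrium pre-stress target (Pa)
#' @param nSteps number of compression steps
#' @param stepFraction step amplitude as a fraction of remaining thickness
#' @param rampRate ramp speed, thickness fractions per second
#' @param relaxTime hold duration per step (s)
#' @param indenterDiameter indenter diameter (m)
#' @param prestressMode \code{"simulated"} solves the pre-stress
#'   equilibrium and keeps its stress state; \code{"reference"} starts from
#'   an unstressed configuration
#' @return a named list of class \code{loadingProtocol}
#' @export
loadingProtocol <- function(prestress = 40e3, nSteps = 4L,
                            stepFraction = 0.04, rampRate = 1.0,
                            relaxTime = 600, indenterDiameter = 0.55e-3,
                            prestressMode = c("simulated", "reference")) {
  prestressMode <- match.arg(prestressMode)
  stopifnot(prestress >= 0, nSteps >= 1, stepFraction > 0, stepFraction < 1,
            rampRate > 0, relaxTime > 0, indenterDiameter > 0)
  structure(list(prestress = prestress, nSteps = as.integer(nSteps),
                 stepFraction = stepFraction, rampRate = rampRate,
                 relaxTime = relaxTime, indenterDiameter = indenterDiameter,
                 prestressMode = prestressMode),
            class = "loadingProtocol")
}

## material vector in SI units for the compiled kernel
.matVec <- function(params, stab) {
  c(params@E_f0 * 1e6, params@E_feps * 1e6, params@E_nf * 1e6,
    params@k0, params@M, params@nu_nf, params@e0, stab)
}

## fibril directions in (r, z, theta) with family weights; 0-row matrix
## disables the fibril network
.fibMat <- function(params, fibrils = TRUE) {
  if (!fibrils || (params@E_f0 == 0 && params@E_feps == 0))
    return(matrix(0, 0, 4))
  arr <- fibrilArrangement()
  # Cartesian (x, y, z): x -> r, y -> theta (hoop), z -> axial
  toRZT <- function(m) cbind(m[, 1], m[, 3], m[, 2])
  prim <- cbind(toRZT(arr$primary), params@rho_z * params@C / 4)
  sec <- cbind(toRZT(arr$secondary), params@rho_z / 13)
  rbind(prim, sec)
}

.dof <- function(node, comp) 3L * (node - 1L) + comp

## Dirichlet sets for the indentation problem. d = indenter displacement
## (positive = into the tissue). drainedAll fixes every pressure dof at 0
## (static drained solve).
.indentBC <- function(model, d, drainedAll = FALSE) {
  ns <- model@nodeSets
  idx <- c(.dof(ns$bottom, 1L), .dof(ns$bottom, 2L), .dof(ns$axis, 1L),
           .dof(ns$contact, 2L))
  val <- c(rep(0, 2 * length(ns$bottom) + length(ns$axis)),
           rep(-d, length(ns$contact)))
  pn <- if (drainedAll) seq_len(nrow(model@coords))
        else sort(unique(c(ns$surfaceFree, ns$lateral)))
  idx <- c(idx, .dof(pn, 3L))
  val <- c(val, rep(0, length(pn)))
  keep <- !duplicated(idx)
  list(idx = as.integer(idx[keep]), val = val[keep])
}

## One backward-Euler increment with recursive halving of both dt and the
## prescribed-value increment on Newton failure.
.solveIncrement <- function(model, U_n, dt, bcFrom, bcTo, fext, matv, fib,
                            control, depth = 0L) {
  st <- cpp_frpe_step(model@coords, model@elements, U_n, U_n, dt, matv, fib,
                      bcTo$idx, bcTo$val, fext,
                      control[c("max_iter", "tol_rel", "abs_u", "abs_p",
                                "h_u", "h_p")])
  if (st$converged) return(st)
  if (depth >= control$max_halving)
    stop("FE solver failed to converge after ", depth, " step halvings: ",
         st$err)
  bcMid <- bcTo
  bcMid$val <- (bcFrom$val + bcTo$val) / 2
  s1 <- .solveIncrement(model, U_n, dt / 2, bcFrom, bcMid, fext, matv, fib,
                        control, depth + 1L)
  .solveIncrement(model, s1$U, dt / 2, bcMid, bcTo, fext, matv, fib,
                  control, depth + 1L)
}

## axial reaction force (N, positive in compression) from an internal
## residual vector
.reactionForce <- function(model, residual) {
  -sum(residual[.dof(model@nodeSets$contact, 2L)])
}

.stateVector <- function(model) {
  U <- numeric(3 * nrow(model@coords))
  U[seq(1, length(U), by = 3)] <- model@displacements[, 1]
  U[seq(2, length(U), by = 3)] <- model@displacements[, 2]
  U[seq(3, length(U), by = 3)] <- model@pressures
  U
}

.setState <- function(model, U) {
  model@displacements <- cbind(U[seq(1, length(U), by = 3)],
                               U[seq(2, length(U), by = 3)])
  model@pressures <- U[seq(3, length(U), by = 3)]
  model
}

#' Advance the model by one time step
#'
#' Prescribes the indenter displacement and integrates the coupled
#' momentum/mass-balance system over one backward-Euler step, with Newton
#' iterations and automatic step halving.
#'
#' @param model an \linkS4class{FEModel}
#' @param dt time-step length (s)
#' @param indenterDisplacement prescribed indenter displacement (m, positive
#'   into the tissue)
#' @param control solver settings, see \code{\link{feControl}}
#' @return list with the updated \code{model} and the axial
#'   \code{reactionForce} (N) on the contact nodes
#' @export
solveTimeStep <- function(model, dt, indenterDisplacement,
                          control = feControl()) {
  stopifnot(dt > 0)
  matv <- .matVec(model@material, control$stab)
  fib <- .fibMat(model@material)
  U_n <- .stateVector(model)
  dPrev <- -min(model@displacements[model@nodeSets$contact, 2], 0)
  bcFrom <- .indentBC(model, dPrev)
  bcTo <- .indentBC(model, indenterDisplacement)
  st <- .solveIncrement(model, U_n, dt, bcFrom, bcTo,
                        numeric(length(U_n)), matv, fib, control)
  list(model = .setState(model, st$U),
       reactionForce = .reactionForce(model, st$residual))
}

## static drained equilibrium at prescribed indenter displacement;
## continuation from a supplied state. Returns list(U, force).
.staticSolve <- function(model, d, U_start, dStart, matv, fib, control,
                         nIncrements = 1L) {
  ds <- seq(dStart, d, length.out = nIncrements + 1L)[-1]
  U <- U_start
  dPrev <- dStart
  st <- NULL
  for (di in ds) {
    bcFrom <- .indentBC(model, dPrev, drainedAll = TRUE)
    bcTo <- .indentBC(model, di, drainedAll = TRUE)
    st <- .solveIncrement(model, U, 1e12, bcFrom, bcTo,
                          numeric(length(U)), matv, fib, control)
    U <- st$U
    dPrev <- di
  }
  list(U = U, force = .reactionForce(model, st$residual))
}

#' Drained equilibrium indentation force
#'
#' Solves the fully drained (zero pore pressure) static equilibrium at a
#' prescribed indenter displacement: the long-time limit of a
#' stress-relaxation hold.
#'
#' @inheritParams solveTimeStep
#' @param indenterDisplacement prescribed displacement (m)
#' @param nIncrements continuation increments for the static solve
#' @return equilibrium reaction force (N)
#' @export
staticIndentationForce <- function(model, indenterDisplacement,
                                   control = feControl(), nIncrements = 4L) {
  matv <- .matVec(model@material, control$stab)
  fib <- .fibMat(model@material)
  U0 <- .stateVector(model)
  .staticSolve(model, indenterDisplacement, U0, 0, matv, fib, control,
               nIncrements)$force
}

#' Find the pre-stress indenter displacement
#'
#' Secant iteration on the drained equilibrium displacement at which the
#' mean contact pressure (reaction force over the indenter face area)
#' equals the protocol pre-stress target, within 0.5%.
#'
#' @param model an \linkS4class{FEModel}
#' @param protocol a \code{\link{loadingProtocol}}
#' @param control solver settings
#' @return the displacement (m), with attributes \code{force} (N) and
#'   \code{state} (the equilibrium dof vector)
#' @export
findPrestressDisplacement <- function(model, protocol = loadingProtocol(),
                                      control = feControl()) {
  a <- protocol$indenterDiameter / 2
  targetF <- protocol$prestress * pi * a^2
  if (targetF == 0) {
    out <- 0
    attr(out, "force") <- 0
    attr(out, "state") <- .stateVector(model)
    return(out)
  }
  matv <- .matVec(model@material, control$stab)
  fib <- .fibMat(model@material)
  h <- model@geometry$thickness

  d0 <- 1e-3 * h
  s0 <- .staticSolve(model, d0, .stateVector(model), 0, matv, fib, control, 2L)
  F0 <- s0$force
  d1 <- min(0.3 * h, d0 * targetF / max(F0, .Machine$double.xmin))
  U <- s0$U
  dPrev <- d0
  F1 <- F0
  for (it in seq_len(40)) {
    s1 <- .staticSolve(model, d1, U, dPrev, matv, fib, control, 1L)
    F1 <- s1$force
    U <- s1$U
    if (abs(F1 - targetF) <= 0.005 * targetF) {
      out <- d1
      attr(out, "force") <- F1
      attr(out, "state") <- U
      return(out)
    }
    dn <- d1 + (targetF - F1) * (d1 - d0) / (F1 - F0)
    if (!is.finite(dn) || dn <= 0) dn <- d1 * targetF / F1
    dn <- min(max(dn, 0.05 * d1), 3 * d1, 0.45 * h)
    d0 <- d1; F0 <- F1; dPrev <- d1; d1 <- dn
  }
  stop(sprintf(paste0("pre-stress displacement not bracketed: reached force ",
                      "%.3g N for target %.3g N"), F1, targetF))
}

#' Simulate a stress-relaxation indentation test
#'
#' Applies the loading protocol to the model: pre-stress equilibrium, then
#' \code{nSteps} displacement ramps (each a fraction of the remaining
#' cartilage thickness, interpreted as initial thickness minus total imposed
#' compression) with uniform sub-stepping, each followed by a relaxation
#' hold integrated on a geometrically growing time grid.
#'
#' @param model an \linkS4class{FEModel}
#' @param protocol a \code{\link{loadingProtocol}}
#' @param control solver settings, see \code{\link{feControl}}
#' @param rampSubsteps sub-steps per ramp (at least 20)
#' @param holdSteps time steps per relaxation hold
#' @return a \linkS4class{ForceTimeCurve}; metadata records the thickness,
#'   protocol, pre-stress displacement and force
#' @export
simulateStressRelaxation <- function(model, protocol = loadingProtocol(),
                                     control = feControl(),
                                     rampSubsteps = 20L, holdSteps = 60L) {
  rampSubsteps <- max(20L, as.integer(rampSubsteps))
  h <- model@geometry$thickness
  if (protocol$stepFraction * protocol$nSteps >= 1)
    stop("protocol compresses the full thickness")

  matv <- .matVec(model@material, control$stab)
  fib <- .fibMat(model@material)
  n3 <- 3 * nrow(model@coords)
  fext <- numeric(n3)

  if (protocol$prestress > 0 && protocol$prestressMode == "simulated") {
    dPre <- findPrestressDisplacement(model, protocol, control)
    U <- attr(dPre, "state")
    F0 <- attr(dPre, "force")
    dCur <- as.numeric(dPre)
  } else {
    U <- .stateVector(model)
    F0 <- 0
    dCur <- 0
  }
  dPrestress <- dCur

  tvec <- 0
  Fvec <- F0
  rampStart <- integer(protocol$nSteps)
  holdEnd <- integer(protocol$nSteps)
  tCur <- 0

  ## geometric hold grid: first step matches the ramp substep length
  holdGrid <- function(dt0, total, n) {
    g <- stats::uniroot(function(g) dt0 * (g^n - 1) / (g - 1) - total,
                        c(1 + 1e-8, 5), tol = 1e-13)$root
    dt0 * g^(seq_len(n) - 1)
  }

  for (s in seq_len(protocol$nSteps)) {
    remaining <- h - dCur
    amp <- protocol$stepFraction * remaining
    if (dCur + amp >= h) stop("cumulative compression exceeds thickness")
    rampDur <- amp / (protocol$rampRate * h)
    dtR <- rampDur / rampSubsteps
    rampStart[s] <- length(tvec) + 1L

    targets <- dCur + amp * seq_len(rampSubsteps) / rampSubsteps
    for (dTar in targets) {
      bcFrom <- .indentBC(model, dCur)
      bcTo <- .indentBC(model, dTar)
      st <- .solveIncrement(model, U, dtR, bcFrom, bcTo, fext, matv, fib,
                            control)
      U <- st$U
      dCur <- dTar
      tCur <- tCur + dtR
      tvec <- c(tvec, tCur)
      Fvec <- c(Fvec, .reactionForce(model, st$residual))
    }

    dts <- holdGrid(dtR, protocol$relaxTime, holdSteps)
    bc <- .indentBC(model, dCur)
    for (dt in dts) {
      st <- .solveIncrement(model, U, dt, bc, bc, fext, matv, fib, control)
      U <- st$U
      tCur <- tCur + dt
      tvec <- c(tvec, tCur)
      Fvec <- c(Fvec, .reactionForce(model, st$residual))
    }
    holdEnd[s] <- length(tvec)
  }

  ForceTimeCurve(tvec, Fvec, cbind(ramp_start = rampStart, hold_end = holdEnd),
                 metadata = list(thickness_m = h,
                                 protocol = unclass(protocol),
                                 prestress_displacement_m = dPrestress,
                                 prestress_force_N = F0,
                                 final_state = U,
                                 solver = list(rampSubsteps = rampSubsteps,
                                               holdSteps = holdSteps)))
}

#' Resample a force-time curve onto a log-spaced reporting grid
#'
#' Interpolates the curve onto \code{nPerHold} log-spaced samples per
#' relaxation hold (plus the original ramp samples), the reporting
#' convention for stress-relaxation data whose early transients decay
#' quickly.
#'
#' @param curve a \linkS4class{ForceTimeCurve}
#' @param nPerHold samples per hold
#' @return a resampled \linkS4class{ForceTimeCurve}
#' @export
resampleLogGrid <- function(curve, nPerHold = 1000L) {
  sb <- curve@stepBounds
  if (!nrow(sb)) return(curve)
  t <- curve@times
  keep <- list()
  newBounds <- matrix(0L, nrow(sb), 2,
                      dimnames = list(NULL, c("ramp_start", "hold_end")))
  out_t <- t[1]
  for (s in seq_len(nrow(sb))) {
    rs <- sb[s, 1]; he <- sb[s, 2]
    # ramp samples: find the hold start = last time the displacement ramped;
    # approximate as the ramp block up to the force peak index
    rampT <- t[rs:he]
    peak <- rs - 1 + which.max(curve@forces[rs:he])
    newBounds[s, 1] <- length(out_t) + 1L
    out_t <- c(out_t, t[rs:peak])
    t0 <- t[peak]; t1 <- t[he]
    lg <- t0 + (t1 - t0) * (exp(seq(0, log(1 + 599), length.out = nPerHold)) - 1) / 599
    out_t <- c(out_t, lg[-1])
    newBounds[s, 2] <- length(out_t)
  }
  f <- stats::approx(t, curve@forces, xout = out_t, rule = 2)$y
  ForceTimeCurve(out_t, f, newBounds, curve@metadata)
}

#' Simulate confined compression consolidation
#'
#' A laterally confined cartilage column under a step axial traction with a
#' drained top surface and impermeable base: the standard consolidation
#' verification geometry with a closed-form series solution in the linear
#' small-strain limit.
#'
#' @param params \linkS4class{FRPEParameters}; set the fibril moduli to 0
#'   and \code{M = 0} for the linear verification case
#' @param height column height (m)
#' @param radius column radius (m)
#' @param n_z axial elements
#' @param n_r radial elements
#' @param sigma0 applied axial traction (Pa, positive = compression)
#' @param times output times (s), strictly increasing
#' @param nSubsteps backward-Euler substeps per output interval
#' @param control solver settings
#' @param fibrils include the fibril network (default FALSE)
#' @return list with \code{z} (node depths, m, 0 = base), \code{times},
#'   \code{pressure} (matrix, axis-column nodes x times, Pa),
#'   \code{settlement} (m, per time), and \code{model}
#' @export
simulateConfinedConsolidation <- function(params, height = 1e-3,
                                          radius = 0.5e-3, n_z = 30L,
                                          n_r = 2L, sigma0 = 100,
                                          times, nSubsteps = 1L,
                                          control = feControl(),
                                          fibrils = FALSE) {
  stopifnot(all(diff(times) > 0), times[1] > 0)
  model <- buildMesh(height, radius, radius * 0.5, n_r = max(3L, n_r),
                     n_z = n_z, material = params)
  ## confined: radial displacement fixed everywhere; bottom fixed;
  ## top drained; traction on the whole top surface
  n <- nrow(model@coords)
  ns <- model@nodeSets
  idx <- c(.dof(seq_len(n), 1L), .dof(ns$bottom, 2L), .dof(ns$surface, 3L))
  val <- rep(0, length(idx))
  bc <- list(idx = as.integer(idx), val = val)

  fext <- numeric(3 * n)
  surf <- ns$surface[order(model@coords[ns$surface, 1])]
  rs <- model@coords[surf, 1]
  for (i in seq_len(length(surf) - 1)) {
    r1 <- rs[i]; r2 <- rs[i + 1]; L <- r2 - r1
    f1 <- 2 * pi * (L * r1 / 2 + L^2 / 6) * (-sigma0)
    f2 <- 2 * pi * (L * r2 / 2 - L^2 / 6) * (-sigma0)
    fext[.dof(surf[i], 2L)] <- fext[.dof(surf[i], 2L)] + f1
    fext[.dof(surf[i + 1], 2L)] <- fext[.dof(surf[i + 1], 2L)] + f2
  }

  matv <- .matVec(params, control$stab)
  fib <- .fibMat(params, fibrils)
  U <- numeric(3 * n)
  axisCol <- which(abs(model@coords[, 1] - 0) < 1e-12)
  axisCol <- axisCol[order(model@coords[axisCol, 2])]
  P <- matrix(NA_real_, length(axisCol), length(times))
  settle <- numeric(length(times))
  tPrev <- 0
  for (j in seq_along(times)) {
    dts <- rep((times[j] - tPrev) / nSubsteps, nSubsteps)
    for (dt in dts) {
      st <- .solveIncrement(model, U, dt, bc, bc, fext, matv, fib, control)
      U <- st$U
    }
    P[, j] <- U[.dof(axisCol, 3L)]
    settle[j] <- -min(U[.dof(ns$surface, 2L)])
    tPrev <- times[j]
  }
  list(z = model@coords[axisCol, 2], times = times, pressure = P,
       settlement = settle, model = .setState(model, U))
}

#' Fluid volume bookkeeping
#'
#' Current and reference mesh volumes (integral of det F over the reference
#' domain), used for mass-conservation checks: with incompressible
#' constituents the change in total volume equals the net fluid efflux.
#'
#' @param model an \linkS4class{FEModel}
#' @return named numeric: \code{current}, \code{reference} (m^3)
#' @export
meshVolumes <- function(model) {
  cpp_volume_integrals(model@coords, model@elements, .stateVector(model))
}
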