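## Inverse identification of the five FRPE parameters from a measured
## stress-relaxation force curve.

#' Mean-squared relative error between measured and simulated forces
#'
#' The fitting objective: the mean over time samples of
#' \eqn{((F_{sim}-F_{meas})/F_{meas})^2}, restricted to the requested
#' relaxation steps (by default steps 2-4, from the ramp start of the first
#' included step to the end of the last included hold). The simulated curve
#' is resampled onto the measured time grid by monotone linear
#' interpolation.
#'
#' @param measured,simulated \linkS4class{ForceTimeCurve} objects; the
#'   measured curve must carry step boundaries
#' @param steps integer vector of step numbers to include
#' @return the dimensionless objective value
#' @examples
#' t <- seq(0, 10, by = 0.5)
#' sb <- cbind(ramp_start = c(1, 6, 11, 16), hold_end = c(5, 10, 15, 21))
#' a <- ForceTimeCurve(t, rep(1, 21), sb)
#' b <- ForceTimeCurve(t, rep(1.1, 21), sb)
#' objectiveMSRE(a, b)  # 0.01
#' @export
objectiveMSRE <- function(measured, simulated, steps = 2:4) {
  w <- .fitWindow(measured, steps)
  fm <- measured@forces[w]
  fs <- stats::approx(simulated@times, simulated@forces,
                      xout = measured@times[w], rule = 2)$y
  ok <- fm > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive measured force sample(s) excluded")
    fm <- fm[ok]; fs <- fs[ok]
  }
  if (!length(fm)) stop("empty fitting window")
  mean(((fs - fm) / fm)^2)
}

## time-sample indices of the fitting window (ramp start of the first
## included step through hold end of the last)
.fitWindow <- function(curve, steps) {
  sb <- curve@stepBounds
  if (!nrow(sb)) stop("curve carries no step boundaries")
  steps <- sort(steps)
  if (any(steps < 1 | steps > nrow(sb))) stop("step index out of range")
  seq(sb[steps[1], 1], sb[steps[length(steps)], 2])
}

#' Coefficient of determination of a fit
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} between measured and simulated forces
#' over an index window.
#'
#' @param measured,simulated numeric force vectors on a common grid
#' @param window integer indices to include (default: all)
#' @return the coefficient of determination (at most 1; can be negative)
#' @examples
#' goodnessOfFitR2(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
goodnessOfFitR2 <- function(measured, simulated, window = NULL) {
  if (is.null(window)) window <- seq_along(measured)
  stopifnot(length(measured) == length(simulated), length(window) >= 2)
  m <- measured[window]; s <- simulated[window]
  sst <- sum((m - mean(m))^2)
  if (sst == 0) stop("measured forces have zero variance in the window")
  1 - sum((s - m)^2) / sst
}

#' Inverse-fit configuration
#'
#' Bounds span the reported cartilage parameter ranges with generous
#' margin; the initial permeability is optimised in log10 space because it
#' spans orders of magnitude. Starts are Latin-hypercube samples of the
#' bounds; every start is screened with one forward solve and the
#' \code{nRefine} most promising are polished with bounded
#' Levenberg-Marquardt on the relative-residual vector.
#'
#' @param bounds named list of c(lower, upper) for \code{E_f0},
#'   \code{E_feps}, \code{E_nf} (MPa), \code{k0} (m^4/(N s)), \code{M}
#' @param nStarts number of Latin-hypercube multistarts
#' @param nRefine number of starts polished with full local optimisation
#' @param seed integer seed controlling the starts
#' @param meshNr,meshNz fitting-mesh density (radial/axial element counts)
#' @param rampSubsteps,holdSteps forward-solver time resolution
#' @param maxIter Levenberg-Marquardt iteration cap per start
#' @param r2Floor fits with R^2 below this are flagged (not excluded)
#' @param start optional explicit start (named vector like the bounds);
#'   when given it replaces the first Latin-hypercube start
#' @return a list of class \code{fitConfig}
#' @export
fitConfig <- function(bounds = list(E_f0 = c(0, 5), E_feps = c(0, 100),
                                    E_nf = c(0.01, 5), k0 = c(1e-17, 1e-13),
                                    M = c(0, 50)),
                      nStarts = 8L, nRefine = 3L, seed = 1L,
                      meshNr = 10L, meshNz = 6L, rampSubsteps = 20L,
                      holdSteps = 40L, maxIter = 30L, r2Floor = 0.8,
                      start = NULL) {
  structure(list(bounds = bounds, nStarts = as.integer(nStarts),
                 nRefine = as.integer(nRefine), seed = as.integer(seed),
                 meshNr = as.integer(meshNr), meshNz = as.integer(meshNz),
                 rampSubsteps = as.integer(rampSubsteps),
                 holdSteps = as.integer(holdSteps),
                 maxIter = as.integer(maxIter), r2Floor = r2Floor,
                 start = start),
            class = "fitConfig")
}

## internal: optimisation vector <-> FRPEParameters (k0 in log10)
.xToParams <- function(x, fixed) {
  FRPEParameters(E_f0 = x[1], E_feps = x[2], E_nf = x[3], k0 = 10^x[4],
                 M = x[5], nu_nf = fixed$nu_nf, e0 = fixed$e0, C = fixed$C,
                 rho_z = fixed$rho_z)
}

#' Fit FRPE parameters to a measured force-time curve
#'
#' Recovers the five sample-specific FRPE parameters (\code{E_f0},
#' \code{E_feps}, \code{E_nf}, \code{k0}, \code{M}) by minimising the
#' mean-squared relative force error over relaxation steps 2-4
#' (\code{\link{objectiveMSRE}}), using seeded Latin-hypercube multistarts
#' and bounded Levenberg-Marquardt. Deterministic for a fixed
#' configuration.
#'
#' @param measured a \linkS4class{ForceTimeCurve} with step boundaries and
#'   thickness metadata (or supply \code{geometry})
#' @param geometry list with \code{thickness}, \code{sampleRadius},
#'   \code{indenterRadius} (m); thickness defaults to the curve metadata
#' @param config a \code{\link{fitConfig}}
#' @param protocol the loading protocol; defaults to the one stored in the
#'   curve metadata, else \code{loadingProtocol()}
#' @param fixed fixed constants (nu_nf, e0, C, rho_z)
#' @param control forward-solver settings
#' @param steps relaxation steps included in the objective
#' @return a \linkS4class{FitResult}
#' @export
fitFRPEParameters <- function(measured,
                              geometry = list(),
                              config = fitConfig(),
                              protocol = NULL,
                              fixed = list(nu_nf = 0.42, e0 = 3.5,
                                           C = 12.16, rho_z = 1),
                              control = feControl(),
                              steps = 2:4) {
  geom <- modifyList(list(thickness = measured@metadata$thickness_m,
                          sampleRadius = 2e-3, indenterRadius = 0.275e-3),
                     geometry)
  if (is.null(geom$thickness))
    stop("cartilage thickness not in curve metadata; supply geometry$thickness")
  if (is.null(protocol)) {
    protocol <- measured@metadata$protocol
    protocol <- if (is.null(protocol)) loadingProtocol()
                else do.call(loadingProtocol,
                             protocol[names(protocol) != "prestressMode"])
  }

  w <- .fitWindow(measured, steps)
  tm <- measured@times[w]
  fm <- measured@forces[w]
  ok <- fm > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive measured force sample(s) excluded")
    tm <- tm[ok]; fm <- fm[ok]
  }
  if (!length(fm)) stop("empty fitting window")

  nb <- names(config$bounds)
  lower <- vapply(config$bounds, `[`, numeric(1), 1)
  upper <- vapply(config$bounds, `[`, numeric(1), 2)
  lower["k0"] <- log10(lower["k0"]); upper["k0"] <- log10(upper["k0"])

  nSolves <- 0L
  simulateAt <- function(x) {
    params <- .xToParams(x, fixed)
    model <- buildMesh(geom$thickness, geom$sampleRadius, geom$indenterRadius,
                       n_r = config$meshNr, n_z = config$meshNz,
                       material = params)
    nSolves <<- nSolves + 1L
    simulateStressRelaxation(model, protocol, control,
                             rampSubsteps = config$rampSubsteps,
                             holdSteps = config$holdSteps)
  }
  residFun <- function(x) {
    sim <- tryCatch(simulateAt(x), error = function(e) NULL)
    if (is.null(sim)) return(rep(1e3, length(fm)))
    fs <- stats::approx(sim@times, sim@forces, xout = tm, rule = 2)$y
    (fs - fm) / fm
  }

  set.seed(config$seed)
  S <- lhs::randomLHS(config$nStarts, 5)
  starts <- t(t(S) * (upper - lower) + lower)
  colnames(starts) <- nb
  if (!is.null(config$start)) {
    s0 <- config$start
    s0["k0"] <- log10(s0["k0"])
    starts[1, ] <- s0[nb]
  }

  screen <- apply(starts, 1, function(x) mean(residFun(x)^2))
  order0 <- order(screen)
  refine <- order0[seq_len(min(config$nRefine, config$nStarts))]

  best <- NULL
  diag <- list()
  for (i in refine) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxIter, nprint = 0)),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag[[length(diag) + 1]] <- list(start = starts[i, ], error = TRUE)
      next
    }
    obj <- fit$deviance / length(fm)
    diag[[length(diag) + 1]] <- list(start = starts[i, ],
                                     par = fit$par, objective = obj,
                                     info = fit$info, niter = fit$niter)
    if (is.null(best) || obj < best$objective)
      best <- list(par = fit$par, objective = obj, info = fit$info,
                   niter = fit$niter)
  }
  if (is.null(best))
    stop("all optimisation starts failed; per-start diagnostics attached: ",
         paste(vapply(diag, function(d) paste(names(d), collapse = "/"),
                      ""), collapse = "; "))

  params <- .xToParams(best$par, fixed)
  sim <- simulateAt(best$par)
  fs <- stats::approx(sim@times, sim@forces, xout = tm, rule = 2)$y
  r2 <- goodnessOfFitR2(fm, fs)
  tolb <- 1e-6 * (upper - lower)
  hit <- nb[best$par <= lower + tolb | best$par >= upper - tolb]
  if (r2 < config$r2Floor)
    warning(sprintf("fit quality R^2 = %.3f below the configured floor %.2f",
                    r2, config$r2Floor))
  new("FitResult", params = params, objective = best$objective,
      rSquared = r2, nForwardSolves = as.numeric(nSolves),
      converged = best$info %in% 1:4, boundsHit = hit,
      diagnostics = list(starts = starts, screen = screen, refined = diag,
                         niter = best$niter, seed = config$seed))
}
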