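## Generics and accessors.

#' @rdname FRPEParameters-class
#' @param E_f0,E_feps,E_nf moduli (MPa)
#' @param k0 initial permeability (m^4/(N s))
#' @param M permeability strain-dependency exponent
#' @param nu_nf non-fibrillar Poisson's ratio
#' @param e0 initial void ratio
#' @param C primary-to-secondary fibril relative density
#' @param rho_z depth-wise fibril density factor
#' @return \code{FRPEParameters()} returns a validated
#'   \linkS4class{FRPEParameters} object.
#' @examples
#' p <- FRPEParameters(E_f0 = 0.29, E_feps = 10.1, E_nf = 0.13,
#'                     k0 = 4.7e-15, M = 20.5)
#' Enf(p)
#' @export
FRPEParameters <- function(E_f0 = 0.3, E_feps = 8, E_nf = 0.25, k0 = 4e-15,
                           M = 20, nu_nf = 0.42, e0 = 3.5, C = 12.16,
                           rho_z = 1) {
  ## Class= spelled out: a partially matching `C = ...` argument must land
  ## in the dots, not in new()'s first formal
  new(Class = "FRPEParameters", E_f0 = as.numeric(E_f0),
      E_feps = as.numeric(E_feps), E_nf = as.numeric(E_nf),
      k0 = as.numeric(k0), M = as.numeric(M), nu_nf = as.numeric(nu_nf),
      e0 = as.numeric(e0), C = as.numeric(C), rho_z = as.numeric(rho_z))
}

#' @rdname FRPEParameters-class
#' @param object,x a \code{FRPEParameters} object
#' @export
setGeneric("Ef0", function(x) standardGeneric("Ef0"))
#' @rdname FRPEParameters-class
#' @export
setGeneric("Efeps", function(x) standardGeneric("Efeps"))
#' @rdname FRPEParameters-class
#' @export
setGeneric("Enf", function(x) standardGeneric("Enf"))
#' @rdname FRPEParameters-class
#' @export
setGeneric("permeability0", function(x) standardGeneric("permeability0"))
#' @rdname FRPEParameters-class
#' @export
setGeneric("permeabilityExponent", function(x) standardGeneric("permeabilityExponent"))

#' @rdname FRPEParameters-class
setMethod("Ef0", "FRPEParameters", function(x) x@E_f0)
#' @rdname FRPEParameters-class
setMethod("Efeps", "FRPEParameters", function(x) x@E_feps)
#' @rdname FRPEParameters-class
setMethod("Enf", "FRPEParameters", function(x) x@E_nf)
#' @rdname FRPEParameters-class
setMethod("permeability0", "FRPEParameters", function(x) x@k0)
#' @rdname FRPEParameters-class
setMethod("permeabilityExponent", "FRPEParameters", function(x) x@M)

#' @rdname FRPEParameters-class
#' @param ... ignored
#' @export
setMethod("as.vector", "FRPEParameters", function(x) {
  c(E_f0 = x@E_f0, E_feps = x@E_feps, E_nf = x@E_nf, k0 = x@k0, M = x@M,
    nu_nf = x@nu_nf, e0 = x@e0, C = x@C, rho_z = x@rho_z)
})

#' @rdname FRPEParameters-class
setMethod("show", "FRPEParameters", function(object) {
  cat("FRPE material parameters\n")
  cat(sprintf("  fibril network : E_f0 = %.4g MPa, E_feps = %.4g MPa (C = %.4g, rho_z = %.3g)\n",
              object@E_f0, object@E_feps, object@C, object@rho_z))
  cat(sprintf("  non-fibrillar  : E_nf = %.4g MPa, nu_nf = %.3g\n",
              object@E_nf, object@nu_nf))
  cat(sprintf("  fluid flow     : k0 = %.4g m^4/(N s), M = %.4g, e0 = %.3g (fluid fraction %.1f%%)\n",
              object@k0, object@M, object@e0,
              100 * voidRatioToFluidFraction(object@e0)))
  invisible(NULL)
})

#' @rdname ForceTimeCurve-class
#' @param times sampling times (s)
#' @param forces reaction forces (N)
#' @param stepBounds integer matrix (columns ramp_start, hold_end)
#' @param metadata list of free-form metadata
#' @return \code{ForceTimeCurve()} returns a validated
#'   \linkS4class{ForceTimeCurve}.
#' @export
ForceTimeCurve <- function(times, forces, stepBounds = NULL, metadata = list()) {
  if (is.null(stepBounds))
    stepBounds <- matrix(integer(), 0, 2,
                         dimnames = list(NULL, c("ramp_start", "hold_end")))
  stepBounds <- matrix(as.integer(stepBounds), ncol = 2,
                       dimnames = list(NULL, c("ramp_start", "hold_end")))
  new("ForceTimeCurve", times = as.numeric(times), forces = as.numeric(forces),
      stepBounds = stepBounds, metadata = metadata)
}

#' @rdname ForceTimeCurve-class
#' @param object,x a \code{ForceTimeCurve}
#' @export
setGeneric("forces", function(x) standardGeneric("forces"))
#' @rdname ForceTimeCurve-class
#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @rdname ForceTimeCurve-class
#' @export
setGeneric("stepBounds", function(x) standardGeneric("stepBounds"))
#' @rdname ForceTimeCurve-class
setMethod("forces", "ForceTimeCurve", function(x) x@forces)
#' @rdname ForceTimeCurve-class
setMethod("times", "ForceTimeCurve", function(x) x@times)
#' @rdname ForceTimeCurve-class
setMethod("stepBounds", "ForceTimeCurve", function(x) x@stepBounds)
#' @rdname ForceTimeCurve-class
#' @export
setMethod("length", "ForceTimeCurve", function(x) length(x@times))
#' @rdname ForceTimeCurve-class
setMethod("show", "ForceTimeCurve", function(object) {
  cat(sprintf("ForceTimeCurve: %d samples, t in [%.3g, %.4g] s, %d steps\n",
              length(object@times),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA,
              nrow(object@stepBounds)))
  if (length(object@forces))
    cat(sprintf("  force range [%.4g, %.4g] N\n",
                min(object@forces), max(object@forces)))
  if (!is.null(object@metadata$thickness_m))
    cat(sprintf("  cartilage thickness %.3g mm\n",
                1e3 * object@metadata$thickness_m))
  invisible(NULL)
})

#' @rdname AttenuationVolume-class
#' @param hu 3D array of Hounsfield units
#' @param voxelSize voxel size (micrometres)
#' @param timepoint "0h" or "96h"
#' @param energyBin energy-bin label
#' @param cartilageMask,bathMask logical arrays matching \code{hu}
#' @return \code{AttenuationVolume()} returns a validated
#'   \linkS4class{AttenuationVolume}.
#' @export
AttenuationVolume <- function(hu, voxelSize, timepoint, energyBin,
                              cartilageMask, bathMask) {
  new("AttenuationVolume", hu = hu, voxelSize = as.numeric(voxelSize),
      timepoint = timepoint, energyBin = energyBin,
      cartilageMask = cartilageMask, bathMask = bathMask)
}

#' @rdname AttenuationVolume-class
#' @param object,x an \code{AttenuationVolume}
#' @export
setGeneric("huValues", function(x) standardGeneric("huValues"))
#' @rdname AttenuationVolume-class
setMethod("huValues", "AttenuationVolume", function(x) x@hu)
#' @rdname AttenuationVolume-class
#' @export
setGeneric("cartilageMask", function(x) standardGeneric("cartilageMask"))
#' @rdname AttenuationVolume-class
setMethod("cartilageMask", "AttenuationVolume", function(x) x@cartilageMask)
#' @rdname AttenuationVolume-class
#' @export
setGeneric("bathMask", function(x) standardGeneric("bathMask"))
#' @rdname AttenuationVolume-class
setMethod("bathMask", "AttenuationVolume", function(x) x@bathMask)
#' @rdname AttenuationVolume-class
setMethod("show", "AttenuationVolume", function(object) {
  d <- dim(object@hu)
  cat(sprintf("AttenuationVolume %d x %d x %d @ %.3g um [%s, %s]\n",
              d[1], d[2], d[3], object@voxelSize, object@timepoint,
              object@energyBin))
  cat(sprintf("  cartilage voxels %d, bath voxels %d, HU range [%.0f, %.0f]\n",
              sum(object@cartilageMask), sum(object@bathMask),
              min(object@hu), max(object@hu)))
  invisible(NULL)
})

#' @rdname DecompositionCalibration-class
setMethod("show", "DecompositionCalibration", function(object) {
  cat("Dual-energy decomposition calibration (HU = A c + b)\n")
  cat(sprintf("  A = [%8.3f %8.3f ; %8.3f %8.3f] HU/(mg/mL)\n",
              object@A[1, 1], object@A[1, 2], object@A[2, 1], object@A[2, 2]))
  cat(sprintf("  b = [%.1f, %.1f] HU, condition number %.3g, residual RMS %.3g HU\n",
              object@b[1], object@b[2], object@conditionNumber,
              object@residualRMS))
  invisible(NULL)
})

#' @rdname PartitionResult-class
setMethod("show", "PartitionResult", function(object) {
  cat("Contrast-agent partition\n")
  cat(sprintf("  Ta2O5-cNP: %.1f%%\n", object@partitionTa))
  if (is.finite(object@partitionI)) {
    cat(sprintf("  iodixanol: %.1f%%\n", object@partitionI))
    cat(sprintf("  combined : %.1f AU\n", object@partitionCombined))
  }
  invisible(NULL)
})

#' @rdname PartitionResult-class
#' @param object,x a \code{PartitionResult}
#' @export
setGeneric("partitionTa", function(x) standardGeneric("partitionTa"))
#' @rdname PartitionResult-class
setMethod("partitionTa", "PartitionResult", function(x) x@partitionTa)
#' @rdname PartitionResult-class
#' @export
setGeneric("partitionI", function(x) standardGeneric("partitionI"))
#' @rdname PartitionResult-class
setMethod("partitionI", "PartitionResult", function(x) x@partitionI)
#' @rdname PartitionResult-class
#' @export
setGeneric("partitionCombined", function(x) standardGeneric("partitionCombined"))
#' @rdname PartitionResult-class
setMethod("partitionCombined", "PartitionResult", function(x) x@partitionCombined)

#' @rdname FitResult-class
#' @param object,x a \code{FitResult}
#' @export
setGeneric("fittedParameters", function(x) standardGeneric("fittedParameters"))
#' @rdname FitResult-class
setMethod("fittedParameters", "FitResult", function(x) x@params)
#' @rdname FitResult-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname FitResult-class
setMethod("rSquared", "FitResult", function(x) x@rSquared)
#' @rdname FitResult-class
setMethod("show", "FitResult", function(object) {
  cat(sprintf("FRPE fit: MSRE = %.4g, R^2 = %.4f, %d forward solves, converged: %s\n",
              object@objective, object@rSquared, object@nForwardSolves,
              object@converged))
  if (length(object@boundsHit))
    cat("  at bounds:", paste(object@boundsHit, collapse = ", "), "\n")
  show(object@params)
  invisible(NULL)
})
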