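## S4 classes for the central data objects.

#' FRPE material parameters
#'
#' Container for the constituent-specific parameters of the fibril-reinforced
#' poroelastic (FRPE) cartilage material: the tension-only collagen fibril
#' network (initial modulus \code{E_f0}, strain-dependent modulus
#' \code{E_feps}), the proteoglycan-dominated non-fibrillar matrix
#' (\code{E_nf}, Poisson's ratio \code{nu_nf}), and Darcy fluid flow
#' (initial permeability \code{k0}, strain-dependency exponent \code{M},
#' initial void ratio \code{e0}). \code{C} is the primary-to-secondary
#' fibril relative density and \code{rho_z} a depth-wise fibril density
#' factor (1 for the homogeneous model used here).
#'
#' Moduli are stored in MPa, the permeability in m^4/(N s); the
#' finite-element solver converts to SI internally.
#'
#' @slot E_f0 initial fibril network modulus (MPa)
#' @slot E_feps strain-dependent fibril network modulus (MPa)
#' @slot E_nf non-fibrillar matrix modulus (MPa)
#' @slot k0 initial permeability (m^4/(N s))
#' @slot M permeability strain-dependency exponent (dimensionless)
#' @slot nu_nf non-fibrillar Poisson's ratio
#' @slot e0 initial void ratio
#' @slot C primary-to-secondary fibril relative density
#' @slot rho_z depth-wise fibril density factor
#' @name FRPEParameters-class
#' @exportClass FRPEParameters
setClass("FRPEParameters",
         representation(E_f0 = "numeric", E_feps = "numeric", E_nf = "numeric",
                        k0 = "numeric", M = "numeric", nu_nf = "numeric",
                        e0 = "numeric", C = "numeric", rho_z = "numeric"),
         prototype(E_f0 = 0.3, E_feps = 8, E_nf = 0.25, k0 = 4e-15, M = 20,
                   nu_nf = 0.42, e0 = 3.5, C = 12.16, rho_z = 1))

setValidity("FRPEParameters", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("E_f0", "E_feps", "E_nf", "k0", "M", "nu_nf", "e0", "C", "rho_z"))
    if (!one(slot(object, s))) msg <- c(msg, paste0(s, " must be a single finite number"))
  if (length(msg)) return(msg)
  if (object@E_f0 < 0 || object@E_feps < 0 || object@E_nf < 0)
    msg <- c(msg, "moduli must be >= 0")
  if (object@k0 <= 0) msg <- c(msg, "k0 must be > 0")
  if (object@M < 0) msg <- c(msg, "M must be >= 0")
  if (object@nu_nf < 0 || object@nu_nf >= 0.5)
    msg <- c(msg, "nu_nf must lie in [0, 0.5) (0.5 is incompressible)")
  if (object@e0 <= 0) msg <- c(msg, "e0 must be > 0")
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@rho_z <= 0) msg <- c(msg, "rho_z must be > 0")
  if (length(msg)) msg else TRUE
})

#' Force-time curve from stress-relaxation indentation
#'
#' Reaction force versus time, either simulated by
#' \code{\link{simulateStressRelaxation}} or measured. Step boundaries mark,
#' for each compression step, the index where its ramp starts and the index
#' where its relaxation hold ends.
#'
#' @slot times sampling times (s), strictly increasing
#' @slot forces reaction forces (N)
#' @slot stepBounds integer matrix with columns \code{ramp_start} and
#'   \code{hold_end}, one row per compression step
#' @slot metadata list (cartilage thickness in m, protocol description,
#'   ground truth for synthetic curves, ...)
#' @name ForceTimeCurve-class
#' @exportClass ForceTimeCurve
setClass("ForceTimeCurve",
         representation(times = "numeric", forces = "numeric",
                        stepBounds = "matrix", metadata = "list"),
         prototype(times = numeric(), forces = numeric(),
                   stepBounds = matrix(integer(), 0, 2,
                                       dimnames = list(NULL, c("ramp_start", "hold_end"))),
                   metadata = list()))

setValidity("ForceTimeCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@forces))
    msg <- c(msg, "times and forces must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  sb <- object@stepBounds
  if (ncol(sb) != 2) msg <- c(msg, "stepBounds must have two columns")
  if (nrow(sb)) {
    if (any(sb < 1) || any(sb > length(object@times)))
      msg <- c(msg, "stepBounds indices out of range")
    if (any(sb[, 2] < sb[, 1]) ||
        (nrow(sb) > 1 && any(diff(sb[, 1]) <= 0)))
      msg <- c(msg, "stepBounds must be ordered")
  }
  if (length(msg)) msg else TRUE
})

#' Axisymmetric finite-element model
#'
#' Mesh, material, boundary node sets and current nodal state of the
#' axisymmetric displacement/pore-pressure model of an indentation test.
#' Coordinates are (r, z) in metres with z = 0 at the cartilage-bone
#' interface and the articulating surface at z = thickness.
#'
#' @slot coords node coordinates, n x 2 matrix (r, z) in m
#' @slot elements element connectivity, m x 4 integer matrix (counterclockwise)
#' @slot nodeSets named list of integer node index vectors: \code{axis},
#'   \code{bottom}, \code{lateral}, \code{surface}, \code{contact},
#'   \code{surfaceFree}
#' @slot material a \linkS4class{FRPEParameters} object
#' @slot displacements n x 2 matrix of nodal displacements (m)
#' @slot pressures length-n vector of nodal pore pressures (Pa)
#' @slot geometry list: thickness, sampleRadius, indenterRadius (m)
#' @name FEModel-class
#' @exportClass FEModel
setClass("FEModel",
         representation(coords = "matrix", elements = "matrix",
                        nodeSets = "list", material = "FRPEParameters",
                        displacements = "matrix", pressures = "numeric",
                        geometry = "list"))

setValidity("FEModel", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2) msg <- c(msg, "coords must be n x 2")
  if (any(object@coords[, 1] < -1e-12)) msg <- c(msg, "radial coordinates must be >= 0")
  if (ncol(object@elements) != 4) msg <- c(msg, "elements must be m x 4")
  if (nrow(object@elements) && (min(object@elements) < 1 || max(object@elements) > n))
    msg <- c(msg, "element connectivity out of range")
  need <- c("axis", "bottom", "lateral", "surface", "contact", "surfaceFree")
  if (!all(need %in% names(object@nodeSets)))
    msg <- c(msg, paste("nodeSets must contain:", paste(need, collapse = ", ")))
  else if (length(intersect(object@nodeSets$contact, object@nodeSets$surfaceFree)))
    msg <- c(msg, "contact and free-surface node sets must be disjoint")
  if (!all(dim(object@displacements) == c(n, 2)))
    msg <- c(msg, "displacements must be n x 2")
  if (length(object@pressures) != n) msg <- c(msg, "pressures must have one entry per node")
  if (length(msg)) msg else TRUE
})

#' Attenuation volume
#'
#' A reconstructed micro-CT attenuation grid in Hounsfield units, with the
#' acquisition timepoint (\code{"0h"} or \code{"96h"}), the energy bin
#' (\code{"single"}, \code{"low_10_80keV"} or \code{"total_10_120keV"}) and
#' logical masks for the cartilage and bath regions.
#'
#' @slot hu 3D numeric array of Hounsfield units
#' @slot voxelSize isotropic voxel size (micrometres)
#' @slot timepoint immersion timepoint label
#' @slot energyBin energy bin label
#' @slot cartilageMask logical array, same dimensions as \code{hu}
#' @slot bathMask logical array, same dimensions as \code{hu}
#' @name AttenuationVolume-class
#' @exportClass AttenuationVolume
setClass("AttenuationVolume",
         representation(hu = "array", voxelSize = "numeric",
                        timepoint = "character", energyBin = "character",
                        cartilageMask = "array", bathMask = "array"))

setValidity("AttenuationVolume", function(object) {
  msg <- character()
  if (length(dim(object@hu)) != 3) msg <- c(msg, "hu must be a 3D array")
  if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (!object@timepoint %in% c("0h", "96h"))
    msg <- c(msg, "timepoint must be '0h' or '96h'")
  if (!object@energyBin %in% c("single", "low_10_80keV", "total_10_120keV", "high_80_120keV"))
    msg <- c(msg, "unknown energy bin label")
  for (m in c("cartilageMask", "bathMask")) {
    mk <- slot(object, m)
    if (!is.logical(mk) || !identical(dim(mk), dim(object@hu)))
      msg <- c(msg, paste(m, "must be a logical array matching hu"))
  }
  if (!length(msg) && any(object@cartilageMask & object@bathMask))
    msg <- c(msg, "cartilage and bath masks must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Dual-energy material decomposition calibration
#'
#' Affine model \eqn{(HU_{low}, HU_{total})^T = A (C_{Ta}, C_I)^T + b}
#' fitted to mixtures of known tantalum oxide nanoparticle and iodixanol
#' concentrations. \code{A} is in HU per (mg/mL), \code{b} in HU (water /
#' background term).
#'
#' @slot A 2 x 2 coefficient matrix, rows (low, total), columns (Ta, I)
#' @slot b length-2 offset vector (low, total)
#' @slot conditionNumber condition number of \code{A}
#' @slot residualRMS root-mean-square HU residual of the calibration fit
#' @name DecompositionCalibration-class
#' @exportClass DecompositionCalibration
setClass("DecompositionCalibration",
         representation(A = "matrix", b = "numeric",
                        conditionNumber = "numeric", residualRMS = "numeric"))

setValidity("DecompositionCalibration", function(object) {
  msg <- character()
  if (!all(dim(object@A) == c(2, 2))) msg <- c(msg, "A must be 2 x 2")
  if (length(object@b) != 2) msg <- c(msg, "b must have length 2")
  if (!length(msg) && abs(det(object@A)) < .Machine$double.eps * max(abs(object@A), 1))
    msg <- c(msg, "A is singular; calibration is degenerate")
  if (length(msg)) msg else TRUE
})

#' Contrast-agent partition result
#'
#' Bulk partitions in percent of the bath concentration, and for dual-contrast
#' data the combined tantalum-iodine partition (Ta partition divided by
#' iodixanol partition, arbitrary units).
#'
#' @slot partitionTa Ta2O5-cNP partition (%)
#' @slot partitionI iodixanol partition (%); NA for single-contrast data
#' @slot partitionCombined combined partition (AU); NA when undefined
#' @slot bathConcentrations named numeric, bath concentrations in mg/mL
#' @name PartitionResult-class
#' @exportClass PartitionResult
setClass("PartitionResult",
         representation(partitionTa = "numeric", partitionI = "numeric",
                        partitionCombined = "numeric",
                        bathConcentrations = "numeric"),
         prototype(partitionI = NA_real_, partitionCombined = NA_real_,
                   bathConcentrations = c(Ta = NA_real_, I = NA_real_)))

setValidity("PartitionResult", function(object) {
  msg <- character()
  if (is.finite(object@partitionTa) && object@partitionTa < 0)
    msg <- c(msg, "partitions must be >= 0")
  if (is.finite(object@partitionI) && object@partitionI < 0)
    msg <- c(msg, "partitions must be >= 0")
  if (is.finite(object@partitionCombined) &&
      !(is.finite(object@partitionI) && object@partitionI > 0))
    msg <- c(msg, "combined partition defined only when partitionI > 0")
  if (length(msg)) msg else TRUE
})

#' Inverse-fit result
#'
#' Output of \code{\link{fitFRPEParameters}}: the best parameter set found,
#' the mean-squared relative error objective over relaxation steps 2-4, the
#' coefficient of determination over the fitting window, and bookkeeping.
#'
#' @slot params recovered \linkS4class{FRPEParameters}
#' @slot objective mean-squared relative force error (dimensionless)
#' @slot rSquared goodness of fit over the fitting window
#' @slot nForwardSolves number of forward simulations used
#' @slot converged logical
#' @slot boundsHit names of parameters that ended on a configured bound
#' @slot diagnostics list of per-start details
#' @name FitResult-class
#' @exportClass FitResult
setClass("FitResult",
         representation(params = "FRPEParameters", objective = "numeric",
                        rSquared = "numeric", nForwardSolves = "numeric",
                        converged = "logical", boundsHit = "character",
                        diagnostics = "list"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (is.finite(object@objective) && object@objective < 0)
    msg <- c(msg, "objective must be >= 0")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared cannot exceed 1")
  if (length(msg)) msg else TRUE
})
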