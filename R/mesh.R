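## Structured axisymmetric mesh for the indentation geometry.

#' Build an axisymmetric indentation mesh
#'
#' Structured quadrilateral mesh of a cartilage layer of the given thickness
#' and radius, graded radially so that elements are fine under the indenter
#' edge (uniform spacing inside the contact radius, geometric growth
#' outside) and mildly refined towards the articulating surface where pore
#' pressure gradients are steepest. The default density gives 350 elements,
#' the mesh size at which the converged element count was established.
#'
#' @param thickness cartilage thickness (m)
#' @param sampleRadius outer sample radius (m)
#' @param indenterRadius indenter radius (m)
#' @param n_r number of element columns (radial); about 40% are placed
#'   inside the contact radius
#' @param n_z number of element rows (axial)
#' @param material a \linkS4class{FRPEParameters} object attached to the model
#' @return an \linkS4class{FEModel} with zero displacements and pressures
#' @examples
#' m <- buildMesh(1e-3, 2e-3, 0.275e-3)
#' nrow(m@elements)  # 350
#' @export
buildMesh <- function(thickness, sampleRadius = 2e-3,
                      indenterRadius = 0.275e-3, n_r = 25, n_z = 14,
                      material = FRPEParameters()) {
  if (thickness <= 0 || sampleRadius <= 0 || indenterRadius <= 0)
    stop("geometry must be positive")
  if (indenterRadius >= sampleRadius)
    stop("indenterRadius must be smaller than sampleRadius")
  if (n_r < 3 || n_z < 2) stop("mesh too coarse: need n_r >= 3, n_z >= 2")

  n_in <- max(2L, round(0.4 * n_r))
  n_out <- n_r - n_in
  # geometric spacing on both sides of the indenter edge (the stress
  # concentration): finest interval dr0 at r = indenterRadius
  dr0 <- indenterRadius / (2 * n_in)
  growSpacings <- function(d0, span, n) {
    f <- function(q) d0 * (q^n - 1) / (q - 1) - span
    q <- if (f(1 + 1e-9) * f(20) < 0)
      stats::uniroot(f, c(1 + 1e-9, 20), tol = 1e-12)$root
    else span / (n * d0)
    d0 * q^(seq_len(n) - 1)
  }
  r_in <- indenterRadius - rev(c(0, cumsum(growSpacings(dr0, indenterRadius, n_in))))
  r_in[1] <- 0
  r_out <- indenterRadius + cumsum(growSpacings(dr0, sampleRadius - indenterRadius, n_out))
  r_out[n_out] <- sampleRadius
  rs <- c(r_in, r_out)

  # axial coordinates, mildly clustered at the articulating surface
  zeta <- seq(0, 1, length.out = n_z + 1)
  zs <- thickness * (1 - (1 - zeta)^1.3)
  zs[n_z + 1] <- thickness

  nnr <- n_r + 1L
  nnz <- n_z + 1L
  coords <- cbind(r = rep(rs, each = nnz), z = rep(zs, times = nnr))
  nodeId <- function(ir, iz) (ir - 1L) * nnz + iz  # ir, iz 1-based

  elements <- matrix(0L, n_r * n_z, 4)
  e <- 0L
  for (ir in seq_len(n_r)) {
    for (iz in seq_len(n_z)) {
      e <- e + 1L
      elements[e, ] <- c(nodeId(ir, iz), nodeId(ir + 1L, iz),
                         nodeId(ir + 1L, iz + 1L), nodeId(ir, iz + 1L))
    }
  }

  tol <- 1e-9 * sampleRadius
  surface <- which(abs(coords[, 2] - thickness) < 1e-9 * thickness)
  contact <- surface[coords[surface, 1] <= indenterRadius + tol]
  nodeSets <- list(
    axis = which(coords[, 1] < tol),
    bottom = which(abs(coords[, 2]) < 1e-12 + 1e-9 * thickness),
    lateral = which(coords[, 1] > sampleRadius - tol),
    surface = surface,
    contact = contact,
    surfaceFree = setdiff(surface, contact))

  new("FEModel", coords = coords, elements = elements, nodeSets = nodeSets,
      material = material,
      displacements = matrix(0, nrow(coords), 2),
      pressures = numeric(nrow(coords)),
      geometry = list(thickness = thickness, sampleRadius = sampleRadius,
                      indenterRadius = indenterRadius))
}

#' Minimum element Jacobian of a model mesh
#'
#' Smallest isoparametric Jacobian determinant over all Gauss points; must
#' be positive for a valid mesh.
#'
#' @param model an \linkS4class{FEModel}
#' @return smallest Jacobian determinant (m^2)
#' @export
minElementJacobian <- function(model) {
  cpp_min_jacobian(model@coords, model@elements)
}

#' @rdname FEModel-class
setMethod("show", "FEModel", function(object) {
  cat(sprintf("Axisymmetric FE model: %d nodes, %d elements\n",
              nrow(object@coords), nrow(object@elements)))
  g <- object@geometry
  cat(sprintf("  thickness %.3g mm, sample radius %.3g mm, indenter radius %.3g mm\n",
              1e3 * g$thickness, 1e3 * g$sampleRadius, 1e3 * g$indenterRadius))
  cat(sprintf("  contact nodes: %d, max |u_z| = %.3g um, max |p| = %.3g kPa\n",
              length(object@nodeSets$contact),
              1e6 * max(abs(object@displacements[, 2]), 0),
              1e-3 * max(abs(object@pressures), 0)))
  invisible(NULL)
})

#' Export a mesh in a plain-text unstructured-grid format
#'
#' Writes the mesh as a legacy VTK ASCII file (quad cells on the r-z plane)
#' for inspection in standard viewers.
#'
#' @param model an \linkS4class{FEModel}
#' @param path output file path
#' @return invisibly, the path
#' @export
writeMeshVTK <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(model@coords)
  m <- nrow(model@elements)
  writeLines(c("# vtk DataFile Version 3.0", "axisymmetric FRPE mesh (r z 0)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9e %.9e 0.0", model@coords[, 1], model@coords[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", model@elements[, 1] - 1L,
                     model@elements[, 2] - 1L, model@elements[, 3] - 1L,
                     model@elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("9", m), con)
  invisible(path)
}
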