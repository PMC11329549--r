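## Plain-text I/O: force curves as CSV + JSON sidecar, volumes as NIfTI
## with a JSON sidecar.

#' Write / read a force-time curve
#'
#' The curve is stored as a two-column CSV (\code{time_s}, \code{force_N})
#' with a JSON sidecar (same path, extension \code{.json}) carrying the
#' thickness, protocol, step boundaries and any ground truth.
#'
#' @param curve a \linkS4class{ForceTimeCurve}
#' @param path CSV file path
#' @return \code{writeForceCurve}: invisibly, the path;
#'   \code{readForceCurve}: a \linkS4class{ForceTimeCurve}
#' @export
writeForceCurve <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve@times, force_N = curve@forces),
                   path, row.names = FALSE, quote = FALSE)
  meta <- curve@metadata
  meta$final_state <- NULL  # solver state is not part of the interchange format
  side <- list(stepBounds = unname(apply(curve@stepBounds, 1, as.list)),
               metadata = meta)
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeForceCurve
#' @export
readForceCurve <- function(path) {
  tab <- utils::read.csv(path)
  sidePath <- sub("\\.csv$", ".json", path)
  sb <- NULL
  meta <- list()
  if (file.exists(sidePath)) {
    side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
    if (!is.null(side$stepBounds))
      sb <- cbind(ramp_start = as.integer(side$stepBounds$ramp_start),
                  hold_end = as.integer(side$stepBounds$hold_end))
    meta <- side$metadata
  }
  ForceTimeCurve(tab$time_s, tab$force_N, sb, as.list(meta))
}

#' Write / read an attenuation volume
#'
#' The HU grid is written as NIfTI; a companion label volume (suffix
#' \code{_mask}) encodes the masks (1 = cartilage, 2 = bath) and a JSON
#' sidecar records voxel size, timepoint and energy bin.
#'
#' @param vol an \linkS4class{AttenuationVolume}
#' @param path output path (\code{.nii} or \code{.nii.gz})
#' @return \code{writeAttenuationVolume}: invisibly, the path;
#'   \code{readAttenuationVolume}: an \linkS4class{AttenuationVolume}
#' @export
writeAttenuationVolume <- function(vol, path) {
  vs <- vol@voxelSize * 1e-3  # mm for the NIfTI header
  RNifti::writeNifti(RNifti::asNifti(vol@hu, pixdim = c(vs, vs, vs)), path)
  lab <- array(0L, dim(vol@hu))
  lab[vol@cartilageMask] <- 1L
  lab[vol@bathMask] <- 2L
  maskPath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  RNifti::writeNifti(RNifti::asNifti(lab, pixdim = c(vs, vs, vs)), maskPath)
  jsonlite::write_json(list(voxel_size_um = vol@voxelSize,
                            timepoint = vol@timepoint,
                            energy_bin = vol@energyBin),
                       sub("(\\.nii(\\.gz)?)$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAttenuationVolume
#' @export
readAttenuationVolume <- function(path) {
  hu <- array(as.numeric(RNifti::readNifti(path)),
              dim = dim(RNifti::readNifti(path)))
  side <- jsonlite::read_json(sub("(\\.nii(\\.gz)?)$", ".json", path),
                              simplifyVector = TRUE)
  maskPath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  lab <- array(as.integer(RNifti::readNifti(maskPath)), dim = dim(hu))
  AttenuationVolume(hu, side$voxel_size_um, side$timepoint, side$energy_bin,
                    cartilageMask = lab == 1L, bathMask = lab == 2L)
}
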