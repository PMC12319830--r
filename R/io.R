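#' Extract voxel timeseries from a 4-D NIfTI volume under an ROI mask
#'
#' Reads a 4-D functional image and an integer-label ROI mask (3-D, same
#' grid) and returns the timeseries of the voxels inside the requested
#' label, in mask scan order (fastest-varying index first), as a TRs x
#' voxels matrix. Requires the \pkg{RNifti} package.
#'
#' @param bold path to (or \code{RNifti} image of) the 4-D BOLD volume.
#' @param mask path to (or image of) the 3-D integer-label mask.
#' @param label integer label selecting the ROI (default: all non-zero).
#' @param scale apply [scale_to_psc()] per voxel (default FALSE, for data
#'   already in percent-signal-change units).
#' @return Matrix of timeseries (TRs x voxels) with voxel linear indices as
#'   column names.
#' @export
read_roi_timeseries <- function(bold, mask, label = NULL, scale = FALSE) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_roi_timeseries requires the RNifti package")
  img <- RNifti::asNifti(bold)
  msk <- RNifti::asNifti(mask)
  d <- dim(img)
  if (length(d) != 4) stop("BOLD volume must be 4-D")
  if (!identical(dim(msk)[1:3], d[1:3]))
    stop("mask grid does not match the BOLD volume")
  sel <- if (is.null(label)) which(msk != 0) else which(msk == label)
  if (length(sel) == 0) stop("no voxels carry the requested label")
  flat <- matrix(img, prod(d[1:3]), d[4])
  out <- t(flat[sel, , drop = FALSE])
  colnames(out) <- sprintf("vox_%d", sel)
  if (scale) out <- apply(out, 2, scale_to_psc)
  out
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror the arguments of [opponency_config()]; unknown fields are
#' rejected so typos fail loudly. Requires the \pkg{yaml} package.
#'
#' @param path YAML file path.
#' @return A validated \code{opponency_config}.
#' @export
read_opponency_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_opponency_config requires the yaml package")
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(opponency_config)), "...")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(opponency_config, raw)
}
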