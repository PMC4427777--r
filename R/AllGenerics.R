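#' Voxel spacing of a gridded image
#'
#' @param x a [Volume-class] or [BinaryMask-class].
#' @return Numeric length-3 vector, mm per voxel along each axis (column
#'   norms of the rotation/scale block of the affine).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Voxel-to-world affine of a gridded image
#'
#' @param x a [Volume-class] or [BinaryMask-class].
#' @return 4x4 matrix mapping 0-based voxel indices (homogeneous) to world mm
#'   (NIfTI sform convention, RAS+ axes).
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' Underlying data array of a gridded image
#'
#' @param x a [Volume-class] or [BinaryMask-class].
#' @return The 3-D array (numeric for volumes, logical for masks).
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Number of foreground voxels in a mask
#'
#' @param x a [BinaryMask-class].
#' @return Integer count of `TRUE` voxels.
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
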