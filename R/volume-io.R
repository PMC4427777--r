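## NIfTI-1 I/O and grid resampling, built on RNifti. One geometry convention
## for the whole package: 0-based voxel indices, sform affine, RAS+ world.

#' Read a 3-D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param role role to assign to the returned [Volume-class].
#' @return A [Volume-class] whose grid, spacing and affine reproduce the
#'   file header; intensities are unchanged.
#' @export
readVolume <- function(path, role = "intensity") {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop(sprintf("expected a 3-D image, got shape %s in %s",
                     paste(d, collapse = "x"), path), call. = FALSE)
    a <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
    arr <- as.array(img)
    attributes(arr) <- list(dim = d)
    volume(arr, affine = a, role = role)
}

#' Read a 3-D NIfTI file as a binary mask
#'
#' @inheritParams readVolume
#' @return A [BinaryMask-class]; any nonzero voxel is foreground.
#' @export
readMask <- function(path) {
    v <- readVolume(path, role = "label")
    binaryMask(v@data != 0, affine = v@affine)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks and label volumes are written as integers (bit-identical on
#' round-trip); fraction, bias and intensity volumes are written as float64.
#'
#' @param vol a [Volume-class] or [BinaryMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
    dir <- dirname(path)
    if (!dir.exists(dir))
        stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
    if (is(vol, "BinaryMask")) {
        arr <- array(as.integer(vol@data), dim(vol@data))
        dtype <- "uint8"
    } else if (is(vol, "Volume") && vol@role == "label") {
        arr <- array(as.integer(round(vol@data)), dim(vol@data))
        dtype <- "int16"
    } else if (is(vol, "Volume")) {
        arr <- vol@data
        dtype <- "double"
    } else stop("vol must be a Volume or BinaryMask", call. = FALSE)
    img <- RNifti::asNifti(arr)
    xf <- structure(vol@affine, code = 2L)
    RNifti::sform(img) <- xf
    RNifti::qform(img) <- xf
    RNifti::writeNifti(img, path, datatype = dtype)
    invisible(path)
}

#' Resample a volume onto a new isotropic/anisotropic grid
#'
#' The target grid covers the same world-space extent as the input (within
#' one voxel), with voxel centres laid out so that the extent is preserved.
#' Intensity-like volumes may use trilinear interpolation; masks and label
#' volumes must use nearest-neighbour.
#'
#' @param vol a [Volume-class] or [BinaryMask-class].
#' @param targetSpacing numeric length-3 (or scalar), mm per voxel.
#' @param interp `"nearest"` or `"trilinear"`.
#' @return The resampled object, same class as the input.
#' @export
resampleToGrid <- function(vol, targetSpacing, interp = c("trilinear", "nearest")) {
    interp <- match.arg(interp)
    if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
    stopifnot(length(targetSpacing) == 3L, all(targetSpacing > 0))
    isMask <- is(vol, "BinaryMask")
    if ((isMask || (is(vol, "Volume") && vol@role == "label")) &&
        interp != "nearest")
        stop("masks and label volumes must be resampled with nearest-neighbour interpolation",
             call. = FALSE)
    sp <- spacing(vol)
    d <- dim(vol@data)
    if (max(abs(sp - targetSpacing)) < 1e-9) return(vol)
    nd <- pmax(1L, as.integer(ceiling(d * sp / targetSpacing)))
    ## direction columns rescaled to the new spacing; origin shifted so that
    ## voxel-centre extents line up (centre-of-voxel convention)
    dirs <- sweep(vol@affine[1:3, 1:3], 2, sp, "/")
    na <- diag(4)
    na[1:3, 1:3] <- sweep(dirs, 2, targetSpacing, "*")
    na[1:3, 4] <- vol@affine[1:3, 4] + dirs %*% ((targetSpacing - sp) / 2)
    grid <- .voxelGrid(nd)
    src <- worldToVoxel(vol@affine, voxelToWorld(na, grid))
    ## clamp coordinates falling within half a voxel outside the source
    ## extent (border replication), so edge voxels are not zeroed
    for (j in 1:3) {
        s <- src[, j]
        s[s < 0 & s > -0.51] <- 0
        s[s > d[j] - 1 & s < d[j] - 0.49] <- d[j] - 1
        src[, j] <- s
    }
    valsIn <- if (isMask) as.numeric(vol@data) else as.vector(vol@data)
    vals <- if (interp == "trilinear")
        sample_trilinear(valsIn, d, src, 0) else sample_nearest(valsIn, d, src, 0)
    if (isMask) {
        dim(vals) <- nd
        return(new("BinaryMask", data = array(vals != 0, nd), affine = na))
    }
    dim(vals) <- nd
    if (vol@role == "fraction") vals <- pmin(pmax(vals, 0), 1)
    volume(vals, affine = na, role = vol@role)
}
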