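## Geometry helpers shared by every module. Convention: voxel indices are
## 0-based; world = affine %*% c(i, j, k, 1); world axes follow NIfTI RAS+.

#' Build an affine from voxel spacing
#'
#' Axis-aligned RAS+ affine with the given mm spacing and origin at the
#' world position of voxel (0,0,0).
#'
#' @param spacing numeric length-3, mm per voxel.
#' @param origin numeric length-3 world position of voxel (0,0,0) (mm).
#' @return 4x4 matrix.
#' @export
spacingAffine <- function(spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
    a <- diag(c(spacing, 1))
    a[1:3, 4] <- origin
    a
}

#' Map voxel indices to world coordinates
#'
#' @param x a gridded object or a 4x4 affine matrix.
#' @param vox n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxelToWorld <- function(x, vox) {
    a <- if (is.matrix(x)) x else affine(x)
    v <- if (is.matrix(vox)) vox else matrix(vox, ncol = 3L)
    t(a %*% rbind(t(v), 1))[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional) voxel indices
#'
#' @inheritParams voxelToWorld
#' @param world n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @return n x 3 matrix of 0-based, possibly fractional voxel indices.
#' @export
worldToVoxel <- function(x, world) {
    a <- if (is.matrix(x)) x else affine(x)
    w <- if (is.matrix(world)) world else matrix(world, ncol = 3L)
    t(solve(a) %*% rbind(t(w), 1))[, 1:3, drop = FALSE]
}

## Geometry-identity test with relative tolerance on affine entries.
.sameGeom <- function(a, b, tol = 1e-4) {
    if (!identical(dim(a@data), dim(b@data))) return(FALSE)
    da <- a@affine; db <- b@affine
    max(abs(da - db)) <= tol * max(1, max(abs(da)))
}

#' Do two gridded objects share one geometry?
#'
#' Same grid shape and affines equal within a relative tolerance of 1e-4,
#' which absorbs float round-trip noise without hiding real mismatches.
#'
#' @param a,b [Volume-class] or [BinaryMask-class] objects.
#' @param tol relative tolerance on affine entries.
#' @return Logical scalar.
#' @export
sameGeometry <- function(a, b, tol = 1e-4) .sameGeom(a, b, tol)

.stopGeom <- function(a, b, what = "inputs") {
    if (!.sameGeom(a, b))
        stop(sprintf(
            "geometry mismatch between %s: shapes %s vs %s (affines must agree within 1e-4)",
            what, paste(dim(a@data), collapse = "x"),
            paste(dim(b@data), collapse = "x")), call. = FALSE)
    invisible(TRUE)
}

## Grid of all voxel centres as an n x 3 matrix of 0-based indices,
## in column-major (raster) order.
.voxelGrid <- function(d) {
    cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
          rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
          rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

#' Construct a Volume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix; built from `spacing` if missing.
#' @param spacing mm per voxel (used only when `affine` is missing).
#' @param role `"intensity"`, `"fraction"`, `"bias"` or `"label"`.
#' @return A [Volume-class].
#' @examples
#' v <- volume(array(0, c(8, 8, 8)))
#' spacing(v)
#' @export
volume <- function(data, affine = NULL, spacing = c(1, 1, 1),
                   role = "intensity") {
    if (is.null(affine)) affine <- spacingAffine(spacing)
    storage.mode(data) <- "double"
    new("Volume", data = data, affine = affine, role = role)
}

#' Construct a BinaryMask
#'
#' @param data 3-D array, coerced to logical (nonzero = foreground).
#' @inheritParams volume
#' @return A [BinaryMask-class].
#' @export
binaryMask <- function(data, affine = NULL, spacing = c(1, 1, 1)) {
    if (is.null(affine)) affine <- spacingAffine(spacing)
    d <- dim(data)
    data <- as.logical(data != 0)
    dim(data) <- d
    new("BinaryMask", data = data, affine = affine)
}

## Rebuild a mask on the geometry of `like` from a logical/integer array.
.maskLike <- function(data, like) {
    d <- dim(like@data)
    data <- as.logical(data)
    dim(data) <- d
    new("BinaryMask", data = data, affine = like@affine)
}

#' @describeIn spacing column norms of the affine 3x3 block.
#' @export
setMethod("spacing", "ImageGrid",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @describeIn affine the stored 4x4 matrix.
#' @export
setMethod("affine", "ImageGrid", function(x) x@affine)

#' @describeIn imgData the stored array.
#' @export
setMethod("imgData", "ImageGrid", function(x) x@data)

#' @describeIn voxelCount foreground count of a mask.
#' @export
setMethod("voxelCount", "BinaryMask", function(x) sum(x@data))

setMethod("show", "Volume", function(object) {
    cat(sprintf("Volume [%s] %s, spacing %s mm, range [%.4g, %.4g]\n",
                object@role, paste(dim(object@data), collapse = "x"),
                paste(signif(spacing(object), 4), collapse = "x"),
                min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask %s, spacing %s mm, %d foreground voxel(s)\n",
                paste(dim(object@data), collapse = "x"),
                paste(signif(spacing(object), 4), collapse = "x"),
                sum(object@data)))
})

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is left untouched.
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}
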