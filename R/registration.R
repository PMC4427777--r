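## Nine-parameter affine registration (translation, rotation, per-axis
## scale) by derivative-free minimisation of the mean squared intensity
## difference, coarse-to-fine over 4/2/1 mm sampling grids. The transform
## maps moving-image world coordinates into fixed-image world coordinates.

#' Construct an AffineTransform
#'
#' @param matrix 4x4 homogeneous world-to-world matrix (mm).
#' @return A validated [AffineTransform-class].
#' @export
affineTransform <- function(matrix = diag(4)) {
    new("AffineTransform", matrix = matrix)
}

#' @describeIn affineTransform the composed transform `a` after `b`
#'   (applies `b` first).
#' @param a,b [AffineTransform-class] objects.
#' @export
composeTransforms <- function(a, b) affineTransform(a@matrix %*% b@matrix)

#' @describeIn affineTransform the inverse transform.
#' @param xf an [AffineTransform-class].
#' @export
invertTransform <- function(xf) affineTransform(solve(xf@matrix))

#' Read/write a transform as a plain-text 4x4 matrix (row-major, mm)
#'
#' @param xf an [AffineTransform-class].
#' @param path text file path.
#' @return `writeTransform` returns `path` invisibly; `readTransform`
#'   returns an [AffineTransform-class].
#' @export
writeTransform <- function(xf, path) {
    write(t(xf@matrix), path, ncolumns = 4)
    invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
    affineTransform(matrix(scan(path, quiet = TRUE), 4, 4, byrow = TRUE))
}

## Rotation (ZYX order, degrees) and per-axis scale about a world centre,
## plus translation: F(w) = R S (w - c) + c + t.
.paramsToMatrix <- function(t, rdeg, s, centre) {
    r <- rdeg * pi / 180
    cx <- cos(r[1]); sx <- sin(r[1])
    cy <- cos(r[2]); sy <- sin(r[2])
    cz <- cos(r[3]); sz <- sin(r[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    A <- Rz %*% Ry %*% Rx %*% diag(s)
    M <- diag(4)
    M[1:3, 1:3] <- A
    M[1:3, 4] <- centre + t - A %*% centre
    M
}

## Intensity-weighted centre of mass and per-axis second moments (world mm).
.moments <- function(vol) {
    w <- pmax(as.vector(vol@data), 0)
    tot <- sum(w)
    if (tot <= 0) stop("volume has no positive mass", call. = FALSE)
    wc <- voxelToWorld(vol@affine, .voxelGrid(dim(vol@data)))
    com <- colSums(wc * w) / tot
    m2 <- colSums((wc - rep(com, each = nrow(wc)))^2 * w) / tot
    list(com = com, m2 = m2)
}

#' Registration settings
#'
#' @param levels sampling spacings in mm, coarse to fine.
#' @param maxSweeps cap on coordinate-descent sweeps per level.
#' @param maxPoints cap on the number of fixed-image sample points.
#' @param tol relative cost-change convergence threshold.
#' @return A plain list of settings for [registerAffine()].
#' @export
registrationControl <- function(levels = c(4, 2, 1), maxSweeps = 200L,
                                maxPoints = 20000L, tol = 1e-6) {
    list(levels = levels, maxSweeps = as.integer(maxSweeps),
         maxPoints = as.integer(maxPoints), tol = tol)
}

#' Affine registration of two volumes
#'
#' Estimates the 9-parameter transform (3 translations, 3 rotations, 3
#' scales) mapping `moving` world coordinates toward `fixed`, by minimising
#' the mean squared intensity difference. Initialisation: centre-of-mass
#' translation plus second-moment per-axis scaling. Optimisation: greedy
#' coordinate descent with step halving, coarse to fine over the control's
#' sampling levels. Fully deterministic for fixed inputs and settings.
#'
#' @param moving,fixed nonconstant intensity [Volume-class]s.
#' @param control settings from [registrationControl()].
#' @return An [AffineTransform-class] (moving world to fixed world), with
#'   the final cost in attribute `"cost"`.
#' @export
registerAffine <- function(moving, fixed, control = registrationControl()) {
    stopifnot(is(moving, "Volume"), is(fixed, "Volume"))
    if (diff(range(moving@data)) < 1e-12 || diff(range(fixed@data)) < 1e-12)
        stop("both volumes must be nonconstant", call. = FALSE)
    mF <- .moments(fixed)
    mM <- .moments(moving)
    centre <- mM$com
    par <- c(mF$com - mM$com, 0, 0, 0,
             log(pmin(pmax(sqrt(mF$m2 / mM$m2), 0.7), 1.4)))

    dM <- dim(moving@data)
    movVec <- as.vector(moving@data)
    movInv <- solve(moving@affine)
    dF <- dim(fixed@data)
    fixVec <- as.vector(fixed@data)
    thr <- 0.05 * max(fixVec)

    cost <- function(par, pts, vals) {
        Fm <- .paramsToMatrix(par[1:3], par[4:6], exp(par[7:9]), centre)
        Minv <- movInv %*% solve(Fm)
        src <- t(Minv %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
        mean((sample_trilinear(movVec, dM, src, 0) - vals)^2)
    }

    spF <- spacing(fixed)
    cur <- NA_real_
    for (lev in control$levels) {
        stride <- pmax(1L, as.integer(round(lev / spF)))
        keep <- array(FALSE, dF)
        keep[seq(1L, dF[1], stride[1]), seq(1L, dF[2], stride[2]),
             seq(1L, dF[3], stride[3])] <- TRUE
        idx <- which(keep & fixVec > thr)
        if (length(idx) > control$maxPoints)
            idx <- idx[seq(1L, length(idx),
                           by = ceiling(length(idx) / control$maxPoints))]
        if (length(idx) < 100L) next
        pts <- voxelToWorld(fixed@affine, arrayInd(idx, dF) - 1)
        vals <- fixVec[idx]

        steps <- c(rep(0.5 * lev, 3), rep(0.5 * lev, 3), rep(0.01 * lev, 3))
        cur <- cost(par, pts, vals)
        if (!is.finite(cur))
            stop("non-finite registration cost at initialisation", call. = FALSE)
        for (sweep in seq_len(control$maxSweeps)) {
            improved <- FALSE
            for (j in 1:9) {
                for (sgn in c(1, -1)) {
                    cand <- par
                    cand[j] <- cand[j] + sgn * steps[j]
                    v <- cost(cand, pts, vals)
                    if (!is.finite(v))
                        stop(sprintf(
                            "non-finite registration cost (level %g mm, sweep %d, parameter %d)",
                            lev, sweep, j), call. = FALSE)
                    if (v < cur * (1 - 1e-12)) {
                        par <- cand; cur <- v; improved <- TRUE
                        break
                    }
                }
            }
            if (!improved) {
                steps <- steps / 2
                if (all(steps < c(rep(0.02, 6), rep(0.001, 3)))) break
            }
        }
    }
    out <- affineTransform(.paramsToMatrix(par[1:3], par[4:6],
                                           exp(par[7:9]), centre))
    attr(out, "cost") <- cur
    out
}

#' Warp a binary mask through an affine transform
#'
#' Resamples `mask` (moving space) onto the `target` geometry (fixed space)
#' with nearest-neighbour interpolation, so the output value set stays
#' binary.
#'
#' @param mask a [BinaryMask-class] in moving space.
#' @param xf [AffineTransform-class] mapping moving world to fixed world.
#' @param target a [Volume-class] or [BinaryMask-class] supplying the output
#'   geometry.
#' @param interp only `"nearest"` is supported for masks.
#' @return A [BinaryMask-class] on the target geometry.
#' @export
applyTransform <- function(mask, xf, target, interp = "nearest") {
    stopifnot(is(mask, "BinaryMask"), is(xf, "AffineTransform"))
    interp <- match.arg(interp, "nearest")
    if (abs(det(xf@matrix[1:3, 1:3])) < 1e-12)
        stop("singular transform", call. = FALSE)
    dT <- dim(target@data)
    grid <- .voxelGrid(dT)
    wFix <- voxelToWorld(target@affine, grid)
    wMov <- t(solve(xf@matrix) %*% rbind(t(wFix), 1))[, 1:3, drop = FALSE]
    src <- worldToVoxel(mask@affine, wMov)
    vals <- sample_nearest(as.numeric(mask@data), dim(mask@data), src, 0)
    .maskLike(vals != 0, .asGridCarrier(target))
}

## Carrier with the geometry of `x` for .maskLike.
.asGridCarrier <- function(x) {
    if (is(x, "BinaryMask")) x
    else new("BinaryMask", data = array(FALSE, dim(x@data)), affine = x@affine)
}

#' Align the brain-stem atlas to a subject
#'
#' Registers the atlas template to the subject volume (affine, 9 d.o.f.)
#' and warps the template-space brain-stem + peduncle mask into subject
#' space with nearest-neighbour resampling.
#'
#' @param atlas a [BrainStemAtlas-class].
#' @param subject the subject's (preprocessed) intensity [Volume-class].
#' @param control settings from [registrationControl()].
#' @return The warped stem [BinaryMask-class] on the subject geometry, with
#'   the recovered [AffineTransform-class] in attribute `"transform"`.
#' @export
alignAtlas <- function(atlas, subject, control = registrationControl()) {
    stopifnot(is(atlas, "BrainStemAtlas"), is(subject, "Volume"))
    xf <- registerAffine(atlas@template, subject, control)
    warped <- applyTransform(atlas@stemMask, xf, subject)
    if (!any(warped@data))
        stop("atlas alignment produced an empty brain-stem mask", call. = FALSE)
    attr(warped, "transform") <- xf
    warped
}

setMethod("show", "AffineTransform", function(object) {
    cat("AffineTransform (world mm, moving -> fixed):\n")
    print(round(object@matrix, 4))
})
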