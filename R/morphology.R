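## 3-D binary morphology and connected components. The contracts are
## definitional: outside the grid counts as background for both erosion and
## dilation; components are relabelled 1..K in decreasing size order with
## ties broken by the smallest minimum raster index.

## Neighbour offsets (excluding the origin) for a connectivity class.
.connOffsets <- function(connectivity) {
    if (!connectivity %in% c(6L, 18L, 26L))
        stop("connectivity must be 6, 18 or 26", call. = FALSE)
    g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
    n <- rowSums(abs(g))
    keep <- switch(as.character(connectivity),
                   "6" = n == 1, "18" = n >= 1 & n <= 2, "26" = n >= 1)
    storage.mode(g) <- "integer"
    unname(g[keep, , drop = FALSE])
}

#' Ball structuring element
#'
#' All integer voxel offsets with Euclidean norm at most `radius`.
#'
#' @param radius nonnegative integer ball radius in voxels. Radius 0 yields
#'   the origin alone (7 offsets at radius 1, 33 at radius 2).
#' @return A [StructuringElement-class].
#' @examples
#' nrow(ballElement(1)@offsets)  # 7
#' @export
ballElement <- function(radius) {
    if (length(radius) != 1L || is.na(radius) || radius < 0 ||
        radius != round(radius))
        stop("radius must be a single nonnegative integer", call. = FALSE)
    r <- as.integer(radius)
    g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
    g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
    storage.mode(g) <- "integer"
    new("StructuringElement", offsets = unname(g), radius = as.numeric(r))
}

#' Binary erosion
#'
#' A voxel stays foreground iff every structuring-element translate lies
#' inside the grid and on foreground; voxels outside the grid count as
#' background. The result is always a subset of the input.
#'
#' @param mask a [BinaryMask-class].
#' @param se a [StructuringElement-class].
#' @return The eroded [BinaryMask-class].
#' @export
erodeMask <- function(mask, se) {
    stopifnot(is(mask, "BinaryMask"), is(se, "StructuringElement"))
    .maskLike(morph_erode(as.vector(mask@data), dim(mask@data), se@offsets), mask)
}

#' Binary dilation
#'
#' A voxel becomes foreground iff any structuring-element translate hits
#' input foreground. The input is always a subset of the result.
#'
#' @inheritParams erodeMask
#' @return The dilated [BinaryMask-class].
#' @export
dilateMask <- function(mask, se) {
    stopifnot(is(mask, "BinaryMask"), is(se, "StructuringElement"))
    .maskLike(morph_dilate(as.vector(mask@data), dim(mask@data), se@offsets), mask)
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same element: removes structures
#' thinner than the element while preserving larger shapes. Idempotent and
#' anti-extensive (`open(X)` is a subset of `X`).
#'
#' @inheritParams erodeMask
#' @return The opened [BinaryMask-class].
#' @export
openMask <- function(mask, se) dilateMask(erodeMask(mask, se), se)

#' Connected-component analysis
#'
#' Labels the foreground into maximal connected components under the chosen
#' adjacency. Components are numbered 1..K in decreasing size order; equal
#' sizes are broken by the smallest minimum raster-order (column-major)
#' index, so labelling is fully deterministic.
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
#' @return List with `labels` (integer array, 0 = background) and `sizes`
#'   (integer vector, `sizes[k]` = voxels in component k). An empty mask
#'   yields zero components.
#' @export
connectedComponents <- function(mask, connectivity = 26L) {
    stopifnot(is(mask, "BinaryMask"))
    off <- .connOffsets(as.integer(connectivity))
    lab <- morph_label(as.vector(mask@data), dim(mask@data), off)
    k <- max(lab)
    if (k == 0L) {
        dim(lab) <- dim(mask@data)
        return(list(labels = lab, sizes = integer(0)))
    }
    sizes <- tabulate(lab, nbins = k)
    first <- match(seq_len(k), lab)      # min raster index per label
    ord <- order(-sizes, first)
    remap <- integer(k)
    remap[ord] <- seq_len(k)
    lab <- c(0L, remap)[lab + 1L]
    dim(lab) <- dim(mask@data)
    list(labels = lab, sizes = sizes[ord])
}

#' Largest connected component
#'
#' @inheritParams connectedComponents
#' @return The component labelled 1 by [connectedComponents()] as a
#'   [BinaryMask-class].
#' @export
largestComponent <- function(mask, connectivity = 26L) {
    stopifnot(is(mask, "BinaryMask"))
    if (!any(mask@data))
        stop("cannot select the largest component of an empty mask",
             call. = FALSE)
    cc <- connectedComponents(mask, connectivity)
    .maskLike(cc$labels == 1L, mask)
}

#' Fill internal holes of a mask
#'
#' Background components not connected (6-adjacency) to the grid border are
#' converted to foreground.
#'
#' @param mask a [BinaryMask-class].
#' @return The filled [BinaryMask-class].
#' @export
fillHoles <- function(mask) {
    stopifnot(is(mask, "BinaryMask"))
    d <- dim(mask@data)
    bg <- morph_label(as.vector(!mask@data), d, .connOffsets(6L))
    dim(bg) <- d
    border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
    border <- border[border != 0L]
    .maskLike(mask@data | (bg != 0L & !(bg %in% border)), mask)
}
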