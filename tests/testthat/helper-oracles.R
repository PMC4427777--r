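## Brute-force oracles, independent of the package's compiled kernels, plus
## a session cache so expensive phantom cases are generated once per run.

.tcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (is.null(.tcache[[key]])) .tcache[[key]] <- force(expr)
    .tcache[[key]]
}

testCase <- function(grid = 64, sigma = 0, amp = 0, seed = 1) {
    cached(paste("case", grid, sigma, amp, seed),
           generatePhantom(phantomConfig(gridShape = grid, noiseSigma = sigma,
                                         biasAmplitude = amp, seed = seed)))
}

testAtlas <- function(grid = 64) {
    cached(paste("atlas", grid), phantomAtlas(phantomConfig(gridShape = grid)))
}

## out[v] <- a[v + o], with FALSE/0 outside the grid
shiftArr <- function(a, o, fill = FALSE) {
    d <- dim(a)
    out <- array(fill, d)
    rx <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    ry <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    rz <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    if (length(rx) < 1 || length(ry) < 1 || length(rz) < 1) return(out)
    out[rx, ry, rz] <- a[rx + o[1], ry + o[2], rz + o[3]]
    out
}

## Definitional erosion: keep v iff a[v + o] for every offset o.
oracleErode <- function(a, off) {
    out <- a
    for (k in seq_len(nrow(off))) out <- out & shiftArr(a, off[k, ])
    out
}

## Definitional dilation: set v iff a[v + o] for any offset o (symmetric SE).
oracleDilate <- function(a, off) {
    out <- array(FALSE, dim(a))
    for (k in seq_len(nrow(off))) out <- out | shiftArr(a, off[k, ])
    out
}

## Connected components by iterated label propagation: every voxel starts
## with its raster index and repeatedly takes the max over its neighbours
## until a fixed point; the component id is the max raster index it holds.
oracleLabel <- function(a, conn = 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    n <- rowSums(abs(g))
    off <- g[switch(as.character(conn), "6" = n == 1,
                    "18" = n >= 1 & n <= 2, "26" = n >= 1), , drop = FALSE]
    lab <- array(0L, dim(a))
    lab[a] <- which(a)
    repeat {
        nb <- lab
        for (k in seq_len(nrow(off)))
            nb <- pmax(nb, shiftArr(lab, off[k, ], fill = 0L))
        nb[!a] <- 0L
        if (identical(nb, lab)) break
        lab <- nb
    }
    lab
}

## Canonical relabelling of an oracle id array: 1..K by decreasing size,
## ties broken by smallest minimum raster index.
oracleComponents <- function(a, conn = 26L) {
    lab <- oracleLabel(a, conn)
    ids <- sort(unique(as.vector(lab[lab > 0])))
    if (length(ids) == 0L)
        return(list(labels = array(0L, dim(a)), sizes = integer(0)))
    sizes <- vapply(ids, function(i) sum(lab == i), 0L)
    first <- vapply(ids, function(i) which(lab == i)[1], 0L)
    ord <- order(-sizes, first)
    out <- array(0L, dim(a))
    for (r in seq_along(ord)) out[lab == ids[ord[r]]] <- r
    list(labels = out, sizes = sizes[ord])
}

## Voxel-loop overlap counts (the slow, direct definition).
oracleOverlap <- function(ref, seg) {
    nRef <- 0L; nSeg <- 0L; nInt <- 0L
    for (i in seq_along(ref)) {
        if (ref[i]) nRef <- nRef + 1L
        if (seg[i]) nSeg <- nSeg + 1L
        if (ref[i] && seg[i]) nInt <- nInt + 1L
    }
    c(nRef = nRef, nSeg = nSeg, nIntersect = nInt)
}

randomMask <- function(d = c(16, 16, 16), density = 0.5) {
    binaryMask(array(runif(prod(d)) < density, d))
}

cubeSE <- function() {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    storage.mode(g) <- "integer"
    new("StructuringElement", offsets = unname(g), radius = 1)
}
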