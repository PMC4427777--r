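## Surrogate preprocessing chain: polynomial bias-field correction,
## threshold-plus-morphology brain extraction, Gaussian-mixture tissue
## classification, and linear two-class partial-volume estimation.

## Tensor monomial exponents up to a total degree.
.polyExponents <- function(order) {
    ex <- as.matrix(expand.grid(a = 0:order, b = 0:order, c = 0:order))
    unname(ex[rowSums(ex) <= order, , drop = FALSE])
}

## Design matrix of monomials at the given normalised coordinates.
.polyDesign <- function(xn, yn, zn, ex) {
    B <- matrix(1, length(xn), nrow(ex))
    for (k in seq_len(nrow(ex)))
        B[, k] <- xn^ex[k, 1] * yn^ex[k, 2] * zn^ex[k, 3]
    B
}

#' Polynomial intensity-inhomogeneity correction
#'
#' Estimates the slowly varying multiplicative bias field by least-squares
#' fitting a 3-D polynomial to the log-intensities inside the brain mask,
#' normalises the field to mean 1 over the brain, and divides it out. To
#' keep genuine tissue contrast out of the spatial fit, the polynomial is
#' anchored on the dominant intensity mode (grey matter in a T1 brain):
#' only voxels near that mode enter the fit, outliers are discarded by a
#' MAD criterion, and the selection is iterated as the running correction
#' sharpens the mode. The mean brain intensity is preserved exactly.
#'
#' @param vol intensity [Volume-class]; the log fit uses the positive
#'   intensities inside the brain mask (at least 100 required).
#' @param brain nonempty [BinaryMask-class] on the same geometry.
#' @param polyOrder total polynomial degree, 1 to 4 (default 3).
#' @return List with `volume` (corrected copy) and `bias` (the estimated
#'   field, role `"bias"`).
#' @export
correctInhomogeneity <- function(vol, brain, polyOrder = 3L) {
    stopifnot(is(vol, "Volume"), is(brain, "BinaryMask"))
    .stopGeom(vol, brain, "volume and brain mask")
    if (length(polyOrder) != 1L || polyOrder < 1 || polyOrder > 4)
        stop("polyOrder must lie in [1, 4]", call. = FALSE)
    idx <- which(brain@data)
    if (length(idx) == 0L) stop("brain mask is empty", call. = FALSE)
    y <- vol@data[idx]
    ## fit on the eroded brain so edge voxels mixing with background do not
    ## masquerade as spatial intensity structure; noise can push boundary
    ## voxels nonpositive, so those are excluded from the log fit
    core <- erodeMask(brain, ballElement(1))
    fitIdx <- which(core@data)
    if (length(fitIdx) < 1000L) fitIdx <- idx
    fitIdx <- fitIdx[vol@data[fitIdx] > 0]
    if (length(fitIdx) < 100L)
        stop("nonpositive intensities inside the brain mask: log-bias undefined",
             call. = FALSE)
    d <- dim(vol@data)
    norm1 <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else i * 0
    yf <- vol@data[fitIdx]
    vox <- arrayInd(fitIdx, d)
    ex <- .polyExponents(as.integer(polyOrder))
    ex <- ex[rowSums(ex) > 0, , drop = FALSE]      # constant lives in the offsets
    B <- .polyDesign(norm1(vox[, 1], d[1]), norm1(vox[, 2], d[2]),
                     norm1(vox[, 3], d[3]), ex)
    ## iterative robust fit anchored on the dominant tissue mode (GM in a
    ## T1 brain): select voxels within a relative window of that mode,
    ## least-squares fit log-intensity, then refit after discarding
    ## MAD-flagged outliers (other tissues, interface partial volumes).
    ## The window narrows as the running correction sharpens the mode.
    yc <- yf
    coefs <- numeric(nrow(ex))
    for (w in c(0.3, 0.2, 0.12, 0.07, 0.04)) {
        m <- .histModes(yc, 1L, nbins = 512L)
        if (length(m) == 0L) m <- stats::median(yc)
        sel <- which(abs(yc / m - 1) < w)
        if (length(sel) < 500L) sel <- seq_along(yc)
        X <- cbind(1, B[sel, , drop = FALSE])
        ly <- log(yf[sel])
        ft <- lm.fit(X, ly)
        s <- stats::mad(ft$residuals)
        thr <- if (is.finite(s) && s > 1e-8) 2.5 * s else 1e-6
        k2 <- abs(ft$residuals) < thr
        if (sum(k2) >= 500L) ft <- lm.fit(X[k2, , drop = FALSE], ly[k2])
        coefs <- ft$coefficients[-1]
        coefs[is.na(coefs)] <- 0
        yc <- yf / exp(as.vector(B %*% coefs))
    }

    ## evaluate the fitted field over the full grid from separable terms
    cx <- norm1(seq_len(d[1]), d[1]); cy <- norm1(seq_len(d[2]), d[2])
    cz <- norm1(seq_len(d[3]), d[3])
    logb <- array(0, d)
    for (k in seq_len(nrow(ex)))
        if (coefs[k] != 0)
            logb <- logb + coefs[k] * outer(outer(cx^ex[k, 1], cy^ex[k, 2]),
                                            cz^ex[k, 3])
    bias <- exp(logb)
    bias <- bias / mean(bias[idx])
    corrected <- vol@data / bias
    s <- mean(y) / mean(corrected[idx])
    corrected <- corrected * s
    bias <- bias / s
    list(volume = volume(corrected, affine = vol@affine, role = vol@role),
         bias = volume(bias, affine = vol@affine, role = "bias"))
}

## Otsu threshold on a 256-bin histogram.
.otsu <- function(x, nbins = 256L) {
    r <- range(x)
    h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
    p <- h / sum(h)
    mids <- r[1] + (seq_len(nbins) - 0.5) * diff(r) / nbins
    w0 <- cumsum(p)
    mu <- cumsum(p * mids)
    muT <- mu[nbins]
    between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
    between[!is.finite(between)] <- 0
    mids[which.max(between)]
}

#' Threshold-based brain extraction
#'
#' Surrogate skull stripping: Otsu threshold, ball-radius-2 morphological
#' closing, largest 26-connected component, internal hole filling. The
#' result is a single connected component without internal holes.
#'
#' @param vol intensity [Volume-class] with nonzero dynamic range.
#' @return A [BinaryMask-class].
#' @export
extractBrainMask <- function(vol) {
    stopifnot(is(vol, "Volume"))
    if (diff(range(vol@data)) < 1e-12)
        stop("volume is constant: no dynamic range for brain extraction",
             call. = FALSE)
    thr <- .otsu(as.vector(vol@data))
    m <- binaryMask(array(vol@data > thr, dim(vol@data)), affine = vol@affine)
    if (!any(m@data))
        stop("thresholding produced an empty brain mask", call. = FALSE)
    se <- ballElement(2)
    m <- erodeMask(dilateMask(m, se), se)           # closing
    m <- largestComponent(m, 26L)
    fillHoles(m)
}

#' Gaussian-mixture tissue classification
#'
#' Fits a deterministic three-component Gaussian mixture to the brain
#' intensities (5/50/95% quantile initialisation refined by Lloyd k-means,
#' EM to convergence with a variance floor), orders components by mean as
#' CSF < GM < WM, and labels every brain voxel by maximum posterior. For
#' speed the mixture parameters are fitted on an evenly strided subsample
#' when the brain exceeds 200000 voxels; labelling always uses all voxels.
#'
#' @param vol intensity [Volume-class] (ideally bias-corrected).
#' @param brain [BinaryMask-class] with at least 100 foreground voxels.
#' @param seed integer; reserved for stochastic restarts (the default
#'   initialisation is deterministic).
#' @param maxIter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return A [TissueLabels-class].
#' @export
classifyTissue <- function(vol, brain, seed = 1L, maxIter = 200L, tol = 1e-6) {
    stopifnot(is(vol, "Volume"), is(brain, "BinaryMask"))
    .stopGeom(vol, brain, "volume and brain mask")
    idx <- which(brain@data)
    if (length(idx) < 100L)
        stop("need at least 100 brain voxels to fit the tissue mixture",
             call. = FALSE)
    x <- vol@data[idx]
    if (length(unique(x)) < 3L)
        stop("degenerate fit: fewer than 3 distinct intensities", call. = FALSE)

    ## fit the mixture on the eroded brain (edge voxels mixing with
    ## background would contaminate the intensity modes); label all voxels
    core <- which(erodeMask(brain, ballElement(1))@data)
    xf <- if (length(core) >= 1000L) vol@data[core] else x
    if (length(xf) > 2e5)
        xf <- xf[seq(1L, length(xf), by = ceiling(length(xf) / 2e5))]
    fit <- .withSeed(seed, .fitGMM3(xf, maxIter = maxIter, tol = tol))

    post <- .gmmPosterior(x, fit)
    lab <- max.col(post, ties.method = "first")
    arr <- array(0L, dim(vol@data))
    arr[idx] <- lab
    new("TissueLabels", data = arr, affine = vol@affine,
        classMeans = c(csf = fit$mean[1], gm = fit$mean[2], wm = fit$mean[3]),
        classSds = c(csf = fit$sd[1], gm = fit$sd[2], wm = fit$sd[3]))
}

## The n most prominent, mutually separated modes of a smoothed histogram
## (greedy: take the tallest bin, suppress its neighbourhood, repeat).
.histModes <- function(x, n = 3L, nbins = 128L) {
    r <- range(x)
    if (diff(r) < 1e-12) return(numeric(0))
    bw <- diff(r) / nbins
    h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / bw)), nbins)
    k <- c(1, 2, 3, 2, 1) / 9
    hs <- as.numeric(stats::filter(c(0, 0, h, 0, 0), k, sides = 2))[3:(nbins + 2)]
    mids <- r[1] + (seq_len(nbins) - 0.5) * bw
    minsep <- max(2L, nbins %/% 8L)
    peaks <- numeric(0)
    for (i in seq_len(n)) {
        j <- which.max(hs)
        if (hs[j] <= 0) break
        peaks <- c(peaks, mids[j])
        hs[max(1L, j - minsep):min(nbins, j + minsep)] <- 0
    }
    peaks
}

## Robust three-component 1-D Gaussian mixture via EM, deterministic init.
## A fourth, uniform "outlier" component over the intensity range absorbs
## the partial-volume mixing plateaus between tissue modes, so the Gaussian
## means lock onto the pure-tissue modes instead of drifting to cover the
## interface tails. Tissue posteriors/labels use the Gaussians only.
.fitGMM3 <- function(x, maxIter = 200L, tol = 1e-6) {
    rng <- range(x)
    floorSd <- max(0.5, 1e-3 * diff(rng))
    logUnif <- -log(diff(rng) + 1e-12)
    mu <- .histModes(x, 3L)
    if (length(mu) < 3L) {
        mu <- unname(quantile(x, c(0.05, 0.5, 0.95)))
        if (any(duplicated(mu))) mu <- mu + c(-1, 0, 1) * max(sd(x), 1) / 2
    }
    mu <- sort(mu)
    sg <- rep(max(floorSd, diff(rng) / 64), 3)
    w <- rep(0.3, 3)
    wu <- 1 - sum(w)                    # uniform outlier weight
    ll0 <- -Inf
    for (it in seq_len(maxIter)) {
        lp <- vapply(1:3, function(k)
            log(w[k]) + dnorm(x, mu[k], sg[k], log = TRUE), numeric(length(x)))
        lp <- cbind(lp, log(wu) + logUnif)
        mx <- lp[cbind(seq_along(x), max.col(lp, ties.method = "first"))]
        se <- exp(lp - mx)
        tot <- rowSums(se)
        ll <- sum(mx + log(tot))
        resp <- se / tot
        nk <- colSums(resp)
        w <- nk[1:3] / length(x)
        wu <- max(nk[4] / length(x), 1e-6)
        mu <- colSums(resp[, 1:3, drop = FALSE] * x) / nk[1:3]
        sg <- sqrt(colSums(resp[, 1:3, drop = FALSE] *
                           (x - rep(mu, each = length(x)))^2) / nk[1:3])
        sg[!is.finite(sg) | sg < floorSd] <- floorSd
        if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1e-12)) break
        ll0 <- ll
    }
    ord <- order(mu)
    list(mean = mu[ord], sd = sg[ord], weight = w[ord], outlierWeight = wu)
}

## Posterior over the three tissue Gaussians (outlier component excluded,
## so every voxel gets a tissue label).
.gmmPosterior <- function(x, fit) {
    lp <- vapply(1:3, function(k)
        log(fit$weight[k]) + dnorm(x, fit$mean[k], fit$sd[k], log = TRUE),
        numeric(length(x)))
    mx <- lp[cbind(seq_along(x), max.col(lp, ties.method = "first"))]
    se <- exp(lp - mx)
    se / rowSums(se)
}

#' Linear two-class partial-volume estimation
#'
#' For a voxel with intensity between two adjacent fitted class means the
#' two classes mix linearly (`fraction_b = (y - mu_a)/(mu_b - mu_a)`); the
#' third class is 0. Intensities at or below the CSF mean are pure CSF, at
#' or above the WM mean pure WM. CSF only ever mixes with GM and GM with WM
#' (no CSF-WM mixing), matching the interface behaviour the segmentation
#' pipeline consumes.
#'
#' @param vol intensity [Volume-class] on the geometry the labels were
#'   fitted on.
#' @param labels a [TissueLabels-class] from [classifyTissue()].
#' @return A [PVEMaps-class]; fractions sum to 1 on brain voxels (nonzero
#'   labels) and are 0 outside.
#' @export
estimatePVE <- function(vol, labels) {
    stopifnot(is(vol, "Volume"), is(labels, "TissueLabels"))
    if (!identical(dim(vol@data), dim(labels@data)) ||
        max(abs(vol@affine - labels@affine)) >
            1e-4 * max(1, max(abs(vol@affine))))
        stop("labels were fitted on a different geometry", call. = FALSE)
    mu <- labels@classMeans
    if (any(diff(mu) <= 0))
        stop("class means must be strictly increasing", call. = FALSE)
    d <- dim(vol@data)
    y <- as.vector(vol@data)
    brain <- as.vector(labels@data) > 0L
    csf <- gm <- wm <- numeric(length(y))
    lo <- brain & y <= mu[1]
    csf[lo] <- 1
    mid <- brain & y > mu[1] & y < mu[2]
    f <- (y[mid] - mu[1]) / (mu[2] - mu[1])
    gm[mid] <- f; csf[mid] <- 1 - f
    up <- brain & y >= mu[2] & y < mu[3]
    f <- (y[up] - mu[2]) / (mu[3] - mu[2])
    wm[up] <- f; gm[up] <- 1 - f
    hi <- brain & y >= mu[3]
    wm[hi] <- 1
    mk <- function(v) volume(array(v, d), affine = vol@affine, role = "fraction")
    new("PVEMaps", csf = mk(csf), gm = mk(gm), wm = mk(wm))
}
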