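## Synthetic skull-stripped head phantom. Anatomy is built from analytic
## primitives: ellipsoids for cerebrum and cerebellum (outer GM shell, inner
## WM core), a vertical cylinder for the brain stem, a horizontal cylinder
## for the cerebellar peduncle bridging stem and cerebellum, a thin CSF
## shell wrapping the cerebellum, and a curved venous-sinus slab behind the
## cerebellum separated from it by that CSF sheet. Partial-volume mixing is
## produced by evaluating the labels on a 3x-supersampled grid and averaging
## 3x3x3 blocks, so the ground-truth fraction maps are exact by construction.

#' Phantom anatomical label codes
#'
#' @return Named integer vector of the label codes used in
#'   [PhantomCase-class] label volumes.
#' @export
phantomLabels <- function() {
    c(background = 0L, cerebrum = 1L, cerebellum_gm = 2L, cerebellum_wm = 3L,
      brainstem = 4L, peduncle = 5L, sinus = 6L, csf = 7L)
}

#' Phantom generator configuration
#'
#' Default tissue means CSF=40, GM=100, WM=150 and sinus=95 (arbitrary
#' units): the sinus deliberately sits within 10% of the GM mean, which is
#' the intensity confound the segmentation pipeline must resolve. Default
#' noise (sigma 3) and bias (amplitude 0.1) are mild, typical-scanner
#' values; both can be set to 0 for an exactly noiseless phantom.
#'
#' @param gridShape voxels per axis (each >= 48); default 128^3 at 1 mm.
#' @param tissueMeans named numeric with `csf`, `gm`, `wm`, `sinus`.
#' @param noiseSigma additive Gaussian noise sd (intensity units).
#' @param biasAmplitude peak multiplicative bias deviation, in \[0, 0.5\].
#' @param csfSheetThickness minimum CSF gap (voxels) between sinus and
#'   cerebellum.
#' @param peduncleRadius peduncle cylinder radius in voxels; default scales
#'   with the grid (`max(2, round(min(gridShape)/21))`, i.e. 6 at 128^3).
#' @param seed integer seed for bias and noise.
#' @return A validated [PhantomConfig-class].
#' @export
phantomConfig <- function(gridShape = c(128L, 128L, 128L),
                          tissueMeans = c(csf = 40, gm = 100, wm = 150, sinus = 95),
                          noiseSigma = 3, biasAmplitude = 0.1,
                          csfSheetThickness = 1, peduncleRadius = NULL,
                          seed = 1L) {
    if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
    if (is.null(peduncleRadius))
        peduncleRadius <- max(2, round(min(gridShape) / 21))
    new("PhantomConfig", gridShape = as.integer(gridShape),
        tissueMeans = tissueMeans, noiseSigma = as.numeric(noiseSigma),
        biasAmplitude = as.numeric(biasAmplitude),
        csfSheetThickness = as.numeric(csfSheetThickness),
        peduncleRadius = as.numeric(peduncleRadius), seed = as.integer(seed))
}

## Geometric parameters in voxel units, proportional to the grid except for
## the CSF sheet, sinus slab and peduncle, whose thicknesses are absolute.
.anatomyParams <- function(config) {
    d <- as.numeric(config@gridShape)
    cerebS <- c(0.235, 0.172, 0.141) * d
    delta <- (config@csfSheetThickness + 0.8) / min(cerebS)
    list(cerebrumC = c(0.50, 0.47, 0.61) * d,
         cerebrumS = c(0.375, 0.43, 0.30) * d,
         cerebC = c(0.50, 0.64, 0.235) * d,
         cerebS = cerebS,
         wmScale = 0.55,
         stemC = c(0.50 * d[1], 0.375 * d[2]),
         stemR = 0.06 * min(d),
         stemZ = c(0.06, 0.39) * d[3],
         pedR = config@peduncleRadius,
         pedX = 0.50 * d[1], pedZ = 0.235 * d[3],
         pedY = c(0.375, 0.64) * d[2],
         shellDelta = delta,
         sinusDelta = max(2, 5 * min(d) / 128) / min(cerebS),
         sinusYmin = 0.64 * d[2] + max(2, 0.03 * d[2]))
}

## Squared normalised ellipsoid radius field over a coordinate grid,
## built from separable outer sums (no n^3 x n^3 work).
.ellipsoidField <- function(xs, ys, zs, centre, semi) {
    outer(outer(((xs - centre[1]) / semi[1])^2,
                ((ys - centre[2]) / semi[2])^2, "+"),
          ((zs - centre[3]) / semi[3])^2, "+")
}

## Paint the anatomical labels at arbitrary (possibly fractional) voxel
## coordinates. Later structures override earlier ones.
.paintLabels <- function(p, xs, ys, zs) {
    dm <- c(length(xs), length(ys), length(zs))
    lab <- array(0L, dm)

    lab[.ellipsoidField(xs, ys, zs, p$cerebrumC, p$cerebrumS) <= 1] <- 1L

    E <- .ellipsoidField(xs, ys, zs, p$cerebC, p$cerebS)
    r1 <- (1 + p$shellDelta)^2
    r2 <- (1 + p$shellDelta + p$sinusDelta)^2
    lab[E > 1 & E <= r1] <- 7L                           # CSF sheet/shell
    sector <- array(rep(rep(ys >= p$sinusYmin, each = dm[1]), dm[3]), dm)
    lab[E > r1 & E <= r2 & sector] <- 6L                 # venous sinus

    stem2 <- outer(((xs - p$stemC[1]) / p$stemR)^2,
                   ((ys - p$stemC[2]) / p$stemR)^2, "+")
    inZ <- zs >= p$stemZ[1] & zs <= p$stemZ[2]
    stem <- array(FALSE, dm)
    stem[, , inZ] <- rep(stem2 <= 1, sum(inZ))
    lab[stem] <- 4L                                      # brain stem

    lab[E <= 1] <- 2L                                    # cerebellar GM
    lab[.ellipsoidField(xs, ys, zs, p$cerebC, p$cerebS * p$wmScale) <= 1] <- 3L

    ped2 <- outer(((xs - p$pedX) / p$pedR)^2, ((zs - p$pedZ) / p$pedR)^2, "+")
    inY <- ys >= p$pedY[1] & ys <= p$pedY[2]
    ped <- array(FALSE, dm)
    ped[, inY, ] <- aperm(array(rep(ped2 <= 1, sum(inY)),
                                c(dm[1], dm[3], sum(inY))), c(1, 3, 2))
    lab[ped] <- 5L                                       # cerebellar peduncle
    lab
}

## Mean over 3x3x3 blocks of a supersampled array.
.blockMean3 <- function(a) {
    d <- dim(a) / 3L
    dim(a) <- c(3L, d[1], 3L, d[2], 3L, d[3])
    a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))
    dim(a) <- c(27L, prod(d))
    m <- colMeans(a)
    dim(m) <- d
    m
}

.anatomyCache <- new.env(parent = emptyenv())

## Labels, ground-truth fractions and ideal (noise- and bias-free) intensity
## for a configuration. Depends only on geometry + tissue means, so it is
## memoised; per-seed work is bias and noise only.
.phantomAnatomy <- function(config) {
    key <- paste(c(config@gridShape, config@tissueMeans,
                   config@csfSheetThickness, config@peduncleRadius),
                 collapse = "|")
    hit <- .anatomyCache[[key]]
    if (!is.null(hit)) return(hit)

    p <- .anatomyParams(config)
    d <- config@gridShape
    xs <- seq_len(d[1]) - 1; ys <- seq_len(d[2]) - 1; zs <- seq_len(d[3]) - 1
    labels <- .paintLabels(p, xs, ys, zs)

    tm <- config@tissueMeans
    ## intensity per label code 0..7
    lut <- c(0, tm["gm"], tm["gm"], tm["wm"], tm["wm"], tm["wm"],
             tm["sinus"], tm["csf"])
    csfSet <- c(7L); gmSet <- c(1L, 2L, 6L); wmSet <- c(3L, 4L, 5L)

    off <- c(-1, 0, 1) / 3
    fine1 <- function(v) as.vector(t(outer(v, off, "+")))   # 3x supersampled axis
    fx <- fine1(xs); fy <- fine1(ys)

    ideal <- array(0, d)
    csfF <- array(0, d); gmF <- array(0, d); wmF <- array(0, d)
    chunk <- max(1L, min(d[3], 16L))
    z0 <- 1L
    while (z0 <= d[3]) {
        z1 <- min(d[3], z0 + chunk - 1L)
        fz <- fine1(zs[z0:z1])
        fl <- .paintLabels(p, fx, fy, fz)
        ideal[, , z0:z1] <- .blockMean3(array(lut[fl + 1L], dim(fl)))
        csfF[, , z0:z1] <- .blockMean3(array(as.numeric(fl %in% csfSet), dim(fl)))
        gmF[, , z0:z1] <- .blockMean3(array(as.numeric(fl %in% gmSet), dim(fl)))
        wmF[, , z0:z1] <- .blockMean3(array(as.numeric(fl %in% wmSet), dim(fl)))
        z0 <- z1 + 1L
    }

    ## normalise fractions to a partition of unity on brain voxels
    brain <- labels > 0L
    tot <- csfF + gmF + wmF
    tot[!brain | tot <= 0] <- 1
    csfF <- ifelse(brain, csfF / tot, 0)
    gmF <- ifelse(brain, gmF / tot, 0)
    wmF <- ifelse(brain, wmF / tot, 0)
    dim(csfF) <- dim(gmF) <- dim(wmF) <- d

    out <- list(labels = labels, ideal = ideal,
                csf = csfF, gm = gmF, wm = wmF)
    .anatomyCache[[key]] <- out
    out
}

## Smooth random order-2 polynomial field with mean 1 and peak deviation
## exactly `amplitude`, deterministic per seed.
.randomPolyField <- function(d, amplitude, seed) {
    cs <- lapply(d, function(n) seq(-1, 1, length.out = n))
    ex <- as.matrix(expand.grid(a = 0:2, b = 0:2, c = 0:2))
    ex <- ex[rowSums(ex) >= 1 & rowSums(ex) <= 2, , drop = FALSE]
    coefs <- .withSeed(seed, runif(nrow(ex), -1, 1))
    g <- array(0, d)
    for (k in seq_len(nrow(ex)))
        g <- g + coefs[k] * outer(outer(cs[[1]]^ex[k, 1], cs[[2]]^ex[k, 2]),
                                  cs[[3]]^ex[k, 3])
    g <- g - mean(g)
    m <- max(abs(g))
    if (m < 1e-12) return(array(1, d))
    1 + amplitude * g / m
}

#' Apply a smooth multiplicative bias field
#'
#' Multiplies a volume by a random low-order (quadratic) polynomial field
#' with mean 1 and maximum deviation from 1 equal to `amplitude`, emulating
#' the slowly varying intensity inhomogeneity of MR acquisition.
#'
#' @param vol an intensity [Volume-class].
#' @param amplitude peak deviation from 1, in \[0, 0.5\].
#' @param seed integer seed selecting the field.
#' @return List with `volume` (biased copy) and `bias` (the field as a
#'   [Volume-class] of role `"bias"`).
#' @export
applyBiasField <- function(vol, amplitude, seed = 1L) {
    stopifnot(is(vol, "Volume"))
    if (length(amplitude) != 1L || amplitude < 0 || amplitude > 0.5)
        stop("amplitude must lie in [0, 0.5]", call. = FALSE)
    d <- dim(vol@data)
    field <- if (amplitude == 0) array(1, d)
             else .randomPolyField(d, amplitude, seed)
    list(volume = volume(vol@data * field, affine = vol@affine, role = vol@role),
         bias = volume(field, affine = vol@affine, role = "bias"))
}

#' Add i.i.d. Gaussian noise
#'
#' @param vol a [Volume-class].
#' @param sigma noise standard deviation (>= 0); 0 returns the input.
#' @param seed integer seed.
#' @return The noisy [Volume-class].
#' @export
addNoise <- function(vol, sigma, seed = 1L) {
    stopifnot(is(vol, "Volume"))
    if (length(sigma) != 1L || sigma < 0)
        stop("sigma must be a single nonnegative number", call. = FALSE)
    if (sigma == 0) return(vol)
    d <- dim(vol@data)
    noise <- .withSeed(seed, array(rnorm(prod(d), 0, sigma), d))
    volume(vol@data + noise, affine = vol@affine, role = vol@role)
}

#' Generate a synthetic head phantom
#'
#' Deterministic for a fixed configuration (seed included): builds the
#' anatomical labels, the exact partial-volume fraction maps and the ideal
#' intensity image, then applies the multiplicative bias field and additive
#' Gaussian noise requested by the configuration.
#'
#' @param config a [PhantomConfig-class].
#' @return A [PhantomCase-class].
#' @examples
#' cfg <- phantomConfig(gridShape = 48, noiseSigma = 0, biasAmplitude = 0)
#' case <- generatePhantom(cfg)
#' table(imgData(case@labels))
#' @export
generatePhantom <- function(config) {
    validObject(config)
    anat <- .phantomAnatomy(config)
    d <- config@gridShape
    aff <- spacingAffine(c(1, 1, 1))

    t1 <- volume(anat$ideal, affine = aff, role = "intensity")
    biased <- applyBiasField(t1, config@biasAmplitude, seed = config@seed)
    t1 <- addNoise(biased$volume, config@noiseSigma, seed = config@seed + 1L)

    pve <- new("PVEMaps",
               csf = volume(anat$csf, affine = aff, role = "fraction"),
               gm = volume(anat$gm, affine = aff, role = "fraction"),
               wm = volume(anat$wm, affine = aff, role = "fraction"))
    new("PhantomCase", t1 = t1,
        labels = volume(anat$labels + 0, affine = aff, role = "label"),
        pve = pve, bias = biased$bias, config = config, pose = diag(4))
}

#' Rigid-plus-scale pose perturbation of a phantom case
#'
#' Resamples every field of the case under a rotation/translation/uniform
#' scale about the volume centre (trilinear for intensities and bias,
#' nearest-neighbour for labels and fraction maps, which keeps the fraction
#' partition of unity exact). The applied world transform is composed into
#' the case's `pose` slot.
#'
#' @param case a [PhantomCase-class].
#' @param translation mm triple.
#' @param rotation degrees triple (each |angle| <= 30).
#' @param scale uniform scale factor in \[0.8, 1.25\].
#' @return The perturbed [PhantomCase-class].
#' @export
perturbPose <- function(case, translation = c(0, 0, 0),
                        rotation = c(0, 0, 0), scale = 1) {
    stopifnot(is(case, "PhantomCase"))
    if (any(abs(rotation) > 30))
        stop("rotation must be at most 30 degrees per axis", call. = FALSE)
    if (scale < 0.8 || scale > 1.25)
        stop("scale must lie in [0.8, 1.25]", call. = FALSE)
    d <- dim(case@t1@data)
    centre <- voxelToWorld(case@t1@affine, (d - 1) / 2)[1, ]
    Fm <- .paramsToMatrix(translation, rotation, rep(scale, 3), centre)
    Finv <- solve(Fm)
    grid <- .voxelGrid(d)
    src <- worldToVoxel(case@t1@affine,
                        voxelToWorld(Finv, voxelToWorld(case@t1@affine, grid)))
    tri <- function(v) {
        out <- sample_trilinear(as.vector(v@data), d, src, 0)
        dim(out) <- d
        volume(out, affine = v@affine, role = v@role)
    }
    nea <- function(v, role) {
        out <- sample_nearest(as.vector(v@data), d, src, 0)
        dim(out) <- d
        volume(out, affine = v@affine, role = role)
    }
    pve <- new("PVEMaps", csf = nea(case@pve@csf, "fraction"),
               gm = nea(case@pve@gm, "fraction"),
               wm = nea(case@pve@wm, "fraction"))
    new("PhantomCase", t1 = tri(case@t1), labels = nea(case@labels, "label"),
        pve = pve, bias = tri(case@bias), config = case@config,
        pose = Fm %*% case@pose)
}

#' Ground-truth masks of a phantom case
#'
#' Convenience accessors deriving binary masks from the label volume:
#' `brainMask` (all non-background labels), `cerebralMask` (cerebrum,
#' optionally dilated as a stand-in for a cortical-surface mask),
#' `cerebellumMask` (cerebellar GM+WM, the segmentation target),
#' `stemPeduncleMask` (brain stem + peduncle), `sinusMask`.
#'
#' @param case a [PhantomCase-class].
#' @param grow dilation radius in voxels applied to the cerebrum label
#'   (`cerebralMask` only).
#' @return A [BinaryMask-class].
#' @name phantom-masks
NULL

#' @rdname phantom-masks
#' @export
brainMask <- function(case) .maskLike(case@labels@data > 0, case@labels)

#' @rdname phantom-masks
#' @export
cerebralMask <- function(case, grow = 1L) {
    m <- .maskLike(case@labels@data == 1, case@labels)
    if (grow > 0) m <- dilateMask(m, ballElement(grow))
    m
}

#' @rdname phantom-masks
#' @export
cerebellumMask <- function(case)
    .maskLike(case@labels@data %in% c(2, 3), case@labels)

#' @rdname phantom-masks
#' @export
stemPeduncleMask <- function(case)
    .maskLike(case@labels@data %in% c(4, 5), case@labels)

#' @rdname phantom-masks
#' @export
sinusMask <- function(case) .maskLike(case@labels@data == 6, case@labels)

#' Phantom-derived brain-stem atlas
#'
#' Builds a [BrainStemAtlas-class] from the phantom anatomy: the template is
#' the ideal (noise- and bias-free) intensity rendering, and the stem mask
#' is the ground-truth brain stem + peduncle dilated by one voxel, emulating
#' the deliberately generous manual delineation of a template-space atlas.
#'
#' @param config a [PhantomConfig-class] describing the template anatomy.
#' @return A [BrainStemAtlas-class].
#' @export
phantomAtlas <- function(config) {
    anat <- .phantomAnatomy(config)
    aff <- spacingAffine(c(1, 1, 1))
    template <- volume(anat$ideal, affine = aff, role = "intensity")
    stem <- binaryMask(array(anat$labels %in% c(4, 5), dim(anat$labels)),
                       affine = aff)
    stem <- dilateMask(stem, ballElement(1))
    new("BrainStemAtlas", template = template, stemMask = stem)
}

#' Write a phantom case to a directory
#'
#' Writes `t1.nii.gz`, `labels.nii.gz`, `pve_csf/gm/wm.nii.gz`,
#' `bias.nii.gz` and a `phantom.yaml` sidecar holding the configuration,
#' seed and pose.
#'
#' @param case a [PhantomCase-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
writePhantomCase <- function(case, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeVolume(case@t1, file.path(dir, "t1.nii.gz"))
    writeVolume(case@labels, file.path(dir, "labels.nii.gz"))
    writeVolume(case@pve@csf, file.path(dir, "pve_csf.nii.gz"))
    writeVolume(case@pve@gm, file.path(dir, "pve_gm.nii.gz"))
    writeVolume(case@pve@wm, file.path(dir, "pve_wm.nii.gz"))
    writeVolume(case@bias, file.path(dir, "bias.nii.gz"))
    cfg <- case@config
    yaml::write_yaml(list(
        grid_shape = as.integer(cfg@gridShape),
        tissue_means = as.list(cfg@tissueMeans),
        noise_sigma = cfg@noiseSigma,
        bias_amplitude = cfg@biasAmplitude,
        csf_sheet_thickness = cfg@csfSheetThickness,
        peduncle_radius = cfg@peduncleRadius,
        seed = cfg@seed,
        pose = as.vector(t(case@pose))), file.path(dir, "phantom.yaml"))
    invisible(dir)
}

#' Read a phantom case written by [writePhantomCase()]
#'
#' @param dir directory containing the phantom files.
#' @return A [PhantomCase-class].
#' @export
readPhantomCase <- function(dir) {
    y <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
    cfg <- phantomConfig(gridShape = y$grid_shape,
                         tissueMeans = unlist(y$tissue_means),
                         noiseSigma = y$noise_sigma,
                         biasAmplitude = y$bias_amplitude,
                         csfSheetThickness = y$csf_sheet_thickness,
                         peduncleRadius = y$peduncle_radius, seed = y$seed)
    new("PhantomCase",
        t1 = readVolume(file.path(dir, "t1.nii.gz")),
        labels = readVolume(file.path(dir, "labels.nii.gz"), role = "label"),
        pve = new("PVEMaps",
                  csf = readVolume(file.path(dir, "pve_csf.nii.gz"), "fraction"),
                  gm = readVolume(file.path(dir, "pve_gm.nii.gz"), "fraction"),
                  wm = readVolume(file.path(dir, "pve_wm.nii.gz"), "fraction")),
        bias = readVolume(file.path(dir, "bias.nii.gz"), role = "bias"),
        config = cfg, pose = matrix(unlist(y$pose), 4, 4, byrow = TRUE))
}

setMethod("show", "PhantomCase", function(object) {
    tab <- table(factor(object@labels@data, levels = 0:7,
                        labels = names(phantomLabels())))
    cat(sprintf("PhantomCase %s, seed %d, noise sd %.3g, bias %.3g\n",
                paste(dim(object@t1@data), collapse = "x"),
                object@config@seed, object@config@noiseSigma,
                object@config@biasAmplitude))
    print(tab)
})
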