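test_that("phantom generation is deterministic and respects the noiseless limit", {
    cfg <- phantomConfig(gridShape = 48, noiseSigma = 2, biasAmplitude = 0.1,
                         seed = 9)
    a <- generatePhantom(cfg)
    b <- generatePhantom(cfg)
    expect_identical(imgData(a@t1), imgData(b@t1))
    expect_identical(imgData(a@labels), imgData(b@labels))

    nl <- testCase(48)          # noiseless, bias-free
    tm <- nl@config@tissueMeans
    L <- imgData(nl@labels)
    ## "pure" = a full 26-neighbourhood of fully-one-fraction voxels, which
    ## rules out any subvoxel background intrusion
    pureOf <- function(lab, frac)
        imgData(erodeMask(binaryMask(array(L == lab & imgData(frac) == 1,
                                           dim(L))), cubeSE()))
    pureGm <- pureOf(2, nl@pve@gm)
    expect_gt(sum(pureGm), 0)
    expect_true(all(imgData(nl@t1)[pureGm] == tm["gm"]))
    pureCsf <- pureOf(7, nl@pve@csf)
    expect_gt(sum(pureCsf), 0)
    expect_true(all(imgData(nl@t1)[pureCsf] == tm["csf"]))
    ## sinus intensity sits within 10% of the GM mean (the stated confound)
    expect_lt(abs(tm["sinus"] - tm["gm"]) / tm["gm"], 0.10)
})

test_that("phantom anatomy satisfies its structural invariants", {
    case <- testCase(128, 0, 0, 42)
    L <- imgData(case@labels)
    ## plausible cerebellar volume fraction
    frac <- sum(L %in% 2:3) / sum(L > 0)
    expect_gte(frac, 0.08)
    expect_lte(frac, 0.20)

    ## fractions are a partition of unity on brain voxels, zero outside
    s <- imgData(case@pve@csf) + imgData(case@pve@gm) + imgData(case@pve@wm)
    expect_true(all(abs(s[L > 0] - 1) <= 1e-6))
    expect_true(all(s[L == 0] == 0))

    ## sinus and cerebellum separated by >= sheet thickness of CSF label
    sheet <- case@config@csfSheetThickness
    grown <- dilateMask(cerebellumMask(case), ballElement(ceiling(sheet)))
    expect_equal(sum(imgData(grown) & imgData(sinusMask(case))), 0L)

    ## excluding CSF (and the cerebral region the pipeline subtracts
    ## anyway), the sinus is disconnected from the cerebellum
    tissue <- binaryMask(array(L > 0 & L != 7 &
                               !imgData(cerebralMask(case)), dim(L)))
    cc <- connectedComponents(tissue, 26L)
    sinComp <- unique(cc$labels[imgData(sinusMask(case))])
    cerComp <- unique(cc$labels[imgData(cerebellumMask(case))])
    expect_length(intersect(sinComp, cerComp), 0L)

    ## the peduncle bridges brain stem and cerebellum into one 26-component
    bridge <- binaryMask(array(L %in% 2:5, dim(L)))
    expect_equal(length(connectedComponents(bridge, 26L)$sizes), 1L)

    expect_error(phantomConfig(gridShape = 32), ">= 48")
})

test_that("bias fields are smooth, centred and amplitude-bounded", {
    v <- volume(array(100, c(48, 48, 48)))
    out <- applyBiasField(v, 0, seed = 1)
    expect_identical(imgData(out$volume), imgData(v))
    expect_true(all(imgData(out$bias) == 1))

    out2 <- applyBiasField(v, 0.2, seed = 4)
    expect_gte(min(imgData(out2$volume)), 80)
    expect_lte(max(imgData(out2$volume)), 120)
    b <- imgData(out2$bias)
    expect_lt(abs(mean(b) - 1), 1e-9)
    expect_lte(max(abs(b - 1)), 0.2 + 1e-12)

    ## at the working 128^3 resolution the per-voxel gradient stays below
    ## 1% of the mean level
    b128 <- imgData(applyBiasField(volume(array(100, c(128, 128, 128))),
                                   0.2, seed = 4)$bias)
    n <- 128
    g <- max(abs(b128[-1, , ] - b128[-n, , ]),
             abs(b128[, -1, ] - b128[, -n, ]),
             abs(b128[, , -1] - b128[, , -n]))
    expect_lt(g, 0.01)

    expect_error(applyBiasField(v, -0.1), "amplitude")
})

test_that("additive noise has the requested statistics and seed behaviour", {
    z <- volume(array(0, c(64, 64, 64)))
    expect_identical(imgData(addNoise(z, 0, seed = 1)), imgData(z))
    n5 <- addNoise(z, 5, seed = 2)
    expect_gte(sd(imgData(n5)), 4.75)
    expect_lte(sd(imgData(n5)), 5.25)
    expect_false(identical(imgData(n5), imgData(addNoise(z, 5, seed = 3))))
    expect_identical(imgData(n5), imgData(addNoise(z, 5, seed = 2)))
    expect_error(addNoise(z, -1), "nonnegative")
})

test_that("pose perturbation resamples all fields consistently", {
    case <- testCase(48)
    idt <- perturbPose(case)
    expect_identical(imgData(idt@labels), imgData(case@labels))

    tr <- perturbPose(case, translation = c(3, -2, 1))  # integer lattice shift
    expect_identical(unname(table(imgData(tr@labels))[-1]),
                     unname(table(imgData(case@labels))[-1]))

    rot <- perturbPose(case, rotation = c(10, 0, 0))
    n0 <- voxelCount(cerebellumMask(case))
    expect_lt(abs(voxelCount(cerebellumMask(rot)) - n0) / n0, 0.03)
    ## fractions remain a valid partition after nearest resampling
    s <- imgData(rot@pve@csf) + imgData(rot@pve@gm) + imgData(rot@pve@wm)
    expect_true(all(s < 1e-6 | abs(s - 1) < 1e-4))

    expect_error(perturbPose(case, rotation = c(40, 0, 0)), "30")
    expect_error(perturbPose(case, scale = 0.5), "scale")
})

test_that("phantom cases round-trip through their directory layout", {
    case <- testCase(48)
    dir <- file.path(tempdir(), "phantom-rt")
    writePhantomCase(case, dir)
    expect_setequal(dir(dir), c("t1.nii.gz", "labels.nii.gz", "pve_csf.nii.gz",
                                "pve_gm.nii.gz", "pve_wm.nii.gz", "bias.nii.gz",
                                "phantom.yaml"))
    back <- readPhantomCase(dir)
    expect_identical(imgData(back@labels), imgData(case@labels))
    expect_lt(max(abs(imgData(back@t1) - imgData(case@t1))), 1e-6)
    expect_equal(back@config@seed, case@config@seed)
    unlink(dir, recursive = TRUE)
})
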