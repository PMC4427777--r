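test_that("bias correction is inert on clean input and invertible", {
    v <- volume(array(100, c(20, 20, 20)))
    b <- binaryMask(array(TRUE, c(20, 20, 20)))
    out <- correctInhomogeneity(v, b)
    expect_lt(max(abs(imgData(out$volume) - imgData(v))) / 100, 1e-6)

    case <- testCase(64, 0, 0.2, 3)
    br <- brainMask(case)
    cc <- correctInhomogeneity(case@t1, br)
    ## output times estimated bias reproduces the input exactly
    recon <- imgData(cc$volume) * imgData(cc$bias)
    expect_lt(max(abs(recon - imgData(case@t1))), 1e-8)
    ## mean brain intensity preserved
    idx <- imgData(br)
    expect_lt(abs(mean(imgData(cc$volume)[idx]) / mean(imgData(case@t1)[idx]) - 1),
              0.01)

    expect_error(correctInhomogeneity(case@t1, br, polyOrder = 0), "\\[1, 4\\]")
    neg <- volume(imgData(case@t1) - 500, affine = affine(case@t1))
    expect_error(correctInhomogeneity(neg, br), "onpositive")
})

test_that("bias correction halves within-tissue variation under strong bias", {
    case <- testCase(64, 0, 0.2, 3)
    br <- brainMask(case)
    cc <- correctInhomogeneity(case@t1, br)
    ## pure cerebral GM spans the whole head, so the field varies across it
    interior <- imgData(erodeMask(br, ballElement(2)))
    gmv <- imgData(case@labels) == 1 & imgData(case@pve@gm) == 1 & interior
    cov0 <- sd(imgData(case@t1)[gmv]) / mean(imgData(case@t1)[gmv])
    cov1 <- sd(imgData(cc$volume)[gmv]) / mean(imgData(cc$volume)[gmv])
    expect_lte(cov1 / cov0, 0.5)
})

test_that("brain extraction produces one holeless component matching truth", {
    case <- testCase(64)
    bm <- extractBrainMask(case@t1)
    expect_gte(diceCoefficient(brainMask(case), bm), 0.95)
    expect_equal(length(connectedComponents(bm, 26L)$sizes), 1L)
    expect_identical(imgData(fillHoles(bm)), imgData(bm))
    expect_error(extractBrainMask(volume(array(1, c(8, 8, 8)))), "constant")
})

test_that("tissue classification recovers well-separated Gaussian classes", {
    set.seed(99)
    x <- c(rnorm(3000, 40, 5), rnorm(3000, 100, 5), rnorm(3000, 150, 5))
    v <- volume(array(x, c(30, 30, 10)))
    b <- binaryMask(array(TRUE, c(30, 30, 10)))
    tl <- classifyTissue(v, b)
    expect_gte(mean(imgData(tl)[seq_along(x)] == rep(1:3, each = 3000)), 0.99)
    expect_lt(max(abs(tl@classMeans - c(40, 100, 150))), 2)
    expect_true(all(diff(tl@classMeans) > 0))
    ## deterministic
    tl2 <- classifyTissue(v, b)
    expect_identical(imgData(tl), imgData(tl2))

    expect_error(classifyTissue(v, binaryMask(array(FALSE, c(30, 30, 10)))),
                 "100")
    flat <- volume(array(rep(c(1, 2), 500), c(10, 10, 10)))
    expect_error(classifyTissue(flat, binaryMask(array(TRUE, c(10, 10, 10)))),
                 "distinct")
})

test_that("classification recovers interior pure-label phantom voxels", {
    case <- testCase(64)
    br <- brainMask(case)
    tl <- classifyTissue(correctInhomogeneity(case@t1, br)$volume, br)
    L <- imgData(case@labels)
    interior <- imgData(erodeMask(br, ballElement(1)))
    pure <- interior & L > 0 &
        imgData(case@pve@csf) %in% c(0, 1) &
        imgData(case@pve@gm) %in% c(0, 1) &
        imgData(case@pve@wm) %in% c(0, 1)
    expected <- c(2, 2, 3, 3, 3, 2, 1)[L[pure]]   # label -> tissue class
    expect_gte(mean(imgData(tl)[pure] == expected), 0.99)
})

test_that("linear partial-volume estimation matches its closed form", {
    ## toy volume holding the interesting intensities
    y <- c(40, 100, 150, 70, 125, 20, 180, 95)
    v <- volume(array(rep(y, length.out = 1000), c(10, 10, 10)))
    lab <- new("TissueLabels",
               data = array(rep(2L, 1000), c(10, 10, 10)),
               affine = affine(v),
               classMeans = c(csf = 40, gm = 100, wm = 150),
               classSds = c(csf = 1, gm = 1, wm = 1))
    pve <- estimatePVE(v, lab)
    at <- function(m, i) imgData(m)[i]
    expect_equal(at(pve@gm, 2), 1)                      # exactly mu_GM
    expect_equal(at(pve@csf, 2), 0)
    expect_equal(at(pve@csf, 4), 0.5)                   # midpoint CSF/GM
    expect_equal(at(pve@gm, 4), 0.5)
    expect_equal(at(pve@gm, 5), 0.5)                    # midpoint GM/WM
    expect_equal(at(pve@wm, 5), 0.5)
    expect_equal(at(pve@csf, 6), 1)                     # below CSF mean
    expect_equal(at(pve@wm, 7), 1)                      # above WM mean
    s <- imgData(pve@csf) + imgData(pve@gm) + imgData(pve@wm)
    expect_true(all(abs(s - 1) < 1e-12))                # partition of unity

    bad <- lab
    bad@classMeans <- c(csf = 100, gm = 40, wm = 150)
    expect_error(estimatePVE(v, bad), "increasing")
})

test_that("phantom partial-volume estimates match ground truth at interfaces", {
    case <- testCase(64)
    br <- brainMask(case)
    corr <- correctInhomogeneity(case@t1, br)$volume
    pve <- estimatePVE(corr, classifyTissue(corr, br))
    interior <- imgData(erodeMask(br, ballElement(1)))
    iface <- interior & imgData(case@pve@gm) > 0.02 & imgData(case@pve@gm) < 0.98
    for (m in c("csf", "gm", "wm")) {
        err <- mean(abs(imgData(slot(pve, m))[iface] -
                        imgData(slot(case@pve, m))[iface]))
        expect_lte(err, 0.05)
    }
})

test_that("mixture fit agrees with an independent reference implementation", {
    suppressMessages(library(mclust))
    set.seed(5)
    x <- c(rnorm(2000, 40, 4), rnorm(2000, 100, 4), rnorm(2000, 150, 4))
    v <- volume(array(x, c(20, 20, 15)))
    b <- binaryMask(array(TRUE, c(20, 20, 15)))
    tl <- classifyTissue(v, b)
    mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
    expect_lt(max(abs(sort(mc$parameters$mean) - tl@classMeans)), 1)
})
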