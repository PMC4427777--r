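test_that("ball structuring elements enumerate integer offsets within radius", {
    expect_equal(nrow(ballElement(0)@offsets), 1L)
    expect_equal(nrow(ballElement(1)@offsets), 7L)
    expect_equal(nrow(ballElement(2)@offsets), 33L)
    expect_error(ballElement(-1), "nonnegative")
    ## symmetry and origin are enforced by the class
    se <- ballElement(3)
    expect_true(validObject(se))
})

test_that("erosion and dilation follow the definitional contracts", {
    se <- ballElement(1)
    single <- binaryMask(array(FALSE, c(5, 5, 5)))
    single@data[3, 3, 3] <- TRUE
    expect_equal(voxelCount(erodeMask(single, se)), 0L)
    expect_equal(voxelCount(dilateMask(single, se)), 7L)

    full <- binaryMask(array(TRUE, c(5, 5, 5)))
    er <- erodeMask(full, se)
    expect_equal(voxelCount(er), 27L)          # 3^3 interior block
    expect_true(all(which(imgData(er), arr.ind = TRUE) >= 2))

    empty <- binaryMask(array(FALSE, c(5, 5, 5)))
    expect_equal(voxelCount(dilateMask(empty, se)), 0L)
})

test_that("operators agree with brute-force oracles on random masks", {
    set.seed(42)
    for (dens in c(0.1, 0.5, 0.9)) {
        for (i in 1:8) {
            m <- randomMask(density = dens)
            for (r in 1:2) {
                se <- ballElement(r)
                expect_identical(imgData(erodeMask(m, se)),
                                 oracleErode(imgData(m), se@offsets))
                expect_identical(imgData(dilateMask(m, se)),
                                 oracleDilate(imgData(m), se@offsets))
            }
            for (conn in c(6L, 18L, 26L)) {
                oc <- oracleComponents(imgData(m), conn)
                cc <- connectedComponents(m, conn)
                expect_identical(cc$labels, oc$labels)
                expect_identical(unname(cc$sizes), unname(oc$sizes))
            }
        }
    }
})

test_that("erosion is anti-extensive, dilation extensive, both monotone", {
    set.seed(7)
    se <- ballElement(1)
    for (i in 1:10) {
        x <- randomMask(density = 0.5)
        y <- binaryMask(imgData(x) | (array(runif(16^3), c(16, 16, 16)) < 0.2))
        expect_true(all(imgData(erodeMask(x, se)) <= imgData(x)))
        expect_true(all(imgData(x) <= imgData(dilateMask(x, se))))
        expect_true(all(imgData(erodeMask(x, se)) <= imgData(erodeMask(y, se))))
        expect_true(all(imgData(dilateMask(x, se)) <= imgData(dilateMask(y, se))))
    }
})

test_that("dilation is the dual of erosion on the complement (padded interior)", {
    set.seed(13)
    se <- ballElement(1)
    for (i in 1:10) {
        ## pad so no foreground touches the border (duality needs it:
        ## outside the grid counts as background for both operators)
        inner <- array(runif(10^3) < 0.5, c(10, 10, 10))
        a <- array(FALSE, c(16, 16, 16))
        a[4:13, 4:13, 4:13] <- inner
        m <- binaryMask(a)
        dual <- !imgData(erodeMask(binaryMask(!a), se))
        dual[c(1:2, 15:16), , ] <- FALSE
        dual[, c(1:2, 15:16), ] <- FALSE
        dual[, , c(1:2, 15:16)] <- FALSE
        expect_identical(imgData(dilateMask(m, se)), dual)
    }
})

test_that("opening removes thin noise, preserves thick shapes, is idempotent", {
    se <- ballElement(1)
    a <- array(FALSE, c(11, 11, 11))
    a[2, 2, 2] <- TRUE                         # isolated voxel
    a[3:9, 3:9, 3:9] <- TRUE                   # solid 7^3 cube
    m <- binaryMask(a)
    op <- openMask(m, se)
    expect_false(imgData(op)[2, 2, 2])
    ## the ball-1 opening preserves the cube faces and interior but rounds
    ## its edges and corners (voxels with two or more extreme coordinates
    ## lie in no ball-1 translate contained in the cube): 12*5 + 8 = 68
    kept <- imgData(op)
    idx <- which(a, arr.ind = TRUE)
    idx <- idx[idx[, 1] >= 3, , drop = FALSE]         # cube voxels only
    nExtreme <- rowSums(idx == 3) + rowSums(idx == 9)
    inOpen <- kept[idx]
    expect_true(all(inOpen[nExtreme <= 1]))           # faces and interior kept
    expect_true(all(!inOpen[nExtreme >= 2]))          # edges and corners lost
    expect_equal(sum(nExtreme >= 2), 68L)
    set.seed(3)
    for (i in 1:10) {
        x <- randomMask(density = 0.5)
        o1 <- openMask(x, se)
        expect_true(all(imgData(o1) <= imgData(x)))
        expect_identical(imgData(openMask(o1, se)), imgData(o1))
    }
})

test_that("component labelling orders by size with raster tie-breaks", {
    a <- array(FALSE, c(12, 8, 8))
    a[1:2, 1:2, 1:2] <- TRUE                   # 8 voxels
    a[5:9, 1:4, 1:5] <- TRUE                   # 100 voxels
    cc <- connectedComponents(binaryMask(a), 26L)
    expect_equal(unname(cc$sizes), c(100L, 8L))
    expect_true(all(cc$labels[5:9, 1:4, 1:5] == 1L))
    big <- largestComponent(binaryMask(a), 26L)
    expect_equal(voxelCount(big), 100L)

    ## equal sizes: the component containing the smallest raster index wins
    b <- array(FALSE, c(10, 4, 4))
    b[8:9, 1:2, 1:2] <- TRUE
    b[1:2, 1:2, 1:2] <- TRUE
    cc2 <- connectedComponents(binaryMask(b), 26L)
    expect_equal(cc2$labels[1, 1, 1], 1L)
    expect_equal(cc2$labels[8, 1, 1], 2L)

    expect_equal(length(connectedComponents(binaryMask(array(FALSE, c(4, 4, 4))))$sizes), 0L)
    expect_error(largestComponent(binaryMask(array(FALSE, c(4, 4, 4)))), "empty")
    expect_error(connectedComponents(randomMask(), 13), "connectivity")

    set.seed(5)
    for (i in 1:5) {
        m <- randomMask(density = 0.3)
        cc <- connectedComponents(m)
        expect_equal(sum(cc$sizes), voxelCount(m))  # partition of foreground
    }
})

test_that("single components and hole filling behave", {
    a <- array(FALSE, c(9, 9, 9))
    a[2:8, 2:8, 2:8] <- TRUE
    a[4:6, 4:6, 4:6] <- FALSE                  # internal cavity
    filled <- fillHoles(binaryMask(a))
    expect_true(all(imgData(filled)[2:8, 2:8, 2:8]))
    m <- binaryMask(a)
    expect_identical(imgData(largestComponent(m)), imgData(m))  # single comp
})
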