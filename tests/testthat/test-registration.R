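test_that("transform helpers compose, invert and serialise", {
    m <- diag(4); m[1:3, 4] <- c(2, -1, 3); m[1, 1] <- 1.1
    xf <- affineTransform(m)
    expect_lt(max(abs(composeTransforms(xf, invertTransform(xf))@matrix -
                      diag(4))), 1e-10)
    f <- tempfile(fileext = ".txt")
    writeTransform(xf, f)
    expect_equal(readTransform(f)@matrix, m)
    bad <- diag(4); bad[1:3, 1:3] <- 0.1 * diag(3)  # det far below bound
    expect_error(affineTransform(bad), "determinant")
})

test_that("self-registration recovers the identity", {
    case <- testCase(64)
    xf <- registerAffine(case@t1, case@t1)
    expect_lt(max(abs(xf@matrix[1:3, 4] +
                      (xf@matrix[1:3, 1:3] - diag(3)) %*%
                      voxelToWorld(affine(case@t1), c(31.5, 31.5, 31.5))[1, ])),
              0.1)                                   # net translation < 0.1 mm
    ang <- acos(pmin(1, (sum(diag(xf@matrix[1:3, 1:3] %*%
                                  solve(t(chol(crossprod(xf@matrix[1:3, 1:3]))))))
                         - 1) / 2)) * 180 / pi
    expect_lt(ang, 0.2)                              # rotation < 0.2 degrees
})

test_that("known pose perturbations are recovered", {
    case <- testCase(64)
    pert <- perturbPose(case, translation = c(5, -3, 2))
    xf <- registerAffine(case@t1, pert@t1)
    centre <- voxelToWorld(affine(case@t1), (dim(imgData(case@t1)) - 1) / 2)[1, ]
    netT <- xf@matrix[1:3, 4] + (xf@matrix[1:3, 1:3] - diag(3)) %*% centre
    expect_true(all(abs(netT - c(5, -3, 2)) < 0.5))

    pert2 <- perturbPose(case, translation = c(4, 2, -3),
                         rotation = c(10, 0, 0), scale = 1.1)
    xf2 <- registerAffine(case@t1, pert2@t1)
    cen <- colMeans(which(imgData(cerebellumMask(case)), arr.ind = TRUE) - 1)
    cenP <- colMeans(which(imgData(cerebellumMask(pert2)), arr.ind = TRUE) - 1)
    pred <- (xf2@matrix %*% c(voxelToWorld(affine(case@t1), cen)[1, ], 1))[1:3]
    err <- sqrt(sum((pred - voxelToWorld(affine(case@t1), cenP)[1, ])^2))
    expect_lte(err, 1)                               # <= 1 voxel at 1 mm

    expect_error(registerAffine(volume(array(1, c(8, 8, 8))), case@t1),
                 "nonconstant")
})

test_that("transform composition transfers centroids consistently", {
    case <- testCase(64)
    b <- perturbPose(case, translation = c(3, 1, -2))
    c2 <- perturbPose(case, translation = c(6, -2, 1))
    ab <- registerAffine(case@t1, b@t1)
    bc <- registerAffine(b@t1, c2@t1)
    ac <- registerAffine(case@t1, c2@t1)
    comp <- composeTransforms(bc, ab)
    cen <- c(voxelToWorld(affine(case@t1),
                          colMeans(which(imgData(cerebellumMask(case)),
                                         arr.ind = TRUE) - 1))[1, ], 1)
    direct <- (ac@matrix %*% cen)[1:3]
    composed <- (comp@matrix %*% cen)[1:3]
    single <- sqrt(sum(((ab@matrix %*% cen)[1:3] -
                        c(voxelToWorld(affine(case@t1),
                                       colMeans(which(imgData(cerebellumMask(b)),
                                                      arr.ind = TRUE) - 1))[1, ]))^2))
    expect_lte(sqrt(sum((direct - composed)^2)), 2 * max(single, 0.5))
})

test_that("mask warping is nearest-neighbour exact on lattice shifts", {
    case <- testCase(48)
    m <- stemPeduncleMask(case)
    idt <- applyTransform(m, affineTransform(diag(4)), case@t1)
    expect_identical(imgData(idt), imgData(m))

    t3 <- diag(4); t3[1:3, 4] <- c(2, 1, -3)
    shifted <- applyTransform(m, affineTransform(t3), case@t1)
    expect_equal(voxelCount(shifted), voxelCount(m))   # interior mask
    expect_true(all(imgData(shifted) %in% c(TRUE, FALSE)))

    ## rotated warp keeps the count within the determinant bound
    rot <- cerebseg:::.paramsToMatrix(c(0, 0, 0), c(10, 0, 0), c(1, 1, 1),
                                      voxelToWorld(affine(case@t1),
                                                   c(23.5, 23.5, 23.5))[1, ])
    warped <- applyTransform(m, affineTransform(rot), case@t1)
    expect_lt(abs(voxelCount(warped) - voxelCount(m)) / voxelCount(m), 0.1)

    sing <- diag(4); sing[1, 1] <- 0
    expect_error(affineTransform(sing), "determinant")
})

test_that("atlas alignment covers the true brain stem and peduncle", {
    case <- testCase(64)
    atlas <- testAtlas(64)
    self <- alignAtlas(atlas, atlas@template)
    expect_gte(diceCoefficient(atlas@stemMask, self), 0.98)

    warped <- alignAtlas(atlas, case@t1)
    truth <- stemPeduncleMask(case)
    expect_gte(sum(imgData(warped) & imgData(truth)) / voxelCount(truth), 0.9)

    pert <- perturbPose(case, translation = c(4, -2, 3), rotation = c(5, 0, 0))
    warped2 <- alignAtlas(atlas, pert@t1)
    truth2 <- stemPeduncleMask(pert)
    expect_gte(sum(imgData(warped2) & imgData(truth2)) / voxelCount(truth2), 0.9)
})
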