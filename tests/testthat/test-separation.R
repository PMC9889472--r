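test_that("voxel decomposition solves the nonnegative two-component fit", {
    c0 <- defaultCoefficient()

    # pure water and pure fat are recovered exactly
    wf <- voxelDecompose(c(1 + 0i, c0), c0)
    expect_equal(wf$water, c(1, 0), tolerance = 1e-14)
    expect_equal(wf$fat, c(0, 1), tolerance = 1e-14)

    # interior solutions reproduce any in-cone signal exactly
    set.seed(3)
    W <- runif(50, 0, 2); F <- runif(50, 0, 2)
    s <- W + c0 * F
    wf <- voxelDecompose(s, c0)
    expect_equal(wf$water, W, tolerance = 1e-12)
    expect_equal(wf$fat, F, tolerance = 1e-12)

    # out-of-cone signals land on the better boundary, never negative
    sOut <- c(1i, -1, 2 * Conj(c0))
    wf <- voxelDecompose(sOut, c0)
    expect_true(all(wf$water >= 0) && all(wf$fat >= 0))
    expect_true(all(wf$water * wf$fat == 0))    # boundary: one component zero

    # degenerate coefficient (TE = 0 makes c real) is refused
    cReal <- fatCoefficient(fatSpectrum(), acquisitionParams(echoTime = 1e-15))
    expect_error(voxelDecompose(1 + 0i, cReal), "degenerate")
})

test_that("voxel decomposition matches the brute-force grid oracle", {
    c0 <- defaultCoefficient()
    set.seed(1)
    n <- 200
    W <- runif(n, 0, 1.2); F <- runif(n, 0, 1.2)
    s <- W + c0 * F + complex(real = rnorm(n, sd = 0.02),
                              imaginary = rnorm(n, sd = 0.02))
    wf <- voxelDecompose(s, c0)
    residPkg <- Mod(s - (wf$water + c0 * wf$fat))^2
    oracle <- bruteForceDecompose(s, c0, step = 1e-3, upper = 2)
    # continuum optimum can only be at or below the grid optimum, and the
    # gap is bounded by the Lipschitz bound at the grid resolution
    expect_true(all(residPkg <= oracle[, "resid"] + 1e-12))
    expect_lt(max(oracle[, "resid"] - residPkg), 2e-4)
})

test_that("smooth-phase estimation recovers an in-span phase exactly", {
    spec <- smallPhantomSpec(corticalPhaseOffset = 0)
    ph <- generatePhantom(spec)
    tr <- ph$truth
    c0 <- defaultCoefficient()
    cfg <- solverConfig(basisOrder = 2L)

    # exact (W, F) given, order-2 truth, order-2 basis: exact recovery on mask
    phi <- estimateSmoothPhase(ph$volume, waterMap(tr), fatMap(tr), c0, cfg)
    mag <- Mod(imageData(ph$volume))
    mask <- mag >= quantile(mag[mag > 0], 0.05)
    expect_lt(max(abs((phi - tr@phaseBackground)[mask])), 1e-6)

    # zero-phase input gives a zero map
    spec0 <- smallPhantomSpec(corticalPhaseOffset = 0,
                              backgroundPhaseCoeffs = rep(0, 10))
    ph0 <- generatePhantom(spec0)
    phi0 <- estimateSmoothPhase(ph0$volume, waterMap(ph0$truth),
                                fatMap(ph0$truth), c0, cfg)
    expect_lt(max(abs(phi0)), 1e-10)

    # adding a constant to the true phase shifts the estimate by it
    gamma <- 0.3
    volShift <- complexVolume(imageData(ph$volume) * exp(1i * gamma),
                              voxelSize = c(1, 1, 3))
    phiShift <- estimateSmoothPhase(volShift, waterMap(tr), fatMap(tr), c0, cfg)
    expect_lt(max(abs((phiShift - phi - gamma)[mask])), 1e-8)

    # an all-zero volume has no usable signal
    z <- complexVolume(array(0 + 0i, c(8, 8, 8)))
    expect_error(estimateSmoothPhase(z, array(0, c(8, 8, 8)),
                                     array(0, c(8, 8, 8)), c0, cfg),
                 "no-signal")
})

test_that("separation inverts its own forward model at machine precision", {
    c0 <- defaultCoefficient()
    spec <- smallPhantomSpec(corticalPhaseOffset = 0,
                             backgroundPhaseCoeffs = rep(0, 10))
    ph <- generatePhantom(spec)   # exactly forward model with phi = 0
    res <- separate(ph$volume)
    expect_lt(res@finalCost, 1e-10 * sum(Mod(imageData(ph$volume))^2))
    nz <- (waterMap(ph$truth) + fatMap(ph$truth)) > 0
    expect_lt(max(abs((waterMap(res) - waterMap(ph$truth))[nz])), 1e-10)
    expect_lt(max(abs((fatMap(res) - fatMap(ph$truth))[nz])), 1e-10)
})

test_that("separation is equivariant under global intensity scaling", {
    ph <- generatePhantom(smallPhantomSpec(snr = 60, seed = 5))
    res1 <- separate(ph$volume)
    k <- 7.3
    res2 <- separate(complexVolume(imageData(ph$volume) * k,
                                   voxelSize = c(1, 1, 3)))
    expect_equal(waterMap(res2), k * waterMap(res1), tolerance = 1e-8)
    expect_equal(fatMap(res2), k * fatMap(res1), tolerance = 1e-8)
    expect_equal(fatFraction(res2), fatFraction(res1), tolerance = 1e-8)
    expect_equal(correctedPhase(res2), correctedPhase(res1), tolerance = 1e-8)
})

test_that("solver output respects its contracts on noisy input", {
    ph <- generatePhantom(smallPhantomSpec(snr = 20, seed = 9))
    res <- separate(ph$volume)
    expect_true(all(waterMap(res) >= 0))
    expect_true(all(fatMap(res) >= 0))
    expect_true(all(fatFraction(res) >= 0 & fatFraction(res) <= 1))
    expect_true(all(correctedPhase(res) > -pi - 1e-12 &
                    correctedPhase(res) <= pi + 1e-12))
    expect_true(all(diff(costTrace(res)) <= 1e-9 * costTrace(res)[1]))

    # exhausting the iteration budget warns and still returns a result
    expect_warning(
        resShort <- separate(ph$volume,
                             config = solverConfig(maxIterations = 1L,
                                                   tolerance = 1e-16)),
        "did not converge")
    expect_s4_class(resShort, "WaterFatResult")
    expect_false(converged(resShort))
})

test_that("the Gaussian low-pass phase basis improves on no correction", {
    spec <- smallPhantomSpec(corticalPhaseOffset = 0)
    ph <- generatePhantom(spec)
    c0 <- defaultCoefficient()
    cfg <- solverConfig(phaseBasis = "gaussian_lowpass", lowpassSigma = 8,
                        maxIterations = 30L)
    res <- suppressWarnings(separate(ph$volume, config = cfg))
    marrow <- tissueLabels(ph$truth) == labelCodes(ph$truth)[["marrow"]]
    errGauss <- mean(abs(fatFraction(res)[marrow] - 0.6))

    # baseline: decompose the raw signal without any phase removal
    raw <- voxelDecompose(imageData(ph$volume), c0)
    ffRaw <- raw$fat / pmax(raw$water + raw$fat, 1e-300)
    errRaw <- mean(abs(ffRaw[marrow] - 0.6))

    # kernel smoothing is a biased estimator of a curved phase field, so
    # the lowpass basis is approximate -- but it must clearly beat an
    # uncorrected decomposition and keep the cost monotone
    expect_lt(errGauss, 0.5 * errRaw)
    expect_true(all(diff(costTrace(res)) <= 1e-9 * costTrace(res)[1]))
})
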