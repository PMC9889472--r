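test_that("fat coefficient follows the multi-peak phasor formula", {
    acq <- acquisitionParams()

    # zero echo time: no chemical-shift evolution
    expect_equal(fatCoefficient(fatSpectrum(), acquisitionParams(echoTime = 1e-12)),
                 1 + 0i, tolerance = 1e-8)

    # single peak at -3.4 ppm, 3 T, TE 0.14 ms: frozen direct evaluation of
    # theta = 2*pi * (-3.4e-6 * gammabar * 3) * 1.4e-4
    thetaExpected <- -0.382021679018125
    c0 <- fatCoefficient(fatSpectrum(), acq)
    expect_equal(Arg(c0), thetaExpected, tolerance = 1e-12)
    expect_equal(Mod(c0), 1, tolerance = 1e-14)

    # equal-amplitude peaks at opposite shifts give a real coefficient
    sym <- fatSpectrum(c(-2.0, 2.0), c(0.5, 0.5))
    expect_lt(abs(Im(fatCoefficient(sym, acq))), 1e-14)

    # |c| <= 1, strictly below 1 for misaligned multi-peak spectra
    multi <- fatSpectrum(c(-3.4, -2.6, 0.6), c(0.7, 0.2, 0.1))
    expect_lt(Mod(fatCoefficient(multi, acq)), 1)

    # continuity in TE near the default echo
    te <- 0.14e-3
    c1 <- fatCoefficient(fatSpectrum(), acquisitionParams(echoTime = te * (1 + 1e-9)))
    expect_lt(Mod(c1 - c0), 1e-6)
})

test_that("spectrum and acquisition validity is enforced", {
    expect_error(fatSpectrum(numeric(0)), "at least one peak")
    expect_error(fatSpectrum(-3.4, 0.9), "sum to 1")
    expect_error(fatSpectrum(c(-3.4, -2.6), c(1.2, -0.2)), "nonnegative")
    expect_error(acquisitionParams(echoTime = 0), "echoTime")
    expect_error(acquisitionParams(fieldStrength = -3), "fieldStrength")
})

test_that("forward signal evaluates (W + cF) e^{i phi} elementwise", {
    c0 <- defaultCoefficient()
    one <- array(1, c(2, 2, 2)); zero <- array(0, c(2, 2, 2))

    expect_equal(forwardSignal(one, zero, zero, c0)[1], 1 + 0i)
    expect_equal(forwardSignal(zero, one, zero, c0)[1], c0)
    expect_equal(forwardSignal(one, one, array(pi / 2, c(2, 2, 2)), c0)[1],
                 1i * (1 + c0), tolerance = 1e-15)

    expect_error(forwardSignal(one, array(0, c(2, 2, 1)), zero, c0), "dimension")
    expect_error(forwardSignal(-one, zero, zero, c0), "domain")
})

test_that("forward signal magnitude ignores phase and is linear in (W, F)", {
    c0 <- defaultCoefficient()
    set.seed(11)
    d <- c(4, 3, 2)
    W <- array(runif(prod(d)), d); F <- array(runif(prod(d)), d)
    p1 <- array(runif(prod(d), -pi, pi), d)
    p2 <- array(runif(prod(d), -pi, pi), d)
    expect_equal(Mod(forwardSignal(W, F, p1, c0)), Mod(forwardSignal(W, F, p2, c0)),
                 tolerance = 1e-14)
    # linearity at fixed phase
    s12 <- forwardSignal(2 * W, 3 * F, p1, c0)
    expect_equal(s12, 2 * forwardSignal(W, zero <- array(0, d), p1, c0) +
                     3 * forwardSignal(zero, F, p1, c0), tolerance = 1e-13)
})

test_that("complex volume validity rejects bad geometry and non-finite data", {
    good <- array(complex(real = 1, imaginary = 0), c(2, 2, 2))
    expect_s4_class(complexVolume(good), "ComplexVolume")
    expect_error(complexVolume(matrix(1 + 0i, 2, 2)), "3D")
    bad <- good; bad[1] <- NaN + 0i
    expect_error(complexVolume(bad), "finite")
    expect_error(complexVolume(good, voxelSize = c(1, 0, 1)), "voxelSize")
})
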