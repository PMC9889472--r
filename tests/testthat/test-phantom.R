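test_that("phantom truth maps reproduce the emitted volume exactly", {
    ph <- generatePhantom(smallPhantomSpec())   # noiseless default structure
    tr <- ph$truth
    c0 <- defaultCoefficient()
    rebuilt <- forwardSignal(waterMap(tr), fatMap(tr),
                             tr@phaseBackground + tr@phaseLocal, c0)
    expect_identical(rebuilt, imageData(ph$volume))

    # marrow fat fraction is exact in the truth maps
    marrow <- tissueLabels(tr) == labelCodes(tr)[["marrow"]]
    ffTrue <- fatMap(tr)[marrow] / (waterMap(tr) + fatMap(tr))[marrow]
    expect_true(all(abs(ffTrue - 0.6) < 1e-12))

    # edema marrow has the reduced fat fraction and raised total signal
    edema <- tissueLabels(tr) == labelCodes(tr)[["edema"]]
    expect_gt(sum(edema), 0)
    ffEd <- fatMap(tr)[edema] / (waterMap(tr) + fatMap(tr))[edema]
    expect_true(all(abs(ffEd - 0.25) < 1e-12))
    expect_gt(mean((waterMap(tr) + fatMap(tr))[edema]), 1)

    # every voxel carries exactly one declared label
    expect_true(all(as.vector(tissueLabels(tr)) %in% labelCodes(tr)))
})

test_that("phantom generation is bit-reproducible for a fixed spec and seed", {
    spec <- smallPhantomSpec(snr = 30, seed = 42L)
    a <- generatePhantom(spec)
    b <- generatePhantom(spec)
    expect_identical(imageData(a$volume), imageData(b$volume))
    expect_identical(waterMap(a$truth), waterMap(b$truth))

    # a different seed changes the noise
    c <- generatePhantom(smallPhantomSpec(snr = 30, seed = 43L))
    expect_false(identical(imageData(a$volume), imageData(c$volume)))

    # the generator leaves the global RNG stream untouched
    set.seed(7); before <- rnorm(3)
    set.seed(7); invisible(generatePhantom(spec)); after <- rnorm(3)
    expect_identical(before, after)
})

test_that("with no phase sources every voxel phase is the chemical angle", {
    spec <- smallPhantomSpec(corticalPhaseOffset = 0,
                             backgroundPhaseCoeffs = rep(0, 10))
    ph <- generatePhantom(spec)
    c0 <- defaultCoefficient()
    S <- imageData(ph$volume)
    tr <- ph$truth
    expected <- Arg(waterMap(tr) + c0 * fatMap(tr))
    nz <- Mod(S) > 0
    expect_equal(Arg(S)[nz], expected[nz], tolerance = 1e-12)
    # pure-water voxels (discs) sit at exactly zero phase
    disc <- tissueLabels(tr) == labelCodes(tr)[["disc"]]
    expect_true(all(Arg(S)[disc] == 0))
})

test_that("realised noise matches the requested SNR within 5% over 10 seeds", {
    snr <- 25
    ratios <- vapply(1:10, function(s) {
        clean <- generatePhantom(smallPhantomSpec(seed = s))
        noisy <- generatePhantom(smallPhantomSpec(snr = snr, seed = s))
        nse <- imageData(noisy$volume) - imageData(clean$volume)
        sdHat <- sd(c(Re(nse), Im(nse)))
        marrow <- tissueLabels(clean$truth) == labelCodes(clean$truth)[["marrow"]]
        mean(Mod(imageData(clean$volume))[marrow]) / sdHat
    }, 0)
    expect_lt(abs(mean(ratios) / snr - 1), 0.05)
})

test_that("phantom spec validity guards its parameter ranges", {
    expect_error(generatePhantom(smallPhantomSpec(edemaVertebraIndex = 9L)),
                 "out of range")
    expect_error(smallPhantomSpec(edemaFatFraction = 0.7),
                 "below 'marrowFatFraction'")
    expect_error(smallPhantomSpec(corticalPhaseOffset = 0.2), "<= 0")
    expect_error(smallPhantomSpec(marrowFatFraction = 1.3), "\\[0, 1\\]")
    # disabling edema removes the label and lifts the fat-fraction ordering
    ph <- generatePhantom(smallPhantomSpec(edemaVertebraIndex = NA))
    expect_equal(sum(tissueLabels(ph$truth) ==
                     labelCodes(ph$truth)[["edema"]]), 0)
})
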