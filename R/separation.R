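## Water-fat separation from a single complex UTE echo.
##
## Model: S(r) = (W(r) + c F(r)) e^{i phi(r)}, W, F >= 0, phi smooth.
## The solver alternates an exact per-voxel nonnegative decomposition at
## fixed phase with a weighted basis fit of the phase residual, under a
## backtracking safeguard that makes the cost non-increasing by
## construction.
##
## A structural property worth knowing: at fixed phase, any corrected
## signal whose phase lies inside the sector [Arg(c), 0] is fit *exactly*
## by some W, F >= 0, so the data cost is insensitive to smooth-phase
## perturbations that keep every voxel inside the sector.  Absolute phase
## information comes from cone-boundary voxels (pure water at phase 0,
## pure fat at Arg(c)); the magnitude-weighted init plus the iteration's
## one-sided clamp corrections resolve the water/fat labeling in practice.

## below this |Im(c)| the TE/spectrum cannot distinguish water from fat
.imagEps <- 1e-6

#' Construct solver settings
#'
#' Defaults: no explicit coefficient penalty (the low-frequency constraint
#' is the basis truncation itself), polynomial basis of total order 3,
#' at most 50 outer iterations, relative cost-change tolerance 1e-6, and a
#' magnitude mask at the 0.05 quantile of nonzero magnitudes (air voxels
#' carry pure noise phase and are excluded from phase fitting, but are
#' still decomposed).
#'
#' @param smoothnessWeight Ridge weight on the phase-basis coefficients.
#' @param maxIterations Maximum outer iterations.
#' @param tolerance Relative cost-change convergence threshold.
#' @param phaseBasis `"polynomial"` or `"gaussian_lowpass"`.
#' @param basisOrder Total polynomial order (polynomial basis).
#' @param lowpassSigma Gaussian sigma in mm (gaussian_lowpass basis).
#' @param maskQuantile Magnitude-mask quantile in [0, 1).
#' @return A [SolverConfig-class] object.
#' @export
solverConfig <- function(smoothnessWeight = 0, maxIterations = 50L,
                         tolerance = 1e-6, phaseBasis = "polynomial",
                         basisOrder = 3L, lowpassSigma = 25,
                         maskQuantile = 0.05) {
    new("SolverConfig",
        smoothnessWeight = as.numeric(smoothnessWeight),
        maxIterations = as.integer(maxIterations),
        tolerance = as.numeric(tolerance),
        phaseBasis = match.arg(phaseBasis, c("polynomial", "gaussian_lowpass")),
        basisOrder = as.integer(basisOrder),
        lowpassSigma = as.numeric(lowpassSigma),
        maskQuantile = as.numeric(maskQuantile))
}

#' Per-voxel nonnegative water-fat decomposition at fixed phase
#'
#' Solves, elementwise, \eqn{\min_{W \ge 0, F \ge 0} |s - (W + cF)|^2} for
#' a phase-corrected complex signal `s`.  The interior solution follows in
#' closed form from `Re(s) = W + Re(c) F`, `Im(s) = Im(c) F` (and fits `s`
#' exactly); when it violates a sign constraint, the better of the two
#' boundary solutions (`F = 0`, `W = max(Re(s), 0)`) and (`W = 0`, `F` the
#' clipped projection on the c-ray) is returned, by residual.
#'
#' @param s Complex vector or array of phase-corrected signals.
#' @param c Complex fat coefficient; `abs(Im(c))` must exceed 1e-6, i.e.
#'   water and fat must be phase-distinguishable at this TE.
#' @return A list with elements `water` and `fat`, shaped like `s`.
#' @examples
#' c0 <- fatCoefficient(fatSpectrum(), acquisitionParams())
#' voxelDecompose(c(1 + 0i, c0), c0)   # pure water, pure fat
#' @export
voxelDecompose <- function(s, c) {
    if (abs(Im(c)) < .imagEps)
        stop("degenerate coefficient: |Im(c)| < 1e-6; water and fat are not ",
             "phase-distinguishable -- use a different echo time or spectrum")
    d <- dim(s)
    s <- as.complex(s)
    F0 <- Im(s) / Im(c)
    W0 <- Re(s) - Re(c) * F0
    interior <- W0 >= 0 & F0 >= 0
    ## boundary candidates
    Wa <- pmax(Re(s), 0)
    residA <- Mod(s - Wa)^2
    Fb <- pmax(Re(s * Conj(c)), 0) / Mod(c)^2
    residB <- Mod(s - c * Fb)^2
    useA <- residA <= residB
    W <- ifelse(interior, W0, ifelse(useA, Wa, 0))
    F <- ifelse(interior, F0, ifelse(useA, 0, Fb))
    if (!is.null(d)) { dim(W) <- d; dim(F) <- d }
    list(water = W, fat = F)
}

## magnitude mask: TRUE where |S| >= quantile q of the nonzero magnitudes
magnitudeMask <- function(mag, q) {
    nz <- mag[mag > 0]
    if (length(nz) == 0L) stop("no-signal error: the volume magnitude is all zero")
    mag >= quantile(nz, q, names = FALSE)
}

## separable 3D Gaussian smoothing (matrix kernels per axis, zero padding)
gaussianSmooth3d <- function(arr, sigmaVox) {
    d <- dim(arr)
    kernelMat <- function(n, sigma) {
        if (sigma <= 0 || n == 1L) return(diag(n))
        K <- exp(-(outer(seq_len(n), seq_len(n), `-`))^2 / (2 * sigma^2))
        K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
        K
    }
    x <- matrix(arr, d[1L], d[2L] * d[3L])
    x <- kernelMat(d[1L], sigmaVox[1L]) %*% x
    arr <- array(x, d)
    arr <- aperm(arr, c(2, 1, 3))
    x <- matrix(arr, d[2L], d[1L] * d[3L])
    x <- kernelMat(d[2L], sigmaVox[2L]) %*% x
    arr <- aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
    arr <- aperm(arr, c(3, 2, 1))
    x <- matrix(arr, d[3L], d[2L] * d[1L])
    x <- kernelMat(d[3L], sigmaVox[3L]) %*% x
    aperm(array(x, d[c(3, 2, 1)]), c(3, 2, 1))
}

## weighted fit of a phase field onto the configured smooth basis;
## returns list(field, coeffs) (coeffs NULL for gaussian_lowpass)
fitSmoothField <- function(resid, wts, gridShape, config, voxelSize) {
    if (config@phaseBasis == "polynomial") {
        B <- polyBasisMatrix(gridShape, config@basisOrder)
        A <- crossprod(B, wts * B)
        lam <- config@smoothnessWeight
        if (lam > 0) A <- A + lam * diag(ncol(B))
        ## guard against rank deficiency when few voxels carry weight
        A <- A + 1e-12 * mean(diag(A)) * diag(ncol(B))
        theta <- solve(A, crossprod(B, wts * as.vector(resid)))
        list(field = array(B %*% theta, gridShape), coeffs = as.vector(theta))
    } else {
        sigmaVox <- config@lowpassSigma / voxelSize
        z <- gaussianSmooth3d(array(wts * exp(1i * as.vector(resid)), gridShape),
                              sigmaVox)
        list(field = Arg(z), coeffs = NULL)
    }
}

#' Estimate the smooth unwanted phase at fixed water/fat maps
#'
#' Fits the phase residual `Arg(S * exp(-i currentPhase) * Conj(W + cF))`
#' onto the configured smooth basis with magnitude-squared weights
#' (restricted to the magnitude mask), avoiding explicit unwrapping for
#' residuals inside (-pi, pi).  The returned map is `currentPhase` plus
#' the fitted field; with `currentPhase = NULL` it is the total smooth
#' phase estimate given `(water, fat)`.
#'
#' @param volume A [ComplexVolume-class].
#' @param water,fat Current component estimates (arrays matching the
#'   volume).
#' @param c Complex fat coefficient.
#' @param config A [SolverConfig-class].
#' @param currentPhase Optional current smooth-phase map the fit is
#'   anchored to.
#' @return A numeric phase array (radians).
#' @export
estimateSmoothPhase <- function(volume, water, fat, c, config = solverConfig(),
                                currentPhase = NULL) {
    stopifnot(is(volume, "ComplexVolume"), is(config, "SolverConfig"))
    S <- volume@data
    d <- dim(S)
    mag <- Mod(S)
    mask <- magnitudeMask(mag, config@maskQuantile)
    wts <- as.vector(mag^2 * mask)
    M <- water + c * fat
    phi0 <- if (is.null(currentPhase)) array(0, d) else currentPhase
    resid <- Arg(S * exp(-1i * phi0) * Conj(M))
    fit <- fitSmoothField(resid, wts, d, config, volume@voxelSize)
    phi0 + fit$field
}

#' Separate water and fat from a single complex UTE volume
#'
#' Block-coordinate minimisation of
#' \deqn{\sum_r w(r) \, |S(r) - (W(r) + c F(r)) e^{i\varphi(r)}|^2 +
#'       \lambda \|\theta\|^2,}
#' with \eqn{w(r) = |S(r)|^2} on the magnitude mask (0 off it), the smooth
#' phase \eqn{\varphi} confined to the configured basis with coefficients
#' \eqn{\theta}, and \eqn{W, F \ge 0}.  The phase is initialised by a
#' weighted basis fit of the raw phase (a near-solution start, since the
#' chemical-shift phase \eqn{|Arg(c)| \approx 0.38} rad at TE 0.14 ms,
#' 3 T, is small); iterations then alternate the exact per-voxel
#' decomposition with a basis fit of the remaining phase residual.  Each
#' phase step is backtracked (step halving) until the cost does not
#' increase, so the cost trace is non-increasing by construction.
#'
#' Off-mask voxels do not influence the phase fit or the cost but are
#' still decomposed.  If the estimated smooth phase spans more than
#' (-pi, pi], a wrap warning is emitted (large B0 excursions are flagged,
#' not silently handled).
#'
#' @param volume A [ComplexVolume-class].
#' @param spectrum A [FatSpectrum-class].
#' @param config A [SolverConfig-class].
#' @return A [WaterFatResult-class].  On non-convergence the result is
#'   returned with `converged = FALSE` and a warning, never an error.
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(32, 40, 8)))
#' res <- separate(ph$volume, config = solverConfig(maxIterations = 10))
#' res
#' @export
separate <- function(volume, spectrum = fatSpectrum(), config = solverConfig()) {
    stopifnot(is(volume, "ComplexVolume"), is(config, "SolverConfig"))
    validObject(config)
    cf <- fatCoefficient(spectrum, volume@acquisition)
    if (abs(Im(cf)) < .imagEps)
        stop("degenerate coefficient: |Im(c)| < 1e-6; water and fat are not ",
             "phase-distinguishable -- use a different echo time or spectrum")
    S <- volume@data
    d <- dim(S)
    mag <- Mod(S)
    mask <- magnitudeMask(mag, config@maskQuantile)
    wts <- as.vector(mag^2 * mask)
    lam <- config@smoothnessWeight
    poly <- config@phaseBasis == "polynomial"

    costOf <- function(phi, wf, theta) {
        dataTerm <- sum(wts * Mod(as.vector(S) -
            (as.vector(wf$water) + cf * as.vector(wf$fat)) *
            exp(1i * as.vector(phi)))^2)
        pen <- if (poly && lam > 0 && !is.null(theta)) lam * sum(theta^2) else 0
        dataTerm + pen
    }

    ## initialisation: basis fit of the raw phase, magnitude weighted
    init <- fitSmoothField(Arg(S), wts, d, config, volume@voxelSize)
    phi <- init$field
    theta <- init$coeffs
    wf <- voxelDecompose(S * exp(-1i * phi), cf)
    cost <- costOf(phi, wf, theta)
    trace <- cost
    convergedFlag <- FALSE
    it <- 0L

    for (it in seq_len(config@maxIterations)) {
        resid <- Arg(S * exp(-1i * phi) * Conj(wf$water + cf * wf$fat))
        ## Gauss-Newton-like step: voxels the decomposition fits exactly
        ## have zero residual AND zero resistance to smooth-phase change
        ## (the cost is locally flat there), so the phase correction is
        ## fitted over the active (clamped) voxels only.
        wFit <- wts * as.vector(abs(resid) > 1e-13)
        if (sum(wFit) == 0) { convergedFlag <- TRUE; it <- it - 1L; break }
        upd <- fitSmoothField(resid, wFit, d, config, volume@voxelSize)
        accepted <- FALSE
        for (t in c(1, 0.5, 0.25, 0.125, 0.0625)) {
            phiT <- phi + t * upd$field
            thetaT <- if (poly && !is.null(theta)) theta + t * upd$coeffs else NULL
            wfT <- voxelDecompose(S * exp(-1i * phiT), cf)
            costT <- costOf(phiT, wfT, thetaT)
            if (costT <= cost) { accepted <- TRUE; break }
        }
        if (!accepted) { convergedFlag <- TRUE; it <- it - 1L; break }
        relChange <- (cost - costT) / max(cost, .Machine$double.xmin)
        phi <- phiT; theta <- thetaT; wf <- wfT
        trace <- c(trace, costT)
        cost <- costT
        if (relChange < config@tolerance) { convergedFlag <- TRUE; break }
    }
    if (!convergedFlag)
        warning("separate() did not converge within ", config@maxIterations,
                " iterations; returning the last iterate")
    if (max(phi) > pi || min(phi) <= -pi)
        warning("estimated smooth phase exceeds (-pi, pi]: the background ",
                "phase may wrap across the volume; results need checking")

    W <- wf$water; F <- wf$fat
    tot <- W + F
    ff <- ifelse(tot > 0, F / tot, 0)
    ff <- pmin(pmax(ff, 0), 1)
    dim(ff) <- d
    corrected <- Arg(S * exp(-1i * phi))
    new("WaterFatResult",
        water = W, fat = F, smoothPhase = phi, correctedPhase = corrected,
        fatFraction = ff, iterationsUsed = max(it, 0L), finalCost = cost,
        costTrace = trace, converged = convergedFlag)
}
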