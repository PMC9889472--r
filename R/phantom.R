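## Synthetic sagittal spine phantom with ground truth.
##
## The geometry is deliberately schematic -- stacked rounded boxes, not
## anatomical meshes -- because the solver and the SWI-like processing only
## need the contrast and phase structure of a spine, not its anatomy, and a
## schematic volume generates in well under a second.

## tissue label coding used by PhantomTruth
.labelCodes <- c(background = 0L, marrow = 1L, cortex = 2L, disc = 3L,
                 edema = 4L, plexus = 5L)

## Default order-2 background-phase coefficients (polyExponents(2) order:
## const, z, y, x, z^2, yz, y^2, xz, xy, x^2).  Chosen once to span about
## +/-1.5 rad over the default grid: large enough to defeat a naive
## per-voxel decomposition, smooth enough for the solver's basis, and
## below +/-pi so no unwrapping is needed.
.defaultBackgroundCoeffs <- c(0.103, 0.259, -0.466, 0.569, 0.207,
                              0.155, -0.362, -0.103, 0.310, 0.414)

#' Construct a phantom specification
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: five vertebrae with fatty marrow (fat fraction 0.6), a
#' cortical shell at 30% marrow magnitude carrying a local phase of
#' -0.5 rad, an edema vertebra (index 3, fat fraction 0.25, raised water),
#' a weakly hyperintense venous-plexus stripe, an order-2 background phase
#' spanning about +/-1.5 rad, and no noise (`snr = Inf`); tests that need
#' noise state their own SNR.
#'
#' @param gridShape Voxels per axis (x = anterior-posterior,
#'   y = superior-inferior, z = left-right slab).
#' @param voxelSize mm per axis.
#' @param nVertebrae Number of vertebral bodies stacked along y.
#' @param marrowFatFraction Fat fraction of normal marrow.
#' @param edemaVertebraIndex Index of the edema vertebra (NA disables).
#' @param edemaFatFraction Marrow fat fraction inside the edema vertebra.
#' @param corticalPhaseOffset Local cortical phase in rad (<= 0).
#' @param corticalMagnitudeFactor Cortical magnitude relative to marrow.
#' @param backgroundPhaseCoeffs Order-2 polynomial coefficients
#'   ([polyExponents()] ordering) of the background phase.
#' @param venousPlexusEnabled Add the plexus stripe?
#' @param venousPlexusIntensityFactor Stripe magnitude relative to marrow.
#' @param snr Mean marrow magnitude / per-channel noise sd; Inf = noiseless.
#' @param seed Integer seed; same spec + seed is bit-identical.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(gridShape = c(64L, 80L, 12L),
                        voxelSize = c(1, 1, 3),
                        nVertebrae = 5L,
                        marrowFatFraction = 0.6,
                        edemaVertebraIndex = 3L,
                        edemaFatFraction = 0.25,
                        corticalPhaseOffset = -0.5,
                        corticalMagnitudeFactor = 0.3,
                        backgroundPhaseCoeffs = .defaultBackgroundCoeffs,
                        venousPlexusEnabled = TRUE,
                        venousPlexusIntensityFactor = 1.1,
                        snr = Inf,
                        seed = 1L) {
    new("PhantomSpec",
        gridShape = as.integer(gridShape),
        voxelSize = as.numeric(voxelSize),
        nVertebrae = as.integer(nVertebrae),
        marrowFatFraction = as.numeric(marrowFatFraction),
        edemaVertebraIndex = if (length(edemaVertebraIndex) == 1L && is.na(edemaVertebraIndex))
            NA_integer_ else as.integer(edemaVertebraIndex),
        edemaFatFraction = as.numeric(edemaFatFraction),
        corticalPhaseOffset = as.numeric(corticalPhaseOffset),
        corticalMagnitudeFactor = as.numeric(corticalMagnitudeFactor),
        backgroundPhaseCoeffs = as.numeric(backgroundPhaseCoeffs),
        venousPlexusEnabled = isTRUE(venousPlexusEnabled),
        venousPlexusIntensityFactor = as.numeric(venousPlexusIntensityFactor),
        snr = as.numeric(snr),
        seed = as.integer(seed))
}

## evaluate expr with a private, seeded RNG stream; global stream untouched
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## logical rounded-rectangle mask in the (x, y) plane
roundedRectMask <- function(nx, ny, x0, x1, y0, y1, r) {
    xs <- matrix(seq_len(nx), nx, ny)
    ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    inside <- xs >= x0 & xs <= x1 & ys >= y0 & ys <= y1
    if (r > 0) {
        for (cx in c(x0 + r, x1 - r)) for (cy in c(y0 + r, y1 - r)) {
            corner <- (if (cx == x0 + r) xs < cx else xs > cx) &
                      (if (cy == y0 + r) ys < cy else ys > cy)
            inside <- inside & (!corner | ((xs - cx)^2 + (ys - cy)^2 <= r^2))
        }
    }
    inside
}

## 6-neighbour binary erosion of a 3D logical array
erode3d <- function(mask) {
    d <- dim(mask)
    out <- mask
    shift <- function(m, axis, by) {
        res <- array(FALSE, d)
        idx <- lapply(d, seq_len)
        src <- idx; dst <- idx
        n <- d[axis]
        if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
        else        { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
        res[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
        res
    }
    for (axis in 1:3) for (by in c(-1L, 1L))
        out <- out & shift(mask, axis, by)
    out
}

#' Generate a synthetic spine phantom
#'
#' Builds a sagittal slab with `nVertebrae` rounded vertebral bodies
#' stacked along y and separated by water-rich discs.  Each body is fatty
#' marrow enclosed by a one-voxel cortical shell with reduced magnitude and
#' an added local negative phase; the optional edema vertebra has reduced
#' fat fraction and raised water; the optional plexus stripe is a thin
#' water-dominant band posterior to the edema vertebra.  Background soft
#' tissue is water at 0.35 (marrow total = 1) with a two-voxel air frame at
#' the volume border, plus a dorsal subcutaneous layer of pure fat (carried
#' under the background label) as found on every sagittal spine image.  The smooth background phase is the order-2
#' polynomial from the spec; circular complex Gaussian noise is added at
#' the requested SNR (per-channel sd = mean marrow magnitude / SNR).
#'
#' The noiseless signal equals
#' `forwardSignal(waterMap, fatMap, phaseBackground + phaseLocal, c)`
#' exactly, which the test suite asserts.
#'
#' @param spec A [PhantomSpec-class].
#' @param spectrum Fat spectrum used for the forward simulation.
#' @param acq Acquisition parameters.
#' @return A list with elements `volume` ([ComplexVolume-class]) and
#'   `truth` ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(32, 40, 8)))
#' ph$truth
#' @export
generatePhantom <- function(spec = phantomSpec(), spectrum = fatSpectrum(),
                            acq = acquisitionParams()) {
    validObject(spec)
    d <- spec@gridShape
    nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
    edemaOn <- !is.na(spec@edemaVertebraIndex)
    if (edemaOn && (spec@edemaVertebraIndex < 1L ||
                    spec@edemaVertebraIndex > spec@nVertebrae))
        stop("config error: 'edemaVertebraIndex' out of range")

    labels <- array(.labelCodes[["background"]], d)
    water <- array(0.35, d)   # paraspinal soft tissue
    fat <- array(0, d)
    phaseLocal <- array(0, d)

    ## air frame (zero signal) at the x and z borders
    air <- array(FALSE, d)
    air[c(1:2, nx - 1L, nx), , ] <- TRUE
    air[, , c(1L, nz)] <- TRUE
    water[air] <- 0

    ## vertebral column geometry
    x0 <- round(0.25 * nx); x1 <- round(0.62 * nx)
    z0 <- max(2L, round(0.2 * nz)); z1 <- min(nz - 1L, round(0.8 * nz))
    m <- max(3L, round(0.05 * ny))                 # y margin
    avail <- ny - 2L * m
    discH <- max(2L, round(0.04 * ny))             # disc thickness
    vertH <- floor((avail - (spec@nVertebrae - 1L) * discH) / spec@nVertebrae)
    if (vertH < 5L)
        stop("grid too small for the requested number of vertebrae")
    r <- 2L                                        # corner radius

    ffMarrow <- spec@marrowFatFraction
    zRange <- z0:z1
    bodyStack <- array(FALSE, d)
    for (v in seq_len(spec@nVertebrae)) {
        y0 <- m + (v - 1L) * (vertH + discH) + 1L
        y1 <- y0 + vertH - 1L
        bodyXY <- roundedRectMask(nx, ny, x0, x1, y0, y1, r)
        body <- array(FALSE, d)
        body[, , zRange] <- bodyXY
        bodyStack <- bodyStack | body
        interior <- erode3d(body)
        shell <- body & !interior

        isEdema <- edemaOn && v == spec@edemaVertebraIndex
        ff <- if (isEdema) spec@edemaFatFraction else ffMarrow
        total <- if (isEdema) 1.15 else 1.0        # edema: raised water signal
        water[interior] <- (1 - ff) * total
        fat[interior] <- ff * total
        labels[interior] <- if (isEdema) .labelCodes[["edema"]] else .labelCodes[["marrow"]]

        water[shell] <- spec@corticalMagnitudeFactor
        fat[shell] <- 0
        labels[shell] <- .labelCodes[["cortex"]]
        phaseLocal[shell] <- spec@corticalPhaseOffset

        ## disc below this vertebra
        if (v < spec@nVertebrae) {
            dy0 <- y1 + 1L; dy1 <- y1 + discH
            discXY <- roundedRectMask(nx, ny, x0 + 1L, x1 - 1L, dy0, dy1, 0L)
            disc <- array(FALSE, d)
            disc[, , zRange] <- discXY
            disc <- disc & !bodyStack
            water[disc] <- 0.9
            fat[disc] <- 0
            labels[disc] <- .labelCodes[["disc"]]
        }
    }

    ## venous plexus: thin water stripe just posterior to one vertebra
    if (spec@venousPlexusEnabled) {
        vp <- if (edemaOn) spec@edemaVertebraIndex else ceiling(spec@nVertebrae / 2)
        y0 <- m + (vp - 1L) * (vertH + discH) + 1L
        y1 <- y0 + vertH - 1L
        px <- (x1 + 2L):min(x1 + 3L, nx - 2L)
        stripe <- array(FALSE, d)
        stripe[px, y0:y1, zRange] <- TRUE
        stripe <- stripe & labels == .labelCodes[["background"]] & !air
        water[stripe] <- spec@venousPlexusIntensityFactor
        fat[stripe] <- 0
        labels[stripe] <- .labelCodes[["plexus"]]
    }

    ## dorsal subcutaneous fat: a pure-fat layer along the posterior edge.
    ## Besides being present on every sagittal spine image, pure fat (like
    ## the pure-water tissues above) anchors the smooth-phase estimate:
    ## only voxels at the water/fat cone boundary carry absolute phase
    ## information in the single-echo model.
    sq <- array(FALSE, d)
    sq[(nx - 7L):(nx - 3L), , zRange] <- TRUE
    sq <- sq & labels == .labelCodes[["background"]] & !air
    water[sq] <- 0
    fat[sq] <- 0.9

    phaseBg <- evalPolyField(spec@backgroundPhaseCoeffs, d, 2L)
    cf <- fatCoefficient(spectrum, acq)
    signal <- forwardSignal(water, fat, phaseBg + phaseLocal, cf)

    if (is.finite(spec@snr)) {
        marrowMag <- mean(Mod(signal)[labels == .labelCodes[["marrow"]]])
        sdNoise <- marrowMag / spec@snr
        noise <- withSeed(spec@seed, {
            n <- prod(d)
            complex(real = rnorm(n, sd = sdNoise), imaginary = rnorm(n, sd = sdNoise))
        })
        signal <- signal + array(noise, d)
    }

    truth <- new("PhantomTruth", waterMap = water, fatMap = fat,
                 phaseBackground = phaseBg, phaseLocal = phaseLocal,
                 tissueLabels = labels, labelCodes = .labelCodes)
    vol <- complexVolume(signal, voxelSize = spec@voxelSize, acquisition = acq)
    list(volume = vol, truth = truth)
}
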