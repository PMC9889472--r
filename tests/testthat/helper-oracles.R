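# Independent oracles and shared fixtures, built in code at test time.

# Exhaustive grid search for the per-voxel water-fat decomposition over
# (W, F) in [0, upper]^2 at the given step.  For each F column the
# grid-optimal W is found from the clamped continuous minimiser (checking
# both neighbouring grid points), which returns exactly the minimum of the
# full 2D grid scan.
bruteForceDecompose <- function(s, c, step = 1e-3, upper = 2) {
    Fg <- seq(0, upper, by = step)
    t(vapply(s, function(sv) {
        Wcont <- pmin(pmax(Re(sv) - Re(c) * Fg, 0), upper)
        Wlo <- pmin(pmax(floor(Wcont / step) * step, 0), upper)
        Whi <- pmin(Wlo + step, upper)
        r2 <- function(W) (Re(sv) - W - Re(c) * Fg)^2 + (Im(sv) - Im(c) * Fg)^2
        rlo <- r2(Wlo); rhi <- r2(Whi)
        useLo <- rlo <= rhi
        rbest <- ifelse(useLo, rlo, rhi)
        i <- which.min(rbest)
        c(W = if (useLo[i]) Wlo[i] else Whi[i], F = Fg[i], resid = rbest[i])
    }, c(W = 0, F = 0, resid = 0)))
}

# Closed-form delta-method sd of the voxel fat fraction F/(W+F) under
# circular complex Gaussian noise of per-channel sd `sigma`, at true
# composition (W, F) and fat coefficient c.
deltaMethodFatFractionSd <- function(W, F, c, sigma) {
    tot <- W + F
    # d(ff) = (W dF - F dW)/tot^2 with dW = n_r - Re(c) dF, dF = n_i/Im(c)
    a <- -F / tot^2                                  # coefficient of n_r
    b <- (W / tot^2 + (F / tot^2) * Re(c)) / Im(c)   # coefficient of n_i
    sigma * sqrt(a^2 + b^2)
}

# 3-category confusion counts (rows rater A, cols rater B) behind the
# frozen kappa oracle values
kappaToyRatings <- function() {
    counts <- matrix(c(11, 3, 1,
                        2, 9, 4,
                        0, 2, 8), 3, 3, byrow = TRUE)
    a <- rep(rep(1:3, each = 3), as.vector(t(counts)))
    b <- rep(rep(1:3, times = 3), as.vector(t(counts)))
    ratingTable(a, b, scale = "ordinal", categories = 1:3)
}

# small default-structure phantom for fast unit tests
smallPhantomSpec <- function(...) {
    phantomSpec(gridShape = c(40L, 48L, 8L), ...)
}

defaultCoefficient <- function() {
    fatCoefficient(fatSpectrum(), acquisitionParams())
}
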