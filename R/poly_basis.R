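## Low-order 3D polynomial basis over normalised coordinates, shared by
## the phantom's background phase and the solver's smooth-phase model.

#' Exponent table of the truncated tensor polynomial basis
#'
#' All exponent triples (i, j, k) with i + j + k <= order, ordered by total
#' degree, then by i, j, k.  This fixed ordering defines the meaning of
#' coefficient vectors everywhere in the package (e.g.
#' `backgroundPhaseCoeffs` in [phantomSpec()]).
#'
#' @param order Maximum total degree (>= 0).
#' @return An integer matrix with columns `i`, `j`, `k` (exponents of the
#'   normalised x, y, z coordinates).
#' @examples
#' polyExponents(2)   # 10 terms
#' @export
polyExponents <- function(order) {
    stopifnot(order >= 0)
    ex <- expand.grid(k = 0:order, j = 0:order, i = 0:order)
    ex <- ex[, c("i", "j", "k")]
    ex <- ex[rowSums(ex) <= order, , drop = FALSE]
    ex <- ex[order(rowSums(ex), ex$i, ex$j, ex$k), , drop = FALSE]
    m <- as.matrix(ex)
    rownames(m) <- NULL
    storage.mode(m) <- "integer"
    m
}

## Normalised axis coordinate in [-1, 1]; a singleton axis maps to 0.
normCoord <- function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
}

#' Design matrix of the 3D polynomial basis on a voxel grid
#'
#' Each axis is mapped linearly to [-1, 1]; the matrix row order is R's
#' native array order (x fastest).
#'
#' @param gridShape Integer length-3 vector of voxels per axis.
#' @param order Maximum total degree.
#' @return A numeric matrix, `prod(gridShape)` rows by `nrow(polyExponents(order))`
#'   columns.
#' @export
polyBasisMatrix <- function(gridShape, order) {
    stopifnot(length(gridShape) == 3L)
    ex <- polyExponents(order)
    u <- normCoord(gridShape[1L]); v <- normCoord(gridShape[2L]); w <- normCoord(gridShape[3L])
    ## per-axis power tables, then combine with outer-product structure
    pu <- outer(u, 0:order, `^`)
    pv <- outer(v, 0:order, `^`)
    pw <- outer(w, 0:order, `^`)
    n <- prod(gridShape)
    B <- matrix(0, n, nrow(ex))
    ix <- rep.int(seq_len(gridShape[1L]), gridShape[2L] * gridShape[3L])
    iy <- rep.int(rep(seq_len(gridShape[2L]), each = gridShape[1L]), gridShape[3L])
    iz <- rep(seq_len(gridShape[3L]), each = gridShape[1L] * gridShape[2L])
    for (t in seq_len(nrow(ex))) {
        B[, t] <- pu[ix, ex[t, 1L] + 1L] * pv[iy, ex[t, 2L] + 1L] *
            pw[iz, ex[t, 3L] + 1L]
    }
    B
}

#' Evaluate a polynomial coefficient vector on a grid
#'
#' @param coeffs Coefficients in the [polyExponents()] ordering.
#' @param gridShape Voxels per axis.
#' @param order Total degree matching `length(coeffs)`.
#' @return A numeric 3D array.
#' @export
evalPolyField <- function(coeffs, gridShape, order) {
    ex <- polyExponents(order)
    if (length(coeffs) != nrow(ex))
        stop(sprintf("expected %d coefficients for order %d, got %d",
                     nrow(ex), order, length(coeffs)))
    array(polyBasisMatrix(gridShape, order) %*% coeffs, dim = gridShape)
}
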