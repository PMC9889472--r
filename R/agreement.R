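## Reader-agreement statistics for paired ratings: weighted Cohen's kappa
## for ordinal scales and ICC(2,1) for continuous measurements.  Results
## always carry the weighting / model-form label, since different choices
## give different numbers on the same data.

#' Construct a paired rating table
#'
#' @param raterA,raterB Paired ratings (ordinal: integer categories) or
#'   measurements (continuous), equal length >= 2.
#' @param scale `"ordinal"` or `"continuous"`.
#' @param subjects Optional subject identifiers (defaults to 1..n).
#' @param categories Declared finite category set for ordinal scales;
#'   defaults to the sorted union of observed ratings.  Declare the full
#'   scale explicitly when some categories were never used.
#' @return A [RatingTable-class] object.
#' @examples
#' ratingTable(c(1, 2, 2, 3), c(1, 2, 3, 3), scale = "ordinal")
#' @export
ratingTable <- function(raterA, raterB, scale = c("ordinal", "continuous"),
                        subjects = NULL, categories = NULL) {
    scale <- match.arg(scale)
    if (is.null(subjects)) subjects <- as.character(seq_along(raterA))
    if (scale == "ordinal" && is.null(categories))
        categories <- sort(unique(c(raterA, raterB)))
    new("RatingTable",
        subjects = as.character(subjects),
        raterA = as.numeric(raterA), raterB = as.numeric(raterB),
        scale = scale,
        categories = if (is.null(categories)) numeric() else as.numeric(categories))
}

#' Weighted Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected ordinal agreement,
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}},}
#' with disagreement weights \eqn{w_{ij} = |i-j|/(k-1)} (linear) or
#' \eqn{((i-j)/(k-1))^2} (quadratic), `O` the observed proportion matrix
#' over the declared k-category set and `E` the outer product of its
#' marginals.  The 95% CI uses the Fleiss-Cohen-Everitt large-sample
#' standard error and is clipped to [-1, 1].  With quadratic weights on a
#' 2-category scale, the weighted kappa equals unweighted kappa.
#'
#' @param table A [RatingTable-class] with ordinal scale.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param conf Confidence level (default 0.95).
#' @return A list: `kappa`, `ci` (length 2), `se`, `n`, `weights`,
#'   `method`.
#' @examples
#' tb <- ratingTable(c(1, 2, 2, 3, 1), c(1, 2, 3, 3, 1), scale = "ordinal")
#' weightedKappa(tb)
#' @export
weightedKappa <- function(table, weights = c("linear", "quadratic"),
                          conf = 0.95) {
    stopifnot(is(table, "RatingTable"))
    if (table@scale != "ordinal")
        stop("weighted kappa requires an ordinal-scale rating table")
    weights <- match.arg(weights)
    cats <- sort(table@categories)
    k <- length(cats)
    if (k < 2L)
        stop("degenerate scale: fewer than 2 distinct categories declared")
    n <- length(table@raterA)
    fa <- factor(table@raterA, levels = cats)
    fb <- factor(table@raterB, levels = cats)
    O <- table(fa, fb) / n
    pi. <- rowSums(O); p.j <- colSums(O)
    E <- outer(pi., p.j)
    dis <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
    if (weights == "quadratic") dis <- dis^2
    denom <- sum(dis * E)
    kap <- if (denom == 0) 1 else 1 - sum(dis * O) / denom

    ## Fleiss-Cohen-Everitt asymptotic SE, in agreement-weight form
    wa <- 1 - dis
    po <- sum(wa * O); pe <- sum(wa * E)
    wbi <- as.vector(wa %*% p.j)       # row-associated expected weights
    wbj <- as.vector(t(wa) %*% pi.)    # column-associated expected weights
    if (pe < 1) {
        sq <- outer(wbi, wbj, `+`)
        v <- (sum(O * (wa - sq * (1 - kap))^2) - (kap - pe * (1 - kap))^2) /
            (n * (1 - pe)^2)
        se <- sqrt(max(v, 0))
    } else se <- 0
    z <- qnorm(1 - (1 - conf) / 2)
    ci <- pmin(pmax(kap + c(-1, 1) * z * se, -1), 1)
    list(kappa = kap, ci = ci, se = se, n = n, weights = weights,
         method = paste0("weighted Cohen's kappa (", weights, " weights)"))
}

#' Intra-class correlation ICC(2,1) with F-based confidence interval
#'
#' Two-way random effects, absolute agreement, single measures -- the
#' conventional form for two readers each measuring every subject:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' with mean squares for subjects (rows), raters (columns) and error from
#' the two-way ANOVA (computed via [stats::aov()]).  The 95% CI is the
#' standard F-based interval with Satterthwaite degrees of freedom
#' (McGraw-Wong).  ICC is invariant under a common affine transform of
#' both raters.
#'
#' @param table A [RatingTable-class] with continuous scale.
#' @param form Only `"two_way_random_absolute_single"` is offered.
#' @param conf Confidence level (default 0.95).
#' @return A list: `icc`, `ci`, `n`, `form`, `method`.
#' @examples
#' tb <- ratingTable(c(7.2, 8.1, 6.5, 9.0), c(7.0, 8.3, 6.9, 8.8),
#'                   scale = "continuous")
#' iccAgreement(tb)
#' @export
iccAgreement <- function(table, form = "two_way_random_absolute_single",
                         conf = 0.95) {
    stopifnot(is(table, "RatingTable"))
    if (table@scale != "continuous")
        stop("ICC requires a continuous-scale rating table")
    form <- match.arg(form)
    n <- length(table@raterA); k <- 2L
    X <- cbind(table@raterA, table@raterB)
    if (all(X == X[1L]))
        stop("undefined ICC: the measurements have zero total variance")
    df <- data.frame(
        value = c(X),
        subject = factor(rep(seq_len(n), k)),
        rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(aov(value ~ subject + rater, data = df))[[1L]][, "Mean Sq"]
    MSR <- ms[1L]; MSC <- ms[2L]; MSE <- ms[3L]
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

    alpha <- 1 - conf
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    list(icc = icc, ci = c(lower, upper), n = n, form = form,
         method = "ICC(2,1): two-way random, absolute agreement, single measures")
}

#' Batch agreement over a directory of rating CSVs
#'
#' Each CSV must have columns `subject`, `rater_a`, `rater_b`, `scale`
#' (constant per file, `ordinal` or `continuous`).  Ordinal files get a
#' weighted kappa, continuous files an ICC(2,1); one summary row per file.
#'
#' @param paths Character vector of CSV paths.
#' @param weights Kappa weighting for the ordinal files.
#' @return A data.frame with columns `file`, `parameter`, `estimate`,
#'   `ci_low`, `ci_high`, `n`, `method`.
#' @export
agreementBatch <- function(paths, weights = "linear") {
    rows <- lapply(paths, function(p) {
        d <- utils::read.csv(p)
        need <- c("subject", "rater_a", "rater_b", "scale")
        if (!all(need %in% names(d)))
            stop("rating CSV must have columns: ", paste(need, collapse = ", "),
                 " (file ", p, ")")
        sc <- unique(d$scale)
        if (length(sc) != 1L)
            stop("'scale' must be constant within a rating CSV (file ", p, ")")
        tb <- ratingTable(d$rater_a, d$rater_b, scale = sc,
                          subjects = d$subject)
        res <- if (sc == "ordinal") {
            r <- weightedKappa(tb, weights = weights)
            list(est = r$kappa, ci = r$ci, n = r$n, method = r$method)
        } else {
            r <- iccAgreement(tb)
            list(est = r$icc, ci = r$ci, n = r$n, method = r$method)
        }
        data.frame(file = basename(p),
                   parameter = sub("\\.csv$", "", basename(p)),
                   estimate = res$est, ci_low = res$ci[1L],
                   ci_high = res$ci[2L], n = res$n, method = res$method,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
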