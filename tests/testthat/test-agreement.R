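# Kappa and ICC oracles are independent from-scratch evaluations of the
# defining formulas (direct weighted-proportion sums; raw ANOVA sums of
# squares), frozen into the expectations below.

test_that("weighted kappa matches the frozen direct-formula oracle", {
    tb <- kappaToyRatings()
    lin <- weightedKappa(tb, "linear")
    expect_equal(lin$kappa, 0.62589928057553956, tolerance = 1e-12)
    expect_equal(lin$ci, c(0.43603598543894362, 0.81576257571213551),
                 tolerance = 1e-9)
    quad <- weightedKappa(tb, "quadratic")
    expect_equal(quad$kappa, 0.70588235294117652, tolerance = 1e-12)
    expect_match(lin$method, "linear")
})

test_that("kappa honours its boundary and invariance properties", {
    # identical ratings: perfect agreement
    same <- ratingTable(c(1, 2, 3, 2, 1, 3), c(1, 2, 3, 2, 1, 3),
                        scale = "ordinal")
    expect_equal(weightedKappa(same)$kappa, 1)

    # independent ratings by construction: kappa near zero, inside its CI
    set.seed(17)
    a <- sample(1:4, 400, replace = TRUE)
    b <- sample(a)             # same marginals, no subject-wise association
    rnd <- weightedKappa(ratingTable(a, b, scale = "ordinal"))
    expect_true(rnd$ci[1] <= 0 || abs(rnd$kappa) < 0.1)

    # permutation of subjects leaves kappa unchanged
    tb <- kappaToyRatings()
    perm <- sample(length(tb@raterA))
    tbP <- ratingTable(tb@raterA[perm], tb@raterB[perm], scale = "ordinal",
                       categories = 1:3)
    expect_equal(weightedKappa(tbP)$kappa, weightedKappa(tb)$kappa,
                 tolerance = 1e-14)

    # on a 2-category scale quadratic weights reduce to unweighted kappa
    set.seed(23)
    a2 <- sample(1:2, 60, replace = TRUE)
    b2 <- ifelse(runif(60) < 0.75, a2, 3 - a2)
    tb2 <- ratingTable(a2, b2, scale = "ordinal", categories = 1:2)
    O <- table(factor(a2, levels = 1:2), factor(b2, levels = 1:2)) / 60
    E <- outer(rowSums(O), colSums(O))
    kappaUnweighted <- 1 - (1 - sum(diag(O))) / (1 - sum(diag(E)))
    expect_equal(weightedKappa(tb2, "quadratic")$kappa, kappaUnweighted,
                 tolerance = 1e-12)

    expect_error(weightedKappa(ratingTable(c(1, 1), c(1, 1),
                                           scale = "ordinal",
                                           categories = 1)),
                 "categories")
})

test_that("ICC(2,1) matches the frozen ANOVA sums-of-squares oracle", {
    tb <- ratingTable(c(7.2, 8.1, 6.5, 9.0, 7.8, 8.4),
                      c(7.0, 8.3, 6.9, 8.8, 7.7, 8.9),
                      scale = "continuous")
    r <- iccAgreement(tb)
    expect_equal(r$icc, 0.94168466522678185, tolerance = 1e-12)
    expect_equal(r$ci, c(0.68669430528088782, 0.99146939788934174),
                 tolerance = 1e-9)
    expect_match(r$method, "two-way random")
})

test_that("ICC honours its boundary and invariance properties", {
    x <- c(3.1, 4.5, 2.2, 6.7, 5.0, 3.9, 4.4, 5.8)

    # a rater agreeing with itself gives ICC 1
    expect_equal(iccAgreement(ratingTable(x, x, scale = "continuous"))$icc, 1,
                 tolerance = 1e-12)

    # overwhelming independent noise drives ICC to zero
    set.seed(31)
    a <- rnorm(200)
    b <- a + rnorm(200, sd = 25)
    r0 <- iccAgreement(ratingTable(a, b, scale = "continuous"))
    expect_lt(abs(r0$icc), 0.2)
    expect_true(r0$ci[1] <= 0)

    # common affine transform of both raters leaves ICC unchanged
    set.seed(37)
    b2 <- x + rnorm(8, sd = 0.4)
    r1 <- iccAgreement(ratingTable(x, b2, scale = "continuous"))
    r2 <- iccAgreement(ratingTable(2.5 * x - 7, 2.5 * b2 - 7,
                                   scale = "continuous"))
    expect_equal(r1$icc, r2$icc, tolerance = 1e-10)

    # subject permutation invariance
    perm <- sample(8)
    r3 <- iccAgreement(ratingTable(x[perm], b2[perm], scale = "continuous"))
    expect_equal(r1$icc, r3$icc, tolerance = 1e-12)

    expect_error(iccAgreement(ratingTable(rep(2, 5), rep(2, 5),
                                          scale = "continuous")),
                 "zero total variance")
    expect_error(iccAgreement(kappaToyRatings()), "continuous")
    expect_error(weightedKappa(ratingTable(x, b2, scale = "continuous")),
                 "ordinal")
})

test_that("batch agreement summarises mixed CSV tables", {
    td <- withr::local_tempdir()
    write.csv(data.frame(subject = 1:6,
                         rater_a = c(1, 2, 2, 3, 1, 3),
                         rater_b = c(1, 2, 3, 3, 1, 3),
                         scale = "ordinal"),
              file.path(td, "fracture_grade.csv"), row.names = FALSE)
    write.csv(data.frame(subject = 1:6,
                         rater_a = c(7.2, 8.1, 6.5, 9.0, 7.8, 8.4),
                         rater_b = c(7.0, 8.3, 6.9, 8.8, 7.7, 8.9),
                         scale = "continuous"),
              file.path(td, "disc_height_mm.csv"), row.names = FALSE)
    out <- agreementBatch(list.files(td, full.names = TRUE))
    expect_equal(nrow(out), 2)
    expect_equal(out$estimate[out$parameter == "disc_height_mm"],
                 0.94168466522678185, tolerance = 1e-10)
    expect_true(all(c("estimate", "ci_low", "ci_high", "n", "method")
                    %in% names(out)))
})
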