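test_that("pearsonR matches hand computations and validates input", {
    x <- 1:10
    expect_equal(pearsonR(x, 2 * x + 1), 1)
    expect_equal(pearsonR(x, -x), -1)
    expect_equal(pearsonR(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
    expect_error(pearsonR(rep(1, 5), 1:5), "constant")
    expect_error(pearsonR(1:2, 2:3), "insufficient")
    # pairwise-complete deletion
    expect_equal(pearsonR(c(x, NA), c(2 * x + 1, 5)), 1)
})

test_that("perfect correlation attains the add-one floor", {
    x <- rnorm(10)
    p <- permutationPvalue(x, x, B = 999, seed = 1)
    expect_equal(as.numeric(p), 1 / 1000)
    expect_equal(attr(p, "r"), 1, tolerance = 1e-12)
})

test_that("exact enumeration equals the brute-force oracle", {
    set.seed(3)
    for (i in 1:3) {
        x <- rnorm(5); y <- rnorm(5)
        for (sided in c("two_sided", "greater", "less")) {
            p <- permutationPvalue(x, y, method = "exact",
                                   sidedness = sided)
            expect_equal(as.numeric(p), exactPermPOracle(x, y, sided),
                         tolerance = 1e-12)
        }
        expect_equal(attr(permutationPvalue(x, y, method = "exact"), "B"),
                     factorial(5))
    }
})

test_that("sampled permutation p is deterministic and affine invariant", {
    set.seed(5)
    x <- rnorm(15); y <- rnorm(15)
    p1 <- permutationPvalue(x, y, B = 500, seed = 99)
    p2 <- permutationPvalue(x, y, B = 500, seed = 99)
    expect_identical(as.numeric(p1), as.numeric(p2))
    # |r| is affine invariant, so the two-sided p is too (same stream)
    p3 <- permutationPvalue(2 * x + 3, -0.5 * y + 1, B = 500, seed = 99)
    expect_identical(as.numeric(p1), as.numeric(p3))
    # two-sided symmetry under y -> -y
    p4 <- permutationPvalue(x, -y, B = 500, seed = 99)
    expect_identical(as.numeric(p1), as.numeric(p4))
    expect_error(permutationPvalue(x, y, B = 0, seed = 1), "B must be")
})

test_that("t-test wrappers agree with hand formulas and each other", {
    set.seed(11)
    a <- rnorm(9, 10, 2); b <- rnorm(11, 9, 3)
    w <- welchTest(a, b)
    # hand-computed Welch statistic and Satterthwaite df
    sa2 <- var(a) / 9; sb2 <- var(b) / 11
    tHand <- (mean(a) - mean(b)) / sqrt(sa2 + sb2)
    dfHand <- (sa2 + sb2)^2 / (sa2^2 / 8 + sb2^2 / 10)
    pHand <- 2 * pt(-abs(tHand), dfHand)
    expect_equal(w$t, tHand, tolerance = 1e-10)
    expect_equal(w$df, dfHand, tolerance = 1e-10)
    expect_equal(w$p, pHand, tolerance = 1e-10)

    s <- studentTest(a, b)
    expect_equal(s$df, 18)

    # equal n and equal sample variance: identical t, different df
    a2 <- c(1, 2, 3, 4); b2 <- c(11, 12, 13, 14)
    expect_equal(welchTest(a2, b2)$t, studentTest(a2, b2)$t,
                 tolerance = 1e-12)
    expect_equal(studentTest(a2, b2)$df, 6)

    expect_equal(welchTest(a2, a2)$t, 0)
    expect_equal(welchTest(a2, a2)$p, 1)
    expect_lt(studentTest(a2, b2)$p, 0.01)
    expect_message(welchTest(c(1, 1), c(1, 1)), "convention")
    expect_error(welchTest(1, a2), "at least 2")
})

test_that("the screen flags tiers consistently and skips degenerate columns", {
    coh <- simulateCohort(cohortSpec(), seed = 19)
    se <- buildFeatureTable(coh)
    sc <- screenFeatures(se, "PFC", B = 399, seed = 23)
    expect_true(all(sc$tier[sc$p_perm < 0.025] == "q975"))
    expect_true(all(sc$tier[sc$p_perm >= 0.05] == "none"))
    expect_true(all(sc$p_perm >= 1 / 400 & sc$p_perm <= 1))
    expect_true(all(abs(sc$r) <= 1))
    expect_equal(sc$neg_log10_p, -log10(sc$p_perm))

    # identical rerun: the per-feature streams derive from the master seed
    sc2 <- screenFeatures(se, "PFC", B = 399, seed = 23)
    expect_identical(sc, sc2, ignore_attr = TRUE)

    # a constant feature is skipped and reported
    a <- SummarizedExperiment::assay(se, "concentration")
    a["PFC:Ala", ] <- 1
    SummarizedExperiment::assay(se, "concentration") <- a
    sc3 <- screenFeatures(se, "PFC", B = 199, seed = 23,
                          includedOnly = FALSE)
    expect_false("Ala" %in% sc3$feature)
    expect_true("Ala" %in% attr(sc3, "skipped"))

    expect_error(screenFeatures(se, "PFC", B = 199), "seed")
    expect_error(screenFeatures(se, "PFC", index = "bogus", B = 199,
                                seed = 1), "not found")
})

test_that("group tests cover every included feature with per-feature n", {
    coh <- simulateCohort(cohortSpec(), seed = 29)
    se <- buildFeatureTable(coh)
    gt <- groupTests(se)
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    expect_true(all(paste(gt$region, gt$feature) %in%
                    paste(rd$region, rd$feature)[rd$included]))
    expect_true(all(gt$df > 0))
    expect_true(all(gt$p > 0 & gt$p <= 1))
    expect_true(all(gt$variant == "welch"))
    gts <- groupTests(se, variant = "student")
    expect_true(all(gts$df == gts$n_a + gts$n_b - 2))
})
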