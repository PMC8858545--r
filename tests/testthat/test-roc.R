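test_that("simple logistic regression behaves at the boundaries", {
    # no information: slope ~ 0, fitted ~ prevalence
    x <- rep(c(1, 2, 3), 4)
    lab <- rep(c("KO", "WT"), 6)
    fit <- fitSimpleLogistic(x, lab, positive = "KO")
    expect_lt(abs(fit$slope), 1e-6)
    expect_equal(fit$fitted, rep(0.5, 12), tolerance = 1e-6)

    # two-point support with overlap: closed-form saturated log-odds
    x2 <- rep(c(0, 1), each = 8)
    lab2 <- c(rep("KO", 2), rep("WT", 6), rep("KO", 6), rep("WT", 2))
    fit2 <- fitSimpleLogistic(x2, lab2, positive = "KO")
    expect_equal(fit2$intercept, log(2 / 6), tolerance = 1e-6)
    expect_equal(fit2$slope, log(6 / 2) - log(2 / 6), tolerance = 1e-6)
    expect_false(fit2$separation)

    # affine rescaling: slope scales inversely, fitted unchanged
    fit3 <- fitSimpleLogistic(10 * x2, lab2, positive = "KO")
    expect_equal(fit3$slope, fit2$slope / 10, tolerance = 1e-6)
    expect_equal(fit3$fitted, fit2$fitted, tolerance = 1e-8)

    # complete separation flagged
    fit4 <- fitSimpleLogistic(c(1:5, 11:15),
                              rep(c("WT", "KO"), each = 5), positive = "KO")
    expect_true(fit4$separation)

    expect_error(fitSimpleLogistic(1:6, rep("KO", 6), positive = "KO"),
                 "two classes")
})

test_that("binormal AUC follows the closed form exactly", {
    lab <- rep(c("neg", "pos"), each = 10)
    # equal means: no separation
    x <- c(1:10, 1:10)
    expect_equal(binormalRoc(x, lab, positive = "pos")$auc, 0.5)
    # mu1 - mu0 = sqrt(s0^2 + s1^2) gives Phi(1)
    x0 <- 1:10
    delta <- sqrt(2 * var(x0))
    roc <- binormalRoc(c(x0, x0 + delta), lab, positive = "pos")
    expect_equal(roc$auc, pnorm(1), tolerance = 1e-12)
    # the general closed form, by construction
    set.seed(4)
    a <- rnorm(9, 5, 1); b <- rnorm(11, 6.2, 1.7)
    roc2 <- binormalRoc(c(a, b), rep(c("WT", "KO"), c(9, 11)),
                        positive = "KO")
    expect_equal(roc2$auc,
                 pnorm((mean(b) - mean(a)) / sqrt(var(a) + var(b))),
                 tolerance = 1e-12)
    # label swap maps AUC to its complement
    roc3 <- binormalRoc(c(a, b), rep(c("WT", "KO"), c(9, 11)),
                        positive = "WT")
    expect_equal(roc3$auc, 1 - roc2$auc, tolerance = 1e-12)
    # CI brackets the estimate and stays in [0, 1]
    expect_true(roc2$auc_ci[1] <= roc2$auc && roc2$auc <= roc2$auc_ci[2])
    expect_true(all(roc2$auc_ci >= 0 & roc2$auc_ci <= 1))
    # curve is a valid ROC: monotone non-increasing in the cutoff
    expect_true(all(diff(roc2$curve$tpr) <= 1e-12))
    expect_true(all(diff(roc2$curve$fpr) <= 1e-12))
    expect_error(binormalRoc(rep(1, 10), rep(c("a", "b"), 5),
                             positive = "a"), "undefined AUC")
})

test_that("Hanley-McNeil interval matches the published formula", {
    set.seed(9)
    a <- rnorm(9); b <- rnorm(11, 1.2)
    roc <- binormalRoc(c(a, b), rep(c("WT", "KO"), c(9, 11)),
                       positive = "KO")
    A <- roc$auc
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    se <- sqrt((A * (1 - A) + 10 * (q1 - A^2) + 8 * (q2 - A^2)) / 99)
    expect_equal(roc$auc_ci,
                 pmin(1, pmax(0, A + c(-1, 1) * qnorm(0.975) * se)),
                 tolerance = 1e-12)
    # bootstrap variant is seeded and reproducible
    r1 <- binormalRoc(c(a, b), rep(c("WT", "KO"), c(9, 11)),
                      positive = "KO", ciMethod = "bootstrap",
                      bootSamples = 200, seed = 3)
    r2 <- binormalRoc(c(a, b), rep(c("WT", "KO"), c(9, 11)),
                      positive = "KO", ciMethod = "bootstrap",
                      bootSamples = 200, seed = 3)
    expect_identical(r1$auc_ci, r2$auc_ci)
})

test_that("Youden cutoff: symmetry, degeneracy and grid-search agreement", {
    lab <- rep(c("neg", "pos"), each = 50)
    # equal variances: analytic optimum at the midpoint of the means
    set.seed(14)
    a <- rnorm(50, 5, 1); a <- (a - mean(a)) / sd(a) + 5
    roc <- binormalRoc(c(a, a + 2), lab, positive = "pos")
    oc <- optimalCutoff(roc)
    expect_equal(oc$cutoff, mean(c(5, 7)), tolerance = 1e-9)
    expect_equal(oc$sensitivity_pct, oc$specificity_pct, tolerance = 1e-6)

    # degenerate: identical classes, J = 0 and flagged
    rocD <- binormalRoc(c(a, a), lab, positive = "pos")
    ocD <- optimalCutoff(rocD)
    expect_true(ocD$degenerate)
    expect_lt(abs(ocD$youden_j), 1e-12)

    # unequal variances: agrees with a brute-force grid search
    set.seed(15)
    lab40 <- rep(c("neg", "pos"), each = 40)
    for (i in 1:5) {
        p <- rnorm(40, runif(1, 1, 3), runif(1, 0.5, 2))
        q <- rnorm(40, 0, runif(1, 0.5, 2))
        rc <- binormalRoc(c(q, p), lab40, positive = "pos")
        oc2 <- optimalCutoff(rc)
        grid <- seq(min(q, p) - 3, max(q, p) + 3, length.out = 1e4)
        J <- (1 - pnorm((grid - rc$mu_pos) / rc$sd_pos)) -
             (1 - pnorm((grid - rc$mu_neg) / rc$sd_neg))
        expect_equal(oc2$youden_j, max(J), tolerance = 1e-5)
        expect_equal(oc2$cutoff, grid[which.max(J)],
                     tolerance = diff(grid[1:2]) * 2)
    }
})

test_that("empirical AUC is invariant under the logistic transform", {
    set.seed(16)
    x <- c(rnorm(15, 0), rnorm(15, 1))
    lab <- rep(c("WT", "KO"), each = 15)
    fit <- fitSimpleLogistic(x, lab, positive = "KO")
    raw <- empiricalAUC(x[lab == "KO"], x[lab == "WT"])
    score <- plogis(fit$intercept + fit$slope * x)
    trans <- empiricalAUC(score[lab == "KO"], score[lab == "WT"])
    expect_identical(raw, trans)
})

test_that("binormal AUC agrees with an independent reference on samples", {
    skip_if_not_installed("pROC")
    set.seed(18)
    x <- c(rnorm(200, 0, 1), rnorm(200, 1, 1.4))
    lab <- rep(c(0, 1), each = 200)
    roc <- binormalRoc(x, lab, positive = 1)
    ref <- as.numeric(pROC::auc(pROC::roc(lab, x, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc$auc, ref, tolerance = 0.05)
})

test_that("rocTable reports per-feature discrimination with explicit class", {
    coh <- simulateCohort(cohortSpec(), seed = 33)
    se <- buildFeatureTable(coh)
    tab <- rocTable(se, c("Glu/GABA", "tCr", "NAA/tCr"), "PFC",
                    positive = "WT")
    expect_equal(nrow(tab), 3L)
    expect_true(all(tab$auc >= 0 & tab$auc <= 1))
    expect_true(all(tab$auc_ci_low <= tab$auc & tab$auc <= tab$auc_ci_high))
    expect_true(all(tab$sensitivity_pct >= 0 & tab$sensitivity_pct <= 100))
    expect_true(all(tab$positive == "WT"))
    expect_error(rocTable(se, "Glu/GABA", "PFC"), "positive")
})
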