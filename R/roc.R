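#' Simple (single-feature) logistic regression
#'
#' Maximum-likelihood logistic fit of class membership on one feature by
#' iteratively reweighted least squares (tolerance 1e-8, at most 100
#' iterations). All samples train the model; no cross-validation. Complete
#' separation is detected (fitted probabilities numerically 0/1 or a
#' diverging slope) and reported via the `separation` flag; the returned
#' coefficients are then the capped values at the iteration limit.
#'
#' @param x numeric feature values.
#' @param labels class labels (two classes required).
#' @param positive the label modelled as 1; must be given explicitly.
#' @return List: intercept, slope (per feature unit), fitted probabilities,
#'   separation flag, convergence flag.
#' @export
#' @examples
#' fitSimpleLogistic(c(1, 2, 3, 4, 2.5, 3.5),
#'                   rep(c("WT", "KO"), each = 3), positive = "KO")
fitSimpleLogistic <- function(x, labels, positive) {
    ok <- complete.cases(x, labels)
    x <- x[ok]; labels <- labels[ok]
    if (length(unique(labels)) != 2L)
        stop("exactly two classes required (got ",
             length(unique(labels)), ")")
    if (!positive %in% labels)
        stop("positive label not present: ", positive)
    if (length(x) < 4L)
        stop("need at least 4 observations")
    yb <- as.integer(labels == positive)
    fit <- suppressWarnings(
        glm(yb ~ x, family = binomial(),
            control = glm.control(epsilon = 1e-8, maxit = 100)))
    pr <- fitted(fit)
    eps <- 1e-8
    separation <- !fit$converged || all(pr > 1 - eps | pr < eps) ||
        abs(coef(fit)[[2L]]) > 1e3 / max(sd(x), .Machine$double.eps)
    list(intercept = coef(fit)[[1L]], slope = coef(fit)[[2L]],
         fitted = as.numeric(pr), separation = separation,
         converged = fit$converged)
}

#' Binormal ROC analysis of a single feature
#'
#' Fits a Gaussian to each class by sample moments and evaluates the binormal
#' ROC: with positive class N(mu1, sigma1) and negative class N(mu0, sigma0),
#' and the convention that a higher score is called more positive,
#' TPR(c) = 1 - Phi((c - mu1)/sigma1), FPR(c) = 1 - Phi((c - mu0)/sigma0),
#' and AUC = Phi((mu1 - mu0)/sqrt(sigma0^2 + sigma1^2)). The AUC is not
#' forced above 0.5 unless `autoFlip = TRUE`, in which case the score sign is
#' inverted when the positive class scores lower. The 95% confidence interval
#' uses the Hanley-McNeil standard error by default, or a seeded bootstrap.
#'
#' @param x numeric feature values.
#' @param labels class labels (two classes).
#' @param positive the positive class label (explicit, no default
#'   convention).
#' @param autoFlip invert orientation when AUC < 0.5 (default FALSE).
#' @param ciMethod "hanley-mcneil" (default) or "bootstrap".
#' @param bootSamples,seed bootstrap resamples (default 2000) and seed.
#' @param nCurve number of cutoffs at which the curve is sampled.
#' @return List of class `"binormalRoc"`: auc, auc_ci (low/high), class
#'   moments, orientation (+1/-1), curve (data.frame cutoff, fpr, tpr),
#'   the input samples by class, positive label, n per class.
#' @export
#' @examples
#' set.seed(1)
#' roc <- binormalRoc(c(rnorm(20), rnorm(20, 1)),
#'                    rep(c("WT", "KO"), each = 20), positive = "KO")
#' roc$auc
binormalRoc <- function(x, labels, positive, autoFlip = FALSE,
                        ciMethod = c("hanley-mcneil", "bootstrap"),
                        bootSamples = 2000, seed = NULL, nCurve = 512) {
    ciMethod <- match.arg(ciMethod)
    ok <- complete.cases(x, labels)
    x <- x[ok]; labels <- labels[ok]
    classes <- unique(labels)
    if (length(classes) != 2L) stop("exactly two classes required")
    if (!positive %in% classes)
        stop("positive label not present: ", positive)
    negative <- setdiff(classes, positive)
    pos <- x[labels == positive]; neg <- x[labels == negative]
    if (length(pos) < 2L || length(neg) < 2L)
        stop("each class needs at least 2 observations")
    s1 <- sd(pos); s0 <- sd(neg)
    if (s1 == 0 && s0 == 0 && mean(pos) == mean(neg))
        stop("undefined AUC: both classes constant and equal")

    orientation <- 1
    if (autoFlip && mean(pos) < mean(neg)) orientation <- -1
    m1 <- mean(orientation * pos); m0 <- mean(orientation * neg)
    auc <- pnorm((m1 - m0) / sqrt(s0^2 + s1^2))

    n1 <- length(pos); n0 <- length(neg)
    if (ciMethod == "hanley-mcneil") {
        q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
        se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                    (n0 - 1) * (q2 - auc^2)) / (as.numeric(n0) * n1))
        ci <- c(auc - qnorm(0.975) * se, auc + qnorm(0.975) * se)
    } else {
        if (is.null(seed)) stop("bootstrap CI requires a seed")
        set.seed(as.integer(seed))
        boot <- vapply(seq_len(bootSamples), function(b) {
            p <- sample(pos, n1, replace = TRUE)
            q <- sample(neg, n0, replace = TRUE)
            sp <- sd(p); sq <- sd(q)
            if (sp == 0 && sq == 0) return(NA_real_)
            pnorm((orientation * (mean(p) - mean(q))) / sqrt(sp^2 + sq^2))
        }, numeric(1))
        ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
    }
    ci <- pmin(1, pmax(0, ci))

    lo <- min(m0 - 4 * max(s0, 1e-12), m1 - 4 * max(s1, 1e-12))
    hi <- max(m0 + 4 * max(s0, 1e-12), m1 + 4 * max(s1, 1e-12))
    cut <- seq(lo, hi, length.out = nCurve)
    curve <- data.frame(cutoff = cut,
                        fpr = 1 - pnorm((cut - m0) / max(s0, 1e-12)),
                        tpr = 1 - pnorm((cut - m1) / max(s1, 1e-12)))

    structure(list(auc = auc, auc_ci = ci, positive = positive,
                   negative = negative, orientation = orientation,
                   mu_pos = m1, sd_pos = s1, mu_neg = m0, sd_neg = s0,
                   n_pos = n1, n_neg = n0, curve = curve,
                   samples_pos = orientation * pos,
                   samples_neg = orientation * neg,
                   ci_method = ciMethod),
              class = "binormalRoc")
}

#' @export
print.binormalRoc <- function(x, ...) {
    cat(sprintf("Binormal ROC (positive = %s, n = %d vs %d): AUC %.3f [%.3f, %.3f] (%s)\n",
                x$positive, x$n_pos, x$n_neg, x$auc, x$auc_ci[1L],
                x$auc_ci[2L], x$ci_method))
    invisible(x)
}

#' Youden-optimal cutoff on a binormal ROC
#'
#' Maximizes the Youden index J(c) = sensitivity(c) + specificity(c) - 1
#' analytically on the binormal curve: the stationarity condition equates
#' the two class densities and reduces to a quadratic in the cutoff (the
#' midpoint (mu0 + mu1)/2 in the equal-variance case). Sensitivity and
#' specificity are reported as percentages, both from the binormal model and
#' empirically at the chosen cutoff. When the two class distributions
#' coincide, J = 0 everywhere and the result carries a `degenerate` flag.
#'
#' @param roc a `"binormalRoc"` object.
#' @return List: cutoff (original feature units), youden_j, sensitivity_pct,
#'   specificity_pct (binormal), sensitivity_emp_pct, specificity_emp_pct
#'   (empirical at the cutoff), degenerate flag.
#' @export
optimalCutoff <- function(roc) {
    stopifnot(inherits(roc, "binormalRoc"))
    m0 <- roc$mu_neg; m1 <- roc$mu_pos
    s0 <- max(roc$sd_neg, 1e-12); s1 <- max(roc$sd_pos, 1e-12)

    degenerate <- isTRUE(all.equal(m0, m1)) && isTRUE(all.equal(s0, s1))
    if (degenerate) {
        cands <- m0
    } else if (abs(1 / s0^2 - 1 / s1^2) < 1e-12) {
        cands <- (m0 + m1) / 2
    } else {
        A <- 1 / s0^2 - 1 / s1^2
        Bq <- -2 * (m0 / s0^2 - m1 / s1^2)
        Cq <- m0^2 / s0^2 - m1^2 / s1^2 - 2 * log(s1 / s0)
        disc <- Bq^2 - 4 * A * Cq
        cands <- if (disc >= 0)
            c((-Bq + sqrt(disc)) / (2 * A), (-Bq - sqrt(disc)) / (2 * A))
        else seq(min(m0, m1) - 3 * max(s0, s1),
                 max(m0, m1) + 3 * max(s0, s1), length.out = 1e4)
    }
    J <- function(c) (1 - pnorm((c - m1) / s1)) - (1 - pnorm((c - m0) / s0))
    j <- vapply(cands, J, numeric(1))
    best <- cands[which.max(j)]

    sens <- 100 * (1 - pnorm((best - m1) / s1))
    spec <- 100 * pnorm((best - m0) / s0)
    sensEmp <- 100 * mean(roc$samples_pos > best)
    specEmp <- 100 * mean(roc$samples_neg <= best)
    list(cutoff = roc$orientation * best, youden_j = max(j),
         sensitivity_pct = sens, specificity_pct = spec,
         sensitivity_emp_pct = sensEmp, specificity_emp_pct = specEmp,
         degenerate = degenerate)
}

#' Biomarker table: logistic fit + binormal ROC per feature
#'
#' Evaluates the genotype-discrimination power of each requested feature in
#' a region: simple logistic regression (in-sample, as a deliberate
#' small-sample choice), binormal ROC AUC with 95% CI, Youden-optimal cutoff
#' with sensitivity and specificity.
#'
#' @param se feature table from [buildFeatureTable()].
#' @param features feature names to evaluate.
#' @param region voxel region.
#' @param positive positive class label (explicit; "WT" or "KO").
#' @param ... passed to [binormalRoc()].
#' @return data.frame, one row per feature: auc, auc_ci_low/high, cutoff,
#'   sensitivity_pct, specificity_pct (empirical at the Youden cutoff),
#'   logit_intercept, logit_slope, separation.
#' @export
rocTable <- function(se, features, region, positive, ...) {
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    g <- as.character(SummarizedExperiment::colData(se)$genotype)
    a <- SummarizedExperiment::assay(se, "concentration")
    rows <- lapply(features, function(f) {
        i <- which(rd$region == region & rd$feature == f)
        if (!length(i)) stop("feature not found in region: ", f)
        x <- a[i, ]
        ok <- complete.cases(x, g)
        lg <- fitSimpleLogistic(x[ok], g[ok], positive = positive)
        roc <- binormalRoc(x[ok], g[ok], positive = positive, ...)
        oc <- optimalCutoff(roc)
        data.frame(feature = f, region = region, positive = positive,
                   n = sum(ok), auc = roc$auc,
                   auc_ci_low = roc$auc_ci[1L],
                   auc_ci_high = roc$auc_ci[2L],
                   cutoff = oc$cutoff,
                   sensitivity_pct = oc$sensitivity_emp_pct,
                   specificity_pct = oc$specificity_emp_pct,
                   logit_intercept = lg$intercept,
                   logit_slope = lg$slope,
                   separation = lg$separation,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
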