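#' Pearson product-moment correlation with validation
#'
#' Thin wrapper around the standard estimator that enforces the screen's
#' preconditions: pairwise-complete input, at least 3 pairs, both vectors
#' non-constant.
#'
#' @param x,y paired numeric vectors (pairs with any `NA` are dropped).
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearsonR <- function(x, y) {
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
        stop("insufficient data: need at least 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0)
        stop("undefined correlation: constant input")
    cor(x, y)
}

## Deterministic per-(feature, index) sub-seed from a master seed and a key
## string, so screen results do not depend on feature order.
.deriveSeed <- function(master, key) {
    h <- (as.double(master) %% 2147483563) + 1
    for (b in utf8ToInt(key))
        h <- (h * 31 + b) %% 2147483563
    as.integer(h)
}

#' Permutation p-value for a Pearson correlation
#'
#' Builds the empirical null by permuting `y` against fixed `x` and applies
#' the add-one convention p = (1 + #\{b : |r_b| >= |r_obs|\}) / (B + 1)
#' (two-sided default), so the p-value is never zero and is valid at finite
#' B. With `method = "exact"` all n! permutations are enumerated (n <= 9)
#' and p = #\{|r_b| >= |r_obs|\} / n!, which includes the identity
#' permutation and is therefore also never zero.
#'
#' @param x,y paired numeric vectors; pairs with `NA` dropped.
#' @param B number of sampled permutations (default 5000).
#' @param seed RNG seed; required for reproducible sampled permutations.
#' @param sidedness "two_sided" (default, on |r|), "greater" or "less".
#' @param method "sampled" (default) or "exact".
#' @return Numeric p-value, with attributes `r` (observed coefficient) and
#'   `B` (permutations used, or n! for exact).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(10)
#' permutationPvalue(x, x, B = 999, seed = 42)  # 1/1000
permutationPvalue <- function(x, y, B = 5000, seed = NULL,
                              sidedness = c("two_sided", "greater", "less"),
                              method = c("sampled", "exact")) {
    sidedness <- match.arg(sidedness)
    method <- match.arg(method)
    ok <- complete.cases(x, y)
    x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
    if (length(x) < 3L)
        stop("insufficient data: need at least 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0)
        stop("undefined correlation: constant input")
    sided <- switch(sidedness, two_sided = 0L, greater = 1L, less = -1L)
    if (method == "exact") {
        res <- .perm_null_exact(x, y, sided)
        p <- res$count / res$total
        attr(p, "r") <- res$r
        attr(p, "B") <- res$total
        return(p)
    }
    if (B < 1L) stop("B must be >= 1")
    if (!is.null(seed)) set.seed(as.integer(seed))
    res <- .perm_null_sampled(x, y, as.integer(B), sided)
    p <- (1 + res$count) / (B + 1)
    attr(p, "r") <- res$r
    attr(p, "B") <- as.integer(B)
    p
}

#' Correlation screen of metabolite features against a behavior index
#'
#' For every included feature in a region, computes the Pearson correlation
#' with the chosen behavior index on pairwise-complete animals, a
#' permutation-null p-value (per-feature RNG stream derived from the master
#' seed, so results are order-independent), the linear-fit slope/intercept
#' with 95% confidence half-widths, quantile tier flags (q95 iff p < 0.05,
#' q975 iff p < 0.025) and volcano coordinates (r, -log10 p). Features with
#' fewer than 3 complete pairs or constant values are skipped and listed in
#' the `"skipped"` attribute.
#'
#' @param se feature table from [buildFeatureTable()].
#' @param region voxel region to screen.
#' @param index behavior index column in `colData(se)`
#'   (default "pi_preference").
#' @param B permutations per feature (default 5000).
#' @param seed master seed (required).
#' @param sidedness passed to [permutationPvalue()].
#' @param includedOnly screen only features passing the inclusion rule.
#' @return data.frame: feature, region, index, n_pairs, r, r2, slope,
#'   intercept, slope_ci_half, p_perm, tier, neg_log10_p.
#' @export
#' @examples
#' coh <- simulateCohort(cohortSpec(), seed = 1)
#' se <- buildFeatureTable(coh)
#' head(screenFeatures(se, "PFC", B = 199, seed = 7))
screenFeatures <- function(se, region, index = "pi_preference", B = 5000,
                           seed, sidedness = "two_sided",
                           includedOnly = TRUE) {
    if (missing(seed) || is.null(seed))
        stop("a master seed is required for the permutation screen")
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    if (!index %in% names(cd))
        stop("behavior index not found: ", index)
    a <- SummarizedExperiment::assay(se, "concentration")
    sel <- rd$region == region & (!includedOnly | rd$included)
    if (!any(sel)) stop("no features to screen in region ", region)
    y <- cd[[index]]
    if (all(is.na(y))) stop("no overlapping animals with a defined index")

    skipped <- character()
    rows <- lapply(which(sel), function(i) {
        x <- a[i, ]
        ok <- complete.cases(x, y)
        if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
            skipped <<- c(skipped, rd$feature[i])
            return(NULL)
        }
        subSeed <- .deriveSeed(seed, paste(region, rd$feature[i], index))
        p <- permutationPvalue(y[ok], x[ok], B = B, seed = subSeed,
                               sidedness = sidedness)
        r <- pearsonR(x[ok], y[ok])
        fit <- lm(x[ok] ~ y[ok])
        ci <- suppressWarnings(stats::confint(fit))
        tier <- if (p < 0.025) "q975" else if (p < 0.05) "q95" else "none"
        data.frame(feature = rd$feature[i], region = region, index = index,
                   n_pairs = sum(ok), r = r, r2 = r^2,
                   slope = coef(fit)[[2L]], intercept = coef(fit)[[1L]],
                   slope_ci_half = (ci[2L, 2L] - ci[2L, 1L]) / 2,
                   p_perm = as.numeric(p), tier = tier,
                   neg_log10_p = -log10(as.numeric(p)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}

.tidyTTest <- function(a, b, variant) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 observations")
    if (var(a) == 0 && var(b) == 0) {
        if (mean(a) == mean(b)) {
            message("both groups constant and equal: p = 1 by convention")
            return(data.frame(n_a = length(a), n_b = length(b),
                              mean_a = mean(a), mean_b = mean(b),
                              sd_a = 0, sd_b = 0, t = 0,
                              df = length(a) + length(b) - 2, p = 1,
                              variant = variant, stringsAsFactors = FALSE))
        }
        stop("zero variance in both groups with unequal means")
    }
    tt <- t.test(a, b, var.equal = (variant == "student"))
    data.frame(n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               sd_a = sd(a), sd_b = sd(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, variant = variant, stringsAsFactors = FALSE)
}

#' Two-sample t tests (Welch and Student variants)
#'
#' Welch's unequal-variance t test with Satterthwaite (fractional) degrees of
#' freedom, or the pooled-variance Student variant with df = n_a + n_b - 2.
#' Two groups that are both constant and equal give p = 1 by convention
#' (with a message); constant and unequal is an error.
#'
#' @param a,b numeric group vectors (`NA` dropped).
#' @return One-row data.frame: group sizes, means, SDs, t, df, p, variant.
#' @export
welchTest <- function(a, b) .tidyTTest(a, b, "welch")

#' @rdname welchTest
#' @export
studentTest <- function(a, b) .tidyTTest(a, b, "student")

#' Genotype group tests for every included feature
#'
#' @param se feature table from [buildFeatureTable()].
#' @param variant "welch" (default) or "student".
#' @param includedOnly test only features passing the inclusion rule.
#' @return data.frame, one row per (region, feature): group ns, means, SDs,
#'   t, df, p.
#' @export
groupTests <- function(se, variant = c("welch", "student"),
                       includedOnly = TRUE) {
    variant <- match.arg(variant)
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    g <- SummarizedExperiment::colData(se)$genotype
    a <- SummarizedExperiment::assay(se, "concentration")
    sel <- which(!includedOnly | rd$included)
    rows <- lapply(sel, function(i) {
        wt <- a[i, g == "WT"]; ko <- a[i, g == "KO"]
        if (sum(!is.na(wt)) < 2L || sum(!is.na(ko)) < 2L) return(NULL)
        cbind(data.frame(region = rd$region[i], feature = rd$feature[i],
                         stringsAsFactors = FALSE),
              .tidyTTest(wt, ko, variant))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
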