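# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# all permutations of a vector, recursively (n small)
permnAll <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in permnAll(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

# exhaustive two-sided permutation p for Pearson r, straight from the
# definition (identity permutation included in the numerator)
exactPermPOracle <- function(x, y, sided = "two_sided") {
    robs <- cor(x, y)
    rs <- vapply(permnAll(seq_along(y)), function(p) cor(x, y[p]), 0)
    tol <- 1e-12
    hits <- switch(sided,
                   two_sided = abs(rs) >= abs(robs) - tol,
                   greater = rs >= robs - tol,
                   less = rs <= robs + tol)
    sum(hits) / length(rs)
}

# textbook balanced two-way ANOVA sums-of-squares decomposition
bruteAnovaOracle <- function(y, a, b) {
    g <- mean(y)
    ssA <- sum(tapply(y, a, function(v) length(v) * (mean(v) - g)^2))
    ssB <- sum(tapply(y, b, function(v) length(v) * (mean(v) - g)^2))
    cell <- tapply(y, list(a, b), mean)
    nc <- table(a, b)
    ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
    ssAB <- 0; ssE <- 0
    for (i in rownames(cell)) for (j in colnames(cell)) {
        ssAB <- ssAB + nc[i, j] * (cell[i, j] - ma[i] - mb[j] + g)^2
        res <- y[a == i & b == j] - cell[i, j]
        ssE <- ssE + sum(res^2)
    }
    dfA <- nlevels(factor(a)) - 1; dfB <- nlevels(factor(b)) - 1
    dfAB <- dfA * dfB
    dfE <- length(y) - nlevels(factor(a)) * nlevels(factor(b))
    mse <- ssE / dfE
    list(F = c(A = (ssA / dfA) / mse, B = (ssB / dfB) / mse,
               AB = (ssAB / dfAB) / mse),
         ss = c(A = ssA, B = ssB, AB = ssAB, E = ssE))
}

# empirical (trapezoidal / Mann-Whitney) AUC: P(pos > neg) + 0.5 P(tie)
empiricalAUC <- function(pos, neg) {
    r <- rank(c(pos, neg))
    n1 <- as.numeric(length(pos)); n0 <- as.numeric(length(neg))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a small fast cohort spec for structural tests (no signal unless given)
tinySpec <- function(genotypeEffects = list(), latentCoupling = list(), ...) {
    cohortSpec(nWt = 4L, nKo = 5L,
               metabolites = c("Glu", "GABA", "Cr", "PCr", "NAA"),
               genotypeEffects = genotypeEffects,
               latentCoupling = latentCoupling, ...)
}
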