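#' Three-chamber preference index
#'
#' PI = (et_target - et_other) / (et_target + et_other): +1 is exclusive
#' preference for the target (mouse, or novel mouse), 0 is indifference.
#' An animal that explored neither side has no defined PI and raises an
#' error rather than silently scoring 0.
#'
#' @param etTarget,etOther exploration times in seconds, >= 0 (vectorised).
#' @return Numeric preference index in \[-1, 1\].
#' @export
#' @examples
#' preferenceIndex(180, 60)   # 0.5
#' preferenceIndex(0, 50)     # -1
preferenceIndex <- function(etTarget, etOther) {
    if (any(etTarget < 0 | etOther < 0))
        stop("exploration times must be >= 0")
    tot <- etTarget + etOther
    if (any(tot == 0))
        stop("undefined preference index: zero total exploration time; ",
             "exclude the animal explicitly")
    (etTarget - etOther) / tot
}

#' Percentage of investigation time on one side
#'
#' 100 * et_a / (et_a + et_b); the two sides sum to 100. Equals
#' 50 * (1 + PI) when `et_a` is the target side.
#'
#' @param etA,etB exploration times in seconds, >= 0 (vectorised).
#' @return Percentage in \[0, 100\].
#' @export
percentInvestigation <- function(etA, etB) {
    if (any(etA < 0 | etB < 0))
        stop("exploration times must be >= 0")
    tot <- etA + etB
    if (any(tot == 0))
        stop("undefined percentage: zero total exploration time")
    100 * etA / tot
}

#' Per-animal behavior indices from a cohort
#'
#' One row per animal with the social-preference and social-recognition
#' preference indices and per-side investigation percentages. Animals with
#' zero total exploration in a session are dropped with a message (the PI is
#' undefined for them) and listed in the `excluded` attribute.
#'
#' @param x a [MrsCohort-class] or a behavior data.frame with columns
#'   id, genotype, session, et_target, et_other.
#' @return data.frame: id, genotype, pi_preference, pi_recognition,
#'   pct_target_preference, pct_target_recognition.
#' @export
behaviorTable <- function(x) {
    beh <- if (is(x, "MrsCohort")) animals(x) else x
    bad <- beh$et_target + beh$et_other == 0
    excluded <- beh[bad, c("id", "session")]
    if (nrow(excluded)) {
        message("excluding ", nrow(excluded),
                " animal-session(s) with zero exploration: ",
                paste(excluded$id, excluded$session, collapse = "; "))
        beh <- beh[!bad, , drop = FALSE]
    }
    wide <- NULL
    for (ses in unique(beh$session)) {
        sub <- beh[beh$session == ses, , drop = FALSE]
        d <- data.frame(id = sub$id, genotype = sub$genotype,
                        stringsAsFactors = FALSE)
        d[[paste0("pi_", ses)]] <-
            preferenceIndex(sub$et_target, sub$et_other)
        d[[paste0("pct_target_", ses)]] <-
            percentInvestigation(sub$et_target, sub$et_other)
        wide <- if (is.null(wide)) d else
            merge(wide, d, by = c("id", "genotype"), all = TRUE)
    }
    wide <- wide[order(match(wide$id, unique(beh$id))), , drop = FALSE]
    rownames(wide) <- NULL
    attr(wide, "excluded") <- excluded
    wide
}

#' Two-way ANOVA (genotype x target) with Sidak pairwise contrasts
#'
#' Ordinary two-way ANOVA with interaction on a long table of investigation
#' values (each animal contributing one value per target side), as used for
#' three-chamber sessions: factors are genotype (WT/KO) and target
#' (e.g. mouse vs empty). Pairwise within-genotype target contrasts use the
#' ANOVA error mean square and residual degrees of freedom, with Sidak
#' adjustment p_adj = 1 - (1 - p)^k over the k contrasts.
#'
#' @param data data.frame with the response and the two factor columns.
#' @param value,factorA,factorB column names: response, genotype-like factor,
#'   target-like factor.
#' @return List with `anova` (data.frame: term, df, sum_sq, mean_sq, F, p)
#'   and `contrasts` (data.frame: one row per level of `factorA`, with the
#'   within-level difference between `factorB` levels, t, df, raw and
#'   Sidak-adjusted p).
#' @export
twoWayAnovaSidak <- function(data, value = "value", factorA = "genotype",
                             factorB = "target") {
    a <- factor(data[[factorA]])
    b <- factor(data[[factorB]])
    y <- data[[value]]
    if (nlevels(a) != 2L || nlevels(b) != 2L)
        stop("both factors must have exactly two levels")
    if (any(table(a, b) < 2L))
        stop("every genotype x target cell needs >= 2 observations")

    fit <- aov(y ~ a * b)
    tab <- summary(fit)[[1L]]
    anova_df <- data.frame(
        term = c(factorA, factorB, paste0(factorA, ":", factorB),
                 "residuals"),
        df = tab[["Df"]],
        sum_sq = tab[["Sum Sq"]],
        mean_sq = tab[["Mean Sq"]],
        F = tab[["F value"]],
        p = tab[["Pr(>F)"]],
        stringsAsFactors = FALSE
    )

    mse <- tab[["Mean Sq"]][4L]
    dfe <- tab[["Df"]][4L]
    k <- nlevels(a)
    contrasts <- do.call(rbind, lapply(levels(a), function(lv) {
        sel <- a == lv
        y1 <- y[sel & b == levels(b)[1L]]
        y2 <- y[sel & b == levels(b)[2L]]
        diff <- mean(y1) - mean(y2)
        se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
        tval <- diff / se
        p <- 2 * pt(-abs(tval), dfe)
        data.frame(level = lv,
                   comparison = paste(levels(b)[1L], "vs", levels(b)[2L]),
                   difference = diff, t = tval, df = dfe, p = p,
                   p_sidak = 1 - (1 - p)^k,
                   stringsAsFactors = FALSE)
    }))
    list(anova = anova_df, contrasts = contrasts)
}
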