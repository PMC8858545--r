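#' Invert a preference index into a pair of exploration times
#'
#' Splits a total exploration time into target/other components whose
#' preference index, (et_target - et_other) / (et_target + et_other), equals
#' `pi` exactly.
#'
#' @param pi preference index in \[-1, 1\].
#' @param totalTime total exploration time in seconds, > 0.
#' @return Named numeric: `et_target`, `et_other` (seconds).
#' @export
#' @examples
#' explorationTimesFromPI(0.5, 400)  # 300, 100
explorationTimesFromPI <- function(pi, totalTime) {
    if (any(abs(pi) > 1))
        stop("preference index must lie in [-1, 1]")
    if (any(totalTime <= 0))
        stop("totalTime must be > 0")
    c(et_target = totalTime * (1 + pi) / 2,
      et_other = totalTime * (1 - pi) / 2)
}

## Canonical feature definitions shared by the feature builder and the
## generative truth calculations: sums first, then ratios.
.featureDefs <- function() {
    list(
        tCr = list(num = c("Cr", "PCr"), den = NULL),
        Glx = list(num = c("Gln", "Glu"), den = NULL),
        `Glu/GABA` = list(num = "Glu", den = "GABA"),
        `GABA/Glu` = list(num = "GABA", den = "Glu"),
        `NAA/tCr` = list(num = "NAA", den = c("Cr", "PCr")),
        `PCr/tCr` = list(num = "PCr", den = c("Cr", "PCr"))
    )
}

#' Simulate a cohort from a generative specification
#'
#' Draws one latent sociability score per animal (unit-SD Gaussian around
#' its genotype mean), converts it to per-session preference indices with
#' additive Gaussian noise (clipped to \[-1, 1\] via the time allocation),
#' and generates every (region, metabolite) concentration as
#' baseline + genotype shift + coupling x latent + Gaussian noise, with an
#' independent shifted-gamma CRLB percent SD per measurement. All draws flow
#' from the single `seed`, so runs are reproducible.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer master seed (required).
#' @return A [MrsCohort-class]; its truth record stores the spec, seed and
#'   per-animal latent scores.
#' @export
#' @examples
#' coh <- simulateCohort(cohortSpec(), seed = 1)
#' coh
simulateCohort <- function(spec, seed) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    if (missing(seed) || is.null(seed))
        stop("a seed is required: the cohort is a random draw")
    set.seed(as.integer(seed))

    n <- spec@nWt + spec@nKo
    id <- c(sprintf("WT%02d", seq_len(spec@nWt)),
            sprintf("KO%02d", seq_len(spec@nKo)))
    genotype <- rep(c("WT", "KO"), c(spec@nWt, spec@nKo))
    s <- rnorm(n, mean = spec@latentMeans[genotype], sd = 1)

    sessions <- c("preference", "recognition")
    beh <- do.call(rbind, lapply(sessions, function(ses) {
        piRaw <- spec@piIntercept[[ses]] + spec@piLatentSlope[[ses]] * s +
            rnorm(n, 0, spec@behaviorNoiseSd)
        piClip <- pmin(1, pmax(-1, piRaw))
        total <- runif(n, spec@totalTimeRange[1L], spec@totalTimeRange[2L])
        data.frame(id = id, genotype = genotype, session = ses,
                   et_target = total * (1 + piClip) / 2,
                   et_other = total * (1 - piClip) / 2,
                   stringsAsFactors = FALSE)
    }))
    rownames(beh) <- NULL

    grid <- expand.grid(metabolite = spec@metabolites,
                        region = spec@regions,
                        stringsAsFactors = FALSE)
    meas <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
        m <- grid$metabolite[k]; rg <- grid$region[k]
        mu <- spec@baselineMeans[rg, m] +
            spec@genotypeEffects[rg, m] * (genotype == "KO") +
            spec@latentCoupling[rg, m] * s
        conc <- pmax(0, rnorm(n, mu, spec@baselineSds[rg, m]))
        crlb <- spec@crlbShift[[m]] +
            rgamma(n, shape = spec@crlbShape[[m]],
                   scale = spec@crlbScale[[m]])
        data.frame(id = id, region = rg, metabolite = m,
                   concentration = conc, crlb_pct = crlb,
                   stringsAsFactors = FALSE)
    }))
    rownames(meas) <- NULL

    truth <- list(
        seed = as.integer(seed),
        latent = setNames(s, id),
        genotype = setNames(genotype, id),
        spec = spec
    )
    new("MrsCohort", animals = beh, measurements = meas, truth = truth)
}

## Group moments (mean, variance) of a feature under the generative model.
## Raw metabolites are exactly Gaussian; sums are Gaussian with the shared
## latent inducing covariance; ratios use the first-order delta method.
.truthMoments <- function(spec, feature, region, genotype) {
    mu_s <- spec@latentMeans[[genotype]]
    met <- spec@metabolites
    mean1 <- function(m) spec@baselineMeans[region, m] +
        spec@genotypeEffects[region, m] * (genotype == "KO") +
        spec@latentCoupling[region, m] * mu_s
    compMoments <- function(parts) {
        mu <- sum(vapply(parts, mean1, 0))
        cpl <- sum(spec@latentCoupling[region, parts])
        v <- sum(spec@baselineSds[region, parts]^2) + cpl^2
        c(mean = mu, var = v, coupling = cpl)
    }
    defs <- .featureDefs()
    if (feature %in% met) {
        mm <- compMoments(feature)
        return(c(mean = mm[["mean"]], var = mm[["var"]]))
    }
    if (!feature %in% names(defs))
        stop("unknown feature: ", feature)
    d <- defs[[feature]]
    a <- compMoments(d$num)
    if (is.null(d$den))
        return(c(mean = a[["mean"]], var = a[["var"]]))
    b <- compMoments(d$den)
    shared <- intersect(d$num, d$den)
    covab <- a[["coupling"]] * b[["coupling"]] +
        sum(spec@baselineSds[region, shared]^2)
    r <- a[["mean"]] / b[["mean"]]
    v <- r^2 * (a[["var"]] / a[["mean"]]^2 + b[["var"]] / b[["mean"]]^2 -
                2 * covab / (a[["mean"]] * b[["mean"]]))
    c(mean = r, var = max(v, 0))
}

#' Generative (closed-form) AUC of a feature for genotype discrimination
#'
#' Under the generative model each group's feature distribution is Gaussian
#' (exactly for raw metabolites and sums; to first order, via the delta
#' method, for ratios), so the binormal AUC
#' \eqn{\Phi((\mu_{pos}-\mu_{neg})/\sqrt{\sigma_{pos}^2+\sigma_{neg}^2})}
#' is available in closed form. Used as ground truth for parameter-recovery
#' checks.
#'
#' @param spec a [CohortSpec-class] (or the `spec` element of a cohort truth
#'   record).
#' @param feature a raw metabolite name or a derived feature
#'   ("tCr", "Glx", "Glu/GABA", "GABA/Glu", "NAA/tCr", "PCr/tCr").
#' @param region voxel region.
#' @param positive which genotype counts as the positive class
#'   (default "WT": the class with the higher Glu/GABA under the defaults).
#' @return The generative AUC in \[0, 1\].
#' @export
#' @examples
#' generativeAUC(cohortSpec(), "Glu/GABA", "PFC", positive = "WT")
generativeAUC <- function(spec, feature, region, positive = "WT") {
    if (is(spec, "MrsCohort")) spec <- cohortTruth(spec)$spec
    negative <- setdiff(c("WT", "KO"), positive)
    p <- .truthMoments(spec, feature, region, positive)
    q <- .truthMoments(spec, feature, region, negative)
    pnorm((p[["mean"]] - q[["mean"]]) / sqrt(p[["var"]] + q[["var"]]))
}

#' Write a cohort to disk as plain-text tables
#'
#' Writes `animals.csv` (id, genotype, session, et_target, et_other),
#' `metabolites.csv` (id, region, metabolite, concentration, crlb_pct) and,
#' for simulated cohorts, `truth.json` with the generative parameters.
#'
#' @param cohort a [MrsCohort-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "MrsCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pa <- file.path(dir, "animals.csv")
    pm <- file.path(dir, "metabolites.csv")
    write.csv(animals(cohort), pa, row.names = FALSE)
    write.csv(measurements(cohort), pm, row.names = FALSE)
    paths <- c(pa, pm)
    tr <- cohortTruth(cohort)
    if (length(tr)) {
        pt <- file.path(dir, "truth.json")
        sp <- tr$spec
        out <- list(
            seed = tr$seed,
            latent = as.list(tr$latent),
            nWt = sp@nWt, nKo = sp@nKo,
            metabolites = sp@metabolites, regions = sp@regions,
            baselineMeans = as.data.frame(sp@baselineMeans),
            baselineSds = as.data.frame(sp@baselineSds),
            genotypeEffects = as.data.frame(sp@genotypeEffects),
            latentCoupling = as.data.frame(sp@latentCoupling),
            crlb = list(shift = as.list(sp@crlbShift),
                        shape = as.list(sp@crlbShape),
                        scale = as.list(sp@crlbScale)),
            latentMeans = as.list(sp@latentMeans),
            piIntercept = as.list(sp@piIntercept),
            piLatentSlope = as.list(sp@piLatentSlope),
            behaviorNoiseSd = sp@behaviorNoiseSd,
            totalTimeRange = sp@totalTimeRange
        )
        jsonlite::write_json(out, pt, auto_unbox = TRUE, digits = NA)
        paths <- c(paths, pt)
    }
    invisible(paths)
}

#' Read a cohort from `animals.csv` / `metabolites.csv`
#'
#' @param dir directory containing the two tables (as written by
#'   [writeCohort()]).
#' @return A [MrsCohort-class] with an empty truth record.
#' @export
readCohort <- function(dir) {
    beh <- read.csv(file.path(dir, "animals.csv"), stringsAsFactors = FALSE)
    meas <- read.csv(file.path(dir, "metabolites.csv"),
                     stringsAsFactors = FALSE)
    new("MrsCohort", animals = beh, measurements = meas, truth = list())
}
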