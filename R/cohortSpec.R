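## Default generative parameters for the synthetic cohort.
##
## Baseline concentrations are typical rodent-brain values at high field in
## arbitrary (roughly mM-like) units; SDs ~8-12% CV. The CRLB model is a
## shifted gamma whose scale grows as concentration falls, so low-abundance
## metabolites (Scyllo, NAAG, PCh, ...) occasionally exceed the 50% filter
## threshold and exercise the quality-control path.

.defaultBaselineMeans <- function(metabolites) {
    full <- c(Ala = 0.8, Asp = 2.5, Cr = 4.0, PCr = 4.0, GABA = 2.5,
              Glc = 1.5, Gln = 3.0, Glu = 10.0, GSH = 1.5, GPC = 0.8,
              Lac = 1.5, Ins = 5.5, NAA = 8.5, NAAG = 0.6, PCh = 0.6,
              Scyllo = 0.2, Tau = 8.0)
    full[metabolites]
}

.defaultBaselineSds <- function(metabolites) {
    means <- .defaultBaselineMeans(metabolites)
    sds <- 0.10 * means
    # glutamate pinned a bit tighter: 8% CV, the best-determined large signal
    if ("Glu" %in% metabolites) sds["Glu"] <- 0.08 * means["Glu"]
    sds
}

.namedMatrix <- function(regions, metabolites, entries = NULL) {
    m <- matrix(0, length(regions), length(metabolites),
                dimnames = list(regions, metabolites))
    if (!is.null(entries))
        for (e in entries) m[e[[1]], e[[2]]] <- e[[3]]
    m
}

#' Construct a cohort generative specification
#'
#' Builds a [CohortSpec-class] describing a two-genotype (wild-type vs
#' knockout) MRS/behavior cohort generated from a single latent sociability
#' score per animal: the score drives both the three-chamber preference index
#' and any latent-coupled metabolite concentrations, so a genotype difference
#' and a behavior-metabolite correlation arise from one mechanism.
#'
#' Default effect sizes (knockout shifts: prefrontal Glu down / GABA up, so
#' the Glu/GABA excitation-inhibition proxy falls; Cr and PCr down, so tCr
#' falls and NAA/tCr rises; hippocampal Glu and Gln up, so Glx rises) and the
#' default latent coupling on prefrontal Glu/Cr/PCr are sized so the
#' generative (delta-method) AUC of the prefrontal Glu/GABA ratio for
#' genotype discrimination is about 0.84 at the default 9 + 11 group sizes.
#'
#' @param nWt,nKo group sizes (default 9 wild-type, 11 knockout).
#' @param metabolites metabolite panel, subset of [metaboliteVocabulary()].
#' @param regions voxel regions, subset of [brainRegions()].
#' @param baselineMeans,baselineSds named numeric per metabolite, or
#'   region x metabolite matrices; defaults as described above.
#' @param genotypeEffects list of `list(region, metabolite, shift)` additive
#'   knockout shifts (concentration units), or a full matrix.
#' @param latentCoupling list of `list(region, metabolite, slope)`
#'   concentration change per unit latent score, or a full matrix.
#' @param crlbShift,crlbShape,crlbScale per-metabolite shifted-gamma CRLB
#'   parameters (percent SD); scalar values are recycled.
#' @param latentMeans genotype means of the unit-SD latent score,
#'   named `c(WT, KO)`.
#' @param piIntercept,piLatentSlope per-session PI model, named
#'   `c(preference, recognition)`.
#' @param behaviorNoiseSd PI residual SD.
#' @param totalTimeRange uniform range (seconds) of per-session total
#'   exploration time.
#' @return A validated [CohortSpec-class].
#' @export
#' @examples
#' spec <- cohortSpec()
#' spec
cohortSpec <- function(nWt = 9L, nKo = 11L,
                       metabolites = metaboliteVocabulary(),
                       regions = brainRegions(),
                       baselineMeans = NULL,
                       baselineSds = NULL,
                       genotypeEffects = list(
                           list("PFC", "Glu", -0.2),
                           list("PFC", "GABA", +0.12),
                           list("PFC", "Cr", -0.3),
                           list("PFC", "PCr", -0.3),
                           list("HPC", "Glu", +0.5),
                           list("HPC", "Gln", +0.4)),
                       latentCoupling = list(
                           list("PFC", "Glu", 0.7),
                           list("PFC", "Cr", 0.12),
                           list("PFC", "PCr", 0.12)),
                       crlbShift = NULL, crlbShape = 2, crlbScale = NULL,
                       latentMeans = c(WT = 2, KO = 0),
                       piIntercept = c(preference = 0, recognition = 0.2),
                       piLatentSlope = c(preference = 0.3,
                                         recognition = 0.05),
                       behaviorNoiseSd = 0.15,
                       totalTimeRange = c(80, 160)) {
    metabolites <- as.character(metabolites)
    regions <- as.character(regions)
    unknown <- setdiff(metabolites, metaboliteVocabulary())
    if (length(unknown))
        stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))

    asMatrix <- function(x, default) {
        if (is.null(x)) x <- default
        if (is.matrix(x)) {
            x[regions, metabolites, drop = FALSE]
        } else {
            m <- .namedMatrix(regions, metabolites)
            m[] <- rep(x[metabolites], each = length(regions))
            m
        }
    }
    bm <- asMatrix(baselineMeans, .defaultBaselineMeans(metabolites))
    bs <- asMatrix(baselineSds, .defaultBaselineSds(metabolites))

    asEffects <- function(x) {
        if (is.matrix(x)) return(x[regions, metabolites, drop = FALSE])
        for (e in x) {
            if (!e[[2]] %in% metabolites)
                stop("effect/coupling references unknown feature: ", e[[2]])
            if (!e[[1]] %in% regions)
                stop("effect/coupling references unknown region: ", e[[1]])
        }
        .namedMatrix(regions, metabolites, x)
    }
    ge <- asEffects(genotypeEffects)
    lc <- asEffects(latentCoupling)

    perMet <- function(x, default) {
        if (is.null(x)) x <- default
        if (length(x) == 1L) x <- rep(x, length(metabolites))
        if (is.null(names(x))) names(x) <- metabolites
        x[metabolites]
    }
    means <- bm[1L, ]
    shift <- perMet(crlbShift, 3)
    shape <- perMet(crlbShape, 2)
    scale <- perMet(crlbScale, pmax(1, 25 / (means + 1)))

    new("CohortSpec",
        nWt = as.integer(nWt), nKo = as.integer(nKo),
        metabolites = metabolites, regions = regions,
        baselineMeans = bm, baselineSds = bs,
        genotypeEffects = ge, latentCoupling = lc,
        crlbShift = shift, crlbShape = shape, crlbScale = scale,
        latentMeans = latentMeans,
        piIntercept = piIntercept, piLatentSlope = piLatentSlope,
        behaviorNoiseSd = behaviorNoiseSd,
        totalTimeRange = totalTimeRange)
}

#' A zero-signal cohort specification
#'
#' Convenience spec with no genotype effects, no latent-metabolite coupling
#' and equal latent means across genotypes, used for null calibration of the
#' downstream screen and group tests.
#'
#' @param ... passed to [cohortSpec()].
#' @return A [CohortSpec-class] with all signal parameters zeroed.
#' @export
nullCohortSpec <- function(...) {
    cohortSpec(genotypeEffects = list(), latentCoupling = list(),
               latentMeans = c(WT = 0, KO = 0), ...)
}
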