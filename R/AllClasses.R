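#' @import methods
#' @importFrom stats rnorm rgamma runif sd var cor pnorm qnorm dnorm pt qt
#'   t.test aov anova lm glm binomial coef fitted glm.control complete.cases
#'   setNames quantile
#' @importFrom utils write.csv read.csv write.table read.table packageVersion
#' @useDynLib socialMRS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Vocabulary of quantified metabolites
#'
#' The 17 metabolites quantified per brain voxel: alanine (Ala), aspartate
#' (Asp), creatine (Cr), phosphocreatine (PCr), GABA, glucose (Glc),
#' glutamine (Gln), glutamate (Glu), glutathione (GSH),
#' glycerophosphorylcholine (GPC), lactate (Lac), myo-inositol (Ins),
#' N-acetylaspartate (NAA), N-acetylaspartylglutamate (NAAG),
#' phosphorylcholine (PCh), scyllo-inositol (Scyllo) and taurine (Tau).
#'
#' @return Character vector of the 17 metabolite names.
#' @export
#' @examples
#' metaboliteVocabulary()
metaboliteVocabulary <- function() {
    c("Ala", "Asp", "Cr", "PCr", "GABA", "Glc", "Gln", "Glu", "GSH",
      "GPC", "Lac", "Ins", "NAA", "NAAG", "PCh", "Scyllo", "Tau")
}

#' Brain regions covered by the voxel panel
#'
#' @return Character vector: prefrontal cortex ("PFC") and hippocampus
#'   ("HPC").
#' @export
brainRegions <- function() c("PFC", "HPC")

#' CohortSpec: generative description of a synthetic MRS/behavior cohort
#'
#' Holds every parameter of the latent-sociability generative model: group
#' sizes, per-(region, metabolite) baseline means and SDs (arbitrary
#' concentration units), genotype mean shifts in knockouts, couplings of
#' metabolite concentrations to the latent sociability score, the CRLB
#' distribution model (shifted gamma, percent SD), and the behavioral
#' parameters mapping latent sociability to preference indices.
#'
#' @slot nWt,nKo integer group sizes (wild-type, knockout).
#' @slot metabolites character, subset of [metaboliteVocabulary()].
#' @slot regions character, subset of [brainRegions()].
#' @slot baselineMeans,baselineSds numeric matrices (region x metabolite),
#'   concentration units.
#' @slot genotypeEffects numeric matrix (region x metabolite): additive mean
#'   shift in KO animals, concentration units.
#' @slot latentCoupling numeric matrix (region x metabolite): concentration
#'   change per unit latent sociability.
#' @slot crlbShift,crlbShape,crlbScale named numeric per metabolite: CRLB
#'   percent SD is drawn as shift + Gamma(shape, scale).
#' @slot latentMeans numeric length 2, named WT/KO: genotype means of the
#'   unit-variance latent sociability score.
#' @slot piIntercept,piLatentSlope named numeric per session
#'   ("preference", "recognition"): PI = intercept + slope * latent + noise.
#' @slot behaviorNoiseSd numeric, PI units.
#' @slot totalTimeRange numeric length 2, seconds: uniform range of the total
#'   exploration time per session.
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
    nWt = "integer",
    nKo = "integer",
    metabolites = "character",
    regions = "character",
    baselineMeans = "matrix",
    baselineSds = "matrix",
    genotypeEffects = "matrix",
    latentCoupling = "matrix",
    crlbShift = "numeric",
    crlbShape = "numeric",
    crlbScale = "numeric",
    latentMeans = "numeric",
    piIntercept = "numeric",
    piLatentSlope = "numeric",
    behaviorNoiseSd = "numeric",
    totalTimeRange = "numeric"
))

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (object@nWt < 2L || object@nKo < 2L)
        msg <- c(msg, "nWt and nKo must both be >= 2")
    if (!all(object@metabolites %in% metaboliteVocabulary()))
        msg <- c(msg, sprintf(
            "unknown metabolite(s): %s",
            paste(setdiff(object@metabolites, metaboliteVocabulary()),
                  collapse = ", ")))
    if (anyDuplicated(object@metabolites))
        msg <- c(msg, "duplicated metabolite names")
    if (!all(object@regions %in% brainRegions()))
        msg <- c(msg, "regions must be a subset of brainRegions()")
    dn <- list(object@regions, object@metabolites)
    for (nm in c("baselineMeans", "baselineSds", "genotypeEffects",
                 "latentCoupling")) {
        m <- slot(object, nm)
        if (!identical(dim(m), c(length(dn[[1]]), length(dn[[2]]))) ||
            !identical(rownames(m), dn[[1]]) ||
            !identical(colnames(m), dn[[2]]))
            msg <- c(msg, sprintf("%s must be a regions x metabolites matrix",
                                  nm))
    }
    if (!length(msg) && any(object@baselineSds <= 0))
        msg <- c(msg, "all baselineSds must be > 0")
    for (nm in c("crlbShift", "crlbShape", "crlbScale")) {
        v <- slot(object, nm)
        if (!identical(names(v), object@metabolites))
            msg <- c(msg, sprintf("%s must be named by metabolite", nm))
        else if (any(v < 0))
            msg <- c(msg, sprintf("%s must be >= 0", nm))
    }
    if (!identical(names(object@latentMeans), c("WT", "KO")))
        msg <- c(msg, "latentMeans must be named c(WT, KO)")
    sess <- c("preference", "recognition")
    if (!identical(names(object@piIntercept), sess) ||
        !identical(names(object@piLatentSlope), sess))
        msg <- c(msg, "piIntercept/piLatentSlope must be named by session")
    if (object@behaviorNoiseSd < 0)
        msg <- c(msg, "behaviorNoiseSd must be >= 0")
    if (length(object@totalTimeRange) != 2L ||
        any(object@totalTimeRange <= 0) ||
        diff(object@totalTimeRange) < 0)
        msg <- c(msg, "totalTimeRange must be positive and non-decreasing")
    if (length(msg)) msg else TRUE
})

#' MrsCohort: one simulated (or assembled) cohort
#'
#' Container pairing the behavior table (one row per animal per session, with
#' exploration times) with the long quantified-metabolite table (one row per
#' animal x region x metabolite, with concentration and CRLB percent SD) and,
#' for simulated cohorts, the generative truth record.
#'
#' @slot animals data.frame: id, genotype, session, et_target, et_other.
#' @slot measurements data.frame: id, region, metabolite, concentration,
#'   crlb_pct.
#' @slot truth list of generative parameters (empty for assembled cohorts).
#' @exportClass MrsCohort
setClass("MrsCohort", representation(
    animals = "data.frame",
    measurements = "data.frame",
    truth = "list"
))

setValidity("MrsCohort", function(object) {
    msg <- character()
    need_a <- c("id", "genotype", "session", "et_target", "et_other")
    if (!all(need_a %in% names(object@animals)))
        msg <- c(msg, paste("animals must have columns:",
                            paste(need_a, collapse = ", ")))
    need_m <- c("id", "region", "metabolite", "concentration", "crlb_pct")
    if (!all(need_m %in% names(object@measurements)))
        msg <- c(msg, paste("measurements must have columns:",
                            paste(need_m, collapse = ", ")))
    if (!length(msg)) {
        key <- with(object@measurements, paste(id, region, metabolite))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (id, region, metabolite) measurement")
        if (any(object@animals$et_target < 0 | object@animals$et_other < 0))
            msg <- c(msg, "exploration times must be >= 0")
        if (!all(object@animals$genotype %in% c("WT", "KO")))
            msg <- c(msg, "genotype must be WT or KO")
    }
    if (length(msg)) msg else TRUE
})

#' BasisSet: metabolite basis lineshapes for the toy quantifier
#'
#' Each metabolite is a set of peaks (centre ppm, relative amplitude,
#' linewidth in ppm) rendered with a common lineshape, the toy analogue of a
#' vendor spectral basis set used by linear-combination fitting.
#'
#' @slot peaks data.frame: metabolite, center_ppm, amplitude, linewidth_ppm.
#' @slot lineshape "lorentzian" or "gaussian".
#' @exportClass BasisSet
setClass("BasisSet", representation(
    peaks = "data.frame",
    lineshape = "character"
))

setValidity("BasisSet", function(object) {
    msg <- character()
    need <- c("metabolite", "center_ppm", "amplitude", "linewidth_ppm")
    if (!all(need %in% names(object@peaks)))
        msg <- c(msg, paste("peaks needs columns:", paste(need, collapse = ", ")))
    else {
        if (any(object@peaks$linewidth_ppm <= 0))
            msg <- c(msg, "linewidths must be > 0")
        if (any(object@peaks$amplitude < 0))
            msg <- c(msg, "amplitudes must be >= 0")
        if (nrow(object@peaks) == 0L)
            msg <- c(msg, "at least one peak required")
    }
    if (!object@lineshape %in% c("lorentzian", "gaussian"))
        msg <- c(msg, "lineshape must be 'lorentzian' or 'gaussian'")
    if (length(msg)) msg else TRUE
})

#' Spectrum: a toy 1H spectrum on a monotone-decreasing ppm grid
#'
#' @slot ppm numeric, strictly monotone decreasing chemical-shift axis.
#' @slot intensity numeric, arbitrary units, same length as ppm.
#' @slot noiseSd numeric, the generating (or estimated) noise SD; NA when
#'   unknown.
#' @exportClass Spectrum
setClass("Spectrum", representation(
    ppm = "numeric",
    intensity = "numeric",
    noiseSd = "numeric"
))

setValidity("Spectrum", function(object) {
    msg <- character()
    if (length(object@ppm) != length(object@intensity))
        msg <- c(msg, "ppm and intensity must have equal length")
    if (length(object@ppm) >= 2L && any(diff(object@ppm) >= 0))
        msg <- c(msg, "ppm axis must be strictly monotone decreasing")
    if (any(!is.finite(object@intensity)))
        msg <- c(msg, "intensity must be finite")
    if (length(msg)) msg else TRUE
})

#' QuantFit: linear-combination fit of a spectrum against a basis set
#'
#' @slot estimates named numeric: non-negative concentration estimates.
#' @slot crlbPct named numeric: Cramer-Rao lower bound as percent SD
#'   (100 * sqrt(variance) / estimate); Inf for zero estimates.
#' @slot covariance symmetric covariance matrix of the estimates on the
#'   active set (inactive metabolites carry zero rows/columns).
#' @slot baseline numeric: fitted baseline polynomial coefficients
#'   (intercept first).
#' @slot noiseSd numeric: the noise SD used for the covariance.
#' @exportClass QuantFit
setClass("QuantFit", representation(
    estimates = "numeric",
    crlbPct = "numeric",
    covariance = "matrix",
    baseline = "numeric",
    noiseSd = "numeric"
))

setValidity("QuantFit", function(object) {
    msg <- character()
    if (!identical(names(object@estimates), names(object@crlbPct)))
        msg <- c(msg, "estimates and crlbPct must share names")
    if (any(object@crlbPct < 0, na.rm = TRUE))
        msg <- c(msg, "crlbPct must be >= 0")
    cv <- object@covariance
    if (nrow(cv) != ncol(cv) || max(abs(cv - t(cv))) > 1e-8 * (1 + max(abs(cv))))
        msg <- c(msg, "covariance must be square and symmetric")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
    cat("CohortSpec:", object@nWt, "WT +", object@nKo, "KO animals;",
        length(object@metabolites), "metabolites x",
        length(object@regions), "regions\n")
    ne <- sum(object@genotypeEffects != 0)
    nc <- sum(object@latentCoupling != 0)
    cat("  genotype effects on", ne, "features; latent coupling on", nc,
        "features\n")
    cat("  latent means: WT", object@latentMeans[["WT"]], "/ KO",
        object@latentMeans[["KO"]], "; PI slope (preference)",
        object@piLatentSlope[["preference"]], "\n")
})

setMethod("show", "MrsCohort", function(object) {
    cat("MrsCohort:", length(unique(object@animals$id)), "animals (",
        sum(object@animals$genotype == "WT" &
            object@animals$session == "preference"), "WT /",
        sum(object@animals$genotype == "KO" &
            object@animals$session == "preference"), "KO );",
        nrow(object@measurements), "metabolite measurements\n")
    if (length(object@truth))
        cat("  simulated cohort (truth record attached)\n")
})

setMethod("show", "BasisSet", function(object) {
    cat("BasisSet:", length(unique(object@peaks$metabolite)),
        "metabolites,", nrow(object@peaks), "peaks,", object@lineshape,
        "lineshape\n")
})

setMethod("show", "Spectrum", function(object) {
    cat("Spectrum:", length(object@ppm), "points,",
        sprintf("%.2f to %.2f ppm", max(object@ppm), min(object@ppm)))
    if (is.finite(object@noiseSd)) cat(", noise SD", object@noiseSd)
    cat("\n")
})

setMethod("show", "QuantFit", function(object) {
    cat("QuantFit:", length(object@estimates), "metabolites; noise SD",
        signif(object@noiseSd, 4), "\n")
    df <- data.frame(estimate = signif(object@estimates, 4),
                     crlb_pct = signif(object@crlbPct, 3))
    print(df)
})

#' @describeIn MrsCohort-class behavior table accessor
#' @param object an `MrsCohort`
#' @export
setGeneric("animals", function(object) standardGeneric("animals"))

#' @export
setMethod("animals", "MrsCohort", function(object) object@animals)

#' @describeIn MrsCohort-class long measurement table accessor
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @export
setMethod("measurements", "MrsCohort", function(object) object@measurements)

#' @describeIn MrsCohort-class generative truth record accessor
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @export
setMethod("cohortTruth", "MrsCohort", function(object) object@truth)

#' @describeIn QuantFit-class concentration estimates accessor
#' @param object a `QuantFit`
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @export
setMethod("estimates", "QuantFit", function(object) object@estimates)

#' @describeIn QuantFit-class CRLB percent-SD accessor
#' @export
setGeneric("crlbPct", function(object) standardGeneric("crlbPct"))

#' @export
setMethod("crlbPct", "QuantFit", function(object) object@crlbPct)
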