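#' Apply the CRLB quality filter
#'
#' Retains a quantified measurement iff its Cramer-Rao lower bound, expressed
#' as percent SD, is less than or equal to `maxCrlbPct` (50% by default; note
#' a CRLB of exactly 50 is retained). Filtered rows keep their place but get
#' `NA` concentration and a logical `filtered` flag; a log of removals with
#' reasons is attached as the `"filterLog"` attribute.
#'
#' @param measurements data.frame with columns id, region, metabolite,
#'   concentration, crlb_pct.
#' @param maxCrlbPct retention threshold on CRLB percent SD.
#' @return The measurement table with `concentration` set `NA` where
#'   filtered, plus a `filtered` column and a `"filterLog"` attribute.
#' @export
applyCrlbFilter <- function(measurements, maxCrlbPct = 50) {
    if (anyNA(measurements$crlb_pct)) {
        bad <- which(is.na(measurements$crlb_pct))[1L]
        stop(sprintf("missing CRLB for (%s, %s, %s)",
                     measurements$id[bad], measurements$region[bad],
                     measurements$metabolite[bad]))
    }
    out <- measurements
    drop <- out$crlb_pct > maxCrlbPct
    out$filtered <- drop
    out$concentration[drop] <- NA_real_
    log <- out[drop, c("id", "region", "metabolite", "crlb_pct")]
    if (nrow(log))
        log$reason <- sprintf("CRLB %.1f%% > %.1f%%", log$crlb_pct,
                              maxCrlbPct)
    attr(out, "filterLog") <- log
    out
}

#' Per-(region, metabolite) inclusion rule
#'
#' A metabolite enters the statistical analysis for a region only if enough
#' animals survive the CRLB filter. Under the default `"per_group"` mode the
#' surviving count must reach `minN` in each genotype group; under
#' `"total"` the pooled surviving count must strictly exceed `minN`
#' (the literal "greater than 5" reading).
#'
#' @param filtered output of [applyCrlbFilter()].
#' @param genotypes named character vector mapping animal id to genotype.
#' @param minN threshold (default 5).
#' @param mode `"per_group"` (default) or `"total"`.
#' @return data.frame: region, metabolite, n_wt, n_ko, n_total, included.
#' @export
metaboliteInclusion <- function(filtered, genotypes, minN = 5,
                                mode = c("per_group", "total")) {
    mode <- match.arg(mode)
    ok <- filtered[!filtered$filtered & !is.na(filtered$concentration), ]
    ok$genotype <- genotypes[ok$id]
    grid <- unique(filtered[, c("region", "metabolite")])
    res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
        sub <- ok[ok$region == grid$region[k] &
                  ok$metabolite == grid$metabolite[k], ]
        nwt <- sum(sub$genotype == "WT")
        nko <- sum(sub$genotype == "KO")
        inc <- if (mode == "per_group") (nwt >= minN && nko >= minN)
               else (nwt + nko > minN)
        data.frame(region = grid$region[k], metabolite = grid$metabolite[k],
                   n_wt = nwt, n_ko = nko, n_total = nwt + nko,
                   included = inc, stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    res
}

## Derived features per animal/region from a wide raw-concentration matrix.
## A derived value is missing if any component is missing; a non-positive
## denominator yields a missing cell (logged upstream), never an infinity.
.deriveRow <- function(conc) {
    val <- function(parts) {
        v <- conc[parts]
        if (anyNA(v)) NA_real_ else sum(v)
    }
    out <- numeric(0)
    for (nm in names(.featureDefs())) {
        d <- .featureDefs()[[nm]]
        num <- val(d$num)
        if (is.null(d$den)) out[nm] <- num
        else {
            den <- val(d$den)
            out[nm] <- if (is.na(num) || is.na(den) || den <= 0) NA_real_
                       else num / den
        }
    }
    out
}

#' Build the animal x feature table as a SummarizedExperiment
#'
#' Runs the full feature-construction path: CRLB filter, per-(region,
#' metabolite) inclusion rule, then derived features (tCr = Cr + PCr,
#' Glx = Gln + Glu, and the Glu/GABA, GABA/Glu, NAA/tCr, PCr/tCr ratios).
#' A derived feature is included iff all its raw components are included,
#' and a derived cell is missing iff any contributing measurement was
#' filtered or absent; division only ever happens by strictly positive
#' denominators.
#'
#' @param cohort a [MrsCohort-class], or a measurement data.frame (then
#'   `behavior` must be supplied).
#' @param behavior optional per-animal behavior table as from
#'   [behaviorTable()]; computed from the cohort when omitted.
#' @param maxCrlbPct CRLB filter threshold (percent SD).
#' @param minN,mode inclusion rule, see [metaboliteInclusion()].
#' @return A [SummarizedExperiment::SummarizedExperiment-class]: rows are
#'   (region, feature) pairs with rowData columns region, feature, type
#'   (raw/derived) and included; columns are animals with colData genotype
#'   and behavior indices; the single assay `"concentration"` holds values
#'   with `NA` for missing cells. `metadata()` carries the filter log and
#'   the inclusion report.
#' @export
#' @examples
#' coh <- simulateCohort(cohortSpec(), seed = 1)
#' se <- buildFeatureTable(coh)
#' se
buildFeatureTable <- function(cohort, behavior = NULL, maxCrlbPct = 50,
                              minN = 5, mode = c("per_group", "total")) {
    mode <- match.arg(mode)
    meas <- if (is(cohort, "MrsCohort")) measurements(cohort) else cohort
    if (is.null(behavior)) {
        if (!is(cohort, "MrsCohort"))
            stop("behavior table required when 'cohort' is a data.frame")
        behavior <- behaviorTable(cohort)
    }
    genotypes <- setNames(behavior$genotype, behavior$id)

    filtered <- applyCrlbFilter(meas, maxCrlbPct)
    inclusion <- metaboliteInclusion(filtered, genotypes, minN, mode)

    ids <- behavior$id
    regions <- unique(meas$region)
    mets <- unique(meas$metabolite)
    defs <- .featureDefs()

    rows <- list(); vals <- list(); logDerived <- list()
    for (rg in regions) {
        sub <- filtered[filtered$region == rg, ]
        conc <- matrix(NA_real_, length(mets), length(ids),
                       dimnames = list(mets, ids))
        idx <- cbind(match(sub$metabolite, mets), match(sub$id, ids))
        keep <- !is.na(idx[, 2L])
        conc[idx[keep, , drop = FALSE]] <- sub$concentration[keep]

        derived <- vapply(ids, function(a) .deriveRow(conc[, a]),
                          numeric(length(defs)))
        # log derived cells missing because of a non-positive denominator
        for (nm in names(defs)) {
            d <- defs[[nm]]
            if (is.null(d$den)) next
            den <- colSums(conc[d$den, , drop = FALSE])
            badDen <- !is.na(den) & den <= 0
            if (any(badDen))
                logDerived[[length(logDerived) + 1L]] <- data.frame(
                    id = ids[badDen], region = rg, feature = nm,
                    reason = "non-positive denominator",
                    stringsAsFactors = FALSE)
        }

        incl <- setNames(inclusion$included[inclusion$region == rg],
                         inclusion$metabolite[inclusion$region == rg])
        dIncl <- vapply(defs, function(d)
            all(incl[c(d$num, d$den)]), logical(1))

        rows[[rg]] <- data.frame(
            region = rg,
            feature = c(mets, names(defs)),
            type = rep(c("raw", "derived"), c(length(mets), length(defs))),
            included = c(incl[mets], dIncl),
            stringsAsFactors = FALSE)
        vals[[rg]] <- rbind(conc, derived)
    }

    rowdat <- do.call(rbind, rows)
    assay <- do.call(rbind, vals)
    rownames(assay) <- rownames(rowdat) <-
        paste(rowdat$region, rowdat$feature, sep = ":")

    colDat <- behavior[match(ids, behavior$id), , drop = FALSE]
    rownames(colDat) <- ids
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(concentration = assay),
        rowData = S4Vectors::DataFrame(rowdat),
        colData = S4Vectors::DataFrame(colDat[, setdiff(names(colDat), "id"),
                                              drop = FALSE]))
    S4Vectors::metadata(se) <- list(
        filterLog = attr(filtered, "filterLog"),
        inclusion = inclusion,
        derivedLog = if (length(logDerived)) do.call(rbind, logDerived)
                     else data.frame(),
        maxCrlbPct = maxCrlbPct, minN = minN, mode = mode)
    se
}

#' Wide per-animal feature table as a data.frame
#'
#' @param se a feature table from [buildFeatureTable()].
#' @param includedOnly drop features that failed the inclusion rule.
#' @return data.frame, one row per animal per region, features as columns.
#' @export
featureFrame <- function(se, includedOnly = FALSE) {
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    a <- SummarizedExperiment::assay(se, "concentration")
    if (includedOnly) {
        a <- a[rd$included, , drop = FALSE]
        rd <- rd[rd$included, , drop = FALSE]
    }
    out <- do.call(rbind, lapply(unique(rd$region), function(rg) {
        sel <- rd$region == rg
        m <- t(a[sel, , drop = FALSE])
        colnames(m) <- rd$feature[sel]
        data.frame(id = rownames(m), region = rg, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
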