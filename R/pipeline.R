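## Small deterministic string hash (FNV-style, 31-bit) for the run manifest.
.configHash <- function(config) {
    s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
    h <- 17
    for (b in utf8ToInt(as.character(s)))
        h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

.defaultRunConfig <- function() {
    list(
        simulate = TRUE,
        inputDir = NULL,
        regions = brainRegions(),
        indices = c("pi_preference", "pi_recognition"),
        maxCrlbPct = 50,
        minN = 5,
        inclusionMode = "per_group",
        permutations = 5000,
        sidedness = "two_sided",
        tVariant = "welch",
        rocPositive = NULL,       # must be explicit when the ROC stage runs
        rocFeatures = "flagged",  # or an explicit character vector
        rocRegion = "PFC",
        rocIndex = "pi_preference",
        ciMethod = "hanley-mcneil",
        seed = NULL
    )
}

#' Validate and complete a pipeline run configuration
#'
#' Fills unspecified keys with defaults and checks ranges before any
#' computation: thresholds must be in range, and a seed must be present
#' whenever a stochastic stage (simulation, permutations) will run. Every
#' analysis choice left open by convention (inclusion mode, test sidedness,
#' t-test variant, ROC positive class, CI method) is an explicit key.
#'
#' @param config named list (or path to a YAML file when the yaml package is
#'   available).
#' @return The completed, validated config list.
#' @export
validateRunConfig <- function(config = list()) {
    if (is.character(config)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("reading YAML configs requires the yaml package")
        config <- yaml::read_yaml(config)
    }
    full <- .defaultRunConfig()
    unknown <- setdiff(names(config), names(full))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    full[names(config)] <- config
    if (full$maxCrlbPct < 0) stop("maxCrlbPct must be >= 0")
    if (full$minN < 0) stop("minN must be >= 0")
    if (!full$inclusionMode %in% c("per_group", "total"))
        stop("inclusionMode must be 'per_group' or 'total'")
    if (!full$sidedness %in% c("two_sided", "greater", "less"))
        stop("invalid sidedness")
    if (!full$tVariant %in% c("welch", "student"))
        stop("tVariant must be 'welch' or 'student'")
    if (full$permutations < 1) stop("permutations must be >= 1")
    needsSeed <- isTRUE(full$simulate) || full$permutations > 0
    if (needsSeed && is.null(full$seed))
        stop("config must set a seed: simulation and permutation stages ",
             "are stochastic")
    if (isTRUE(full$simulate) && !is.null(full$inputDir))
        stop("set either simulate = TRUE or inputDir, not both")
    if (!isTRUE(full$simulate) && is.null(full$inputDir))
        stop("either simulate = TRUE or an inputDir is required")
    full
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> behavior -> features -> screen ->
#' group tests -> ROC -> report, writing each stage's CSV outputs plus a
#' human-readable `report.txt` and a `manifest.json` recording the config
#' hash, seed and package version. Reruns with an identical config and seed
#' are byte-identical on all CSVs.
#'
#' @param config run configuration, see [validateRunConfig()]. The ROC stage
#'   runs only when `rocPositive` is set (the positive class is never
#'   defaulted).
#' @param outDir output directory.
#' @param spec optional [CohortSpec-class] for the simulation stage
#'   (default [cohortSpec()]).
#' @return Invisibly, a list with every stage's tables and the output paths.
#' @export
#' @examples
#' \donttest{
#' res <- runPipeline(list(seed = 7, permutations = 199,
#'                         rocPositive = "WT"),
#'                    outDir = tempfile())
#' names(res)
#' }
runPipeline <- function(config = list(), outDir, spec = cohortSpec()) {
    config <- validateRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name) {
        p <- file.path(outDir, name)
        write.csv(x, p, row.names = FALSE)
        p
    }
    paths <- character()

    # stage: cohort
    if (isTRUE(config$simulate)) {
        cohort <- simulateCohort(spec, seed = config$seed)
        paths <- c(paths, writeCohort(cohort, outDir))
    } else {
        cohort <- readCohort(config$inputDir)
    }

    # stage: behavior
    beh <- behaviorTable(cohort)
    paths <- c(paths, wr(beh, "behavior_results.csv"))
    anovaRows <- list()
    for (ses in unique(animals(cohort)$session)) {
        sub <- animals(cohort)[animals(cohort)$session == ses, ]
        long <- rbind(
            data.frame(genotype = sub$genotype, target = "target",
                       value = percentInvestigation(sub$et_target,
                                                    sub$et_other)),
            data.frame(genotype = sub$genotype, target = "other",
                       value = percentInvestigation(sub$et_other,
                                                    sub$et_target)))
        av <- twoWayAnovaSidak(long)
        av$anova$session <- ses
        av$contrasts$session <- ses
        anovaRows[[ses]] <- av
    }
    anovaTab <- do.call(rbind, lapply(anovaRows, `[[`, "anova"))
    sidakTab <- do.call(rbind, lapply(anovaRows, `[[`, "contrasts"))
    rownames(anovaTab) <- rownames(sidakTab) <- NULL
    paths <- c(paths, wr(anovaTab, "anova.csv"),
               wr(sidakTab, "sidak_contrasts.csv"))

    # stage: features
    se <- buildFeatureTable(cohort, behavior = beh,
                            maxCrlbPct = config$maxCrlbPct,
                            minN = config$minN, mode = config$inclusionMode)
    paths <- c(paths, wr(featureFrame(se), "features.csv"),
               wr(S4Vectors::metadata(se)$inclusion, "inclusion_report.csv"))

    # stage: screen
    screens <- list()
    for (rg in config$regions) for (ix in config$indices) {
        sc <- tryCatch(
            screenFeatures(se, rg, index = ix, B = config$permutations,
                           seed = config$seed,
                           sidedness = config$sidedness),
            error = function(e) NULL)
        if (!is.null(sc)) screens[[paste(rg, ix)]] <- sc
    }
    screenTab <- do.call(rbind, screens)
    rownames(screenTab) <- NULL
    paths <- c(paths, wr(screenTab, "screen_results.csv"),
               wr(screenTab[, c("feature", "region", "index", "r",
                                "neg_log10_p", "tier")], "volcano.csv"))

    # stage: group tests
    gt <- groupTests(se, variant = config$tVariant)
    paths <- c(paths, wr(gt, "group_tests.csv"))

    # stage: ROC (only with an explicit positive class)
    rocTab <- NULL
    if (!is.null(config$rocPositive)) {
        feats <- config$rocFeatures
        if (identical(feats, "flagged")) {
            sel <- screenTab$region == config$rocRegion &
                screenTab$index == config$rocIndex &
                screenTab$tier != "none"
            feats <- screenTab$feature[sel]
        }
        if (length(feats)) {
            rocTab <- rocTable(se, feats, config$rocRegion,
                               positive = config$rocPositive,
                               ciMethod = config$ciMethod,
                               seed = config$seed)
            paths <- c(paths, wr(rocTab, "roc_results.csv"))
        }
    }

    # manifest + report
    manifest <- list(config = config, configHash = .configHash(config),
                     seed = config$seed,
                     package = "socialMRS",
                     version = as.character(packageVersion("socialMRS")))
    mp <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, mp)

    rp <- file.path(outDir, "report.txt")
    lines <- c(
        "Metabolite / social-behavior analysis report",
        sprintf("config %s, seed %s", manifest$configHash, config$seed),
        "",
        sprintf("Animals: %d WT, %d KO",
                sum(beh$genotype == "WT"), sum(beh$genotype == "KO")),
        sprintf("Features screened: %d; flagged q95: %d; q975: %d",
                nrow(screenTab), sum(screenTab$tier != "none"),
                sum(screenTab$tier == "q975")),
        "",
        "Flagged features:",
        if (any(screenTab$tier != "none"))
            sprintf("  %s %s vs %s: r = %.3f, p_perm = %.4g (%s)",
                    screenTab$region[screenTab$tier != "none"],
                    screenTab$feature[screenTab$tier != "none"],
                    screenTab$index[screenTab$tier != "none"],
                    screenTab$r[screenTab$tier != "none"],
                    screenTab$p_perm[screenTab$tier != "none"],
                    screenTab$tier[screenTab$tier != "none"])
        else "  (none)",
        "",
        if (!is.null(rocTab)) c(
            "Biomarker evaluation (in-sample logistic + binormal ROC,",
            sprintf(" positive class %s, Youden cutoff):",
                    config$rocPositive),
            sprintf("  %s %s: AUC %.3f [%.3f, %.3f], cutoff %.3f, sens %.1f%%, spec %.1f%%",
                    rocTab$region, rocTab$feature, rocTab$auc,
                    rocTab$auc_ci_low, rocTab$auc_ci_high, rocTab$cutoff,
                    rocTab$sensitivity_pct, rocTab$specificity_pct),
            "  note: trained on all samples (no held-out validation)")
        else "ROC stage skipped (no positive class configured)")
    writeLines(unlist(lines), rp)
    paths <- c(paths, rp)

    invisible(list(cohort = cohort, behavior = beh, anova = anovaTab,
                   sidak = sidakTab, features = se, screen = screenTab,
                   groupTests = gt, roc = rocTab, manifest = manifest,
                   paths = paths))
}
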