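mkMeas <- function(crlb) {
    data.frame(id = sprintf("A%02d", seq_along(crlb)), region = "PFC",
               metabolite = "Glu", concentration = 5, crlb_pct = crlb,
               stringsAsFactors = FALSE)
}

test_that("CRLB filter boundary: exactly 50 retained, above filtered", {
    m <- mkMeas(c(0, 49.9, 50, 50.1, 80))
    out <- applyCrlbFilter(m, maxCrlbPct = 50)
    expect_equal(out$filtered, c(FALSE, FALSE, FALSE, TRUE, TRUE))
    expect_equal(is.na(out$concentration), out$filtered)
    log <- attr(out, "filterLog")
    expect_equal(nrow(log), 2L)
    expect_match(log$reason[1], "CRLB")

    # all-zero CRLB: identity
    clean <- applyCrlbFilter(mkMeas(rep(0, 4)))
    expect_identical(clean$concentration, rep(5, 4))

    bad <- mkMeas(c(1, NA))
    expect_error(applyCrlbFilter(bad), "A02")
})

test_that("filter is monotone in the threshold", {
    set.seed(10)
    m <- mkMeas(runif(60, 0, 100))
    kept40 <- !applyCrlbFilter(m, 40)$filtered
    kept60 <- !applyCrlbFilter(m, 60)$filtered
    expect_true(all(kept60[kept40]))  # raising the cap never drops a row
})

test_that("inclusion rule counts survivors per genotype group", {
    ids <- sprintf("A%02d", 1:15)
    genotypes <- setNames(rep(c("WT", "KO"), c(5, 10)), ids)
    m <- data.frame(id = ids, region = "PFC", metabolite = "Cr",
                    concentration = 4, crlb_pct = 10,
                    stringsAsFactors = FALSE)
    f <- applyCrlbFilter(m)
    inc <- metaboliteInclusion(f, genotypes, minN = 5)
    expect_true(inc$included)        # 5 WT / 10 KO survivors
    expect_equal(inc$n_wt, 5L); expect_equal(inc$n_ko, 10L)

    # filter one WT away: 4 WT / 10 KO fails the per-group rule
    m$crlb_pct[1] <- 60
    inc2 <- metaboliteInclusion(applyCrlbFilter(m), genotypes, minN = 5)
    expect_false(inc2$included)
    # ...but passes the pooled "greater than" mode (14 > 5)
    inc3 <- metaboliteInclusion(applyCrlbFilter(m), genotypes, minN = 5,
                                mode = "total")
    expect_true(inc3$included)
    # minN = 0: anything observed at all is included
    inc4 <- metaboliteInclusion(applyCrlbFilter(m), genotypes, minN = 0)
    expect_true(inc4$included)
})

test_that("derived features follow their definitions and propagate NA", {
    coh <- simulateCohort(tinySpec(), seed = 6)
    meas <- measurements(coh)
    pick <- function(id, met) meas$concentration[meas$id == id &
        meas$region == "PFC" & meas$metabolite == met]
    meas$concentration[meas$id == "WT01" & meas$region == "PFC" &
                       meas$metabolite == "Cr"] <- 4
    meas$concentration[meas$id == "WT01" & meas$region == "PFC" &
                       meas$metabolite == "PCr"] <- 2
    meas$crlb_pct <- 1  # keep everything
    # knock out GABA for one animal via the filter
    meas$crlb_pct[meas$id == "WT02" & meas$region == "PFC" &
                  meas$metabolite == "GABA"] <- 99
    coh2 <- new("MrsCohort", animals = animals(coh), measurements = meas,
                truth = list())
    se <- buildFeatureTable(coh2, minN = 0)
    a <- SummarizedExperiment::assay(se, "concentration")
    expect_equal(a["PFC:tCr", "WT01"], 6)
    expect_equal(a["PFC:Glu/GABA", "WT01"],
                 pick("WT01", "Glu") / pick("WT01", "GABA"))
    expect_equal(a["PFC:Glu/GABA", "WT01"] * a["PFC:GABA/Glu", "WT01"], 1,
                 tolerance = 1e-12)
    # GABA filtered -> both ratios missing even though Glu is present
    expect_true(is.na(a["PFC:Glu/GABA", "WT02"]))
    expect_true(is.na(a["PFC:GABA/Glu", "WT02"]))
    expect_false(is.na(a["PFC:Glu", "WT02"]))
})

test_that("zero denominators yield missing cells and a log entry, never Inf", {
    coh <- simulateCohort(tinySpec(), seed = 13)
    meas <- measurements(coh)
    meas$crlb_pct <- 1
    meas$concentration[meas$id == "KO01" & meas$region == "PFC" &
                       meas$metabolite == "GABA"] <- 0
    coh2 <- new("MrsCohort", animals = animals(coh), measurements = meas,
                truth = list())
    se <- buildFeatureTable(coh2, minN = 0)
    a <- SummarizedExperiment::assay(se, "concentration")
    expect_true(is.na(a["PFC:Glu/GABA", "KO01"]))
    expect_false(any(is.infinite(a)))
    log <- S4Vectors::metadata(se)$derivedLog
    expect_true(any(log$id == "KO01" & log$feature == "Glu/GABA"))
})

test_that("every missing derived cell traces to a missing component", {
    coh <- simulateCohort(cohortSpec(), seed = 17)
    se <- buildFeatureTable(coh)
    a <- SummarizedExperiment::assay(se, "concentration")
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    defs <- socialMRS:::.featureDefs()
    for (i in which(rd$type == "derived")) {
        parts <- unique(unlist(defs[[rd$feature[i]]]))
        partRows <- paste(rd$region[i], parts, sep = ":")
        miss <- is.na(a[i, ])
        if (any(miss))
            expect_true(all(colSums(is.na(
                a[partRows, miss, drop = FALSE])) > 0))
    }
    # derived feature included iff all components included
    incl <- setNames(rd$included, rownames(rd))
    for (i in which(rd$type == "derived")) {
        parts <- paste(rd$region[i],
                       unique(unlist(defs[[rd$feature[i]]])), sep = ":")
        expect_equal(rd$included[i], all(incl[parts]))
    }
})
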